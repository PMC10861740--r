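# Synthetic multi-unit ICU registry generator.
#
# Emulates the joint structure the benchmarking assumes: a right-skewed
# SAPS II severity distribution per diagnosis group (discretized gamma
# matched to published per-group quartiles), GCS monotonically coupled to
# severity, hospital death driven by a logistic risk model with per-unit
# odds multipliers, log-normal length of stay with severity-linked
# location and a shorter location for non-survivors, TISS accrued as a
# per-day rate with a severity loading, and annual unit costs proportional
# to the unit's total TISS with multiplicative noise. Unit-level
# distortions (resource/cost inflation, mortality odds) are injectable and
# recorded in a truth table for parameter-recovery tests.

# per-diagnosis-group marginal parameters; SAPS gamma shape/rate fitted
# once to the published per-group quartiles, LOS/TISS locations chosen so
# group medians land on the published values
.GROUP_PARAMS <- data.frame(
  group = c("NONTRAUMATIC_ICH", "SAH", "TBI_MULTITRAUMA", "TBI_ISOLATED",
            "OTHER"),
  saps_shape = c(5.2438, 2.5998, 3.2855, 3.5155, 4.3590),
  saps_rate = c(0.14065, 0.07590, 0.09658, 0.10843, 0.11265),
  saps_med = c(34, 28, 31, 29, 36),
  los_med = c(1.7, 3.4, 2.3, 1.5, 1.5),
  los_sdlog = c(1.108, 1.225, 1.335, 1.015, 0.933),
  tiss_rate = c(36, 36, 36, 36, 39),
  age_mean = c(67, 57, 48, 56, 61),
  age_sd = c(14, 14, 20, 20, 16),
  p_female = c(0.37, 0.59, 0.28, 0.28, 0.39),
  p_operative = c(0.49, 0.28, 0.25, 0.31, 0.25),
  stringsAsFactors = FALSE)

.PREMORBID_P <- list(
  NONTRAUMATIC_ICH = c(0.80, 0.13, 0.053, 0.018),
  SAH = c(0.87, 0.11, 0.016, 0.009),
  TBI_MULTITRAUMA = c(0.92, 0.057, 0.022, 0.004),
  TBI_ISOLATED = c(0.79, 0.16, 0.044, 0.010),
  OTHER = c(0.70, 0.18, 0.087, 0.031))

#' Configuration for the synthetic registry generator
#'
#' Defaults describe a realistic 6-unit, 3-year university-ICU registry:
#' about a fifth of emergency admissions are neurosurgical, split across
#' nontraumatic ICH, SAH and traumatic brain injury with published
#' case-mix proportions; severity, stay length and TISS accrual follow the
#' per-group marginals the package documents in its methods vignette.
#'
#' @param n_units Number of ICUs (ids \code{U1..Un}; the last unit
#'   invoices in CHF, the rest in EUR).
#' @param years Calendar years covered.
#' @param admissions_per_unit_year Rows generated per unit-year; a length-2
#'   vector is treated as a uniform range.
#' @param neuro_fraction Fraction of admissions with a neurosurgical
#'   diagnosis.
#' @param neuro_mix Probabilities over the four neurosurgical groups
#'   (ICH, SAH, multitrauma TBI, isolated TBI); must sum to 1.
#' @param mortality_model \code{\link{risk_model}} generating death
#'   probabilities from severity.
#' @param los_saps_slope Increase in log LOS per SAPS II point.
#' @param nonsurvivor_los_shift Additive shift of the log-LOS location for
#'   non-survivors (negative: decedents stay shorter).
#' @param tiss_saps_loading Increase in log TISS-per-day rate per SAPS II
#'   point above the cohort median.
#' @param tiss_sdlog SD of the log TISS-per-day rate.
#' @param cost_level_meanlog,cost_level_sdlog Log-normal parameters of the
#'   per-unit cost level (EUR per TISS point).
#' @param cost_noise_sdlog SD of the multiplicative noise on annual costs.
#' @param donor_fraction Fraction admitted as potential organ donors.
#' @param elective_fraction,transfer_fraction,readmission_fraction
#'   Fractions exercising the corresponding exclusion rules.
#' @param unknown_outcome_fraction,missing_tiss_fraction,
#'   missing_sex_fraction,missing_gcs_fraction Missingness fractions.
#' @param beds_range,fte_per_bed_range Uniform sampling ranges for unit
#'   size and physician staffing.
#' @param p_independent_org Probability a unit is an independent
#'   organization (vs part of another department).
#' @param unit_mortality_odds Baseline per-unit mortality odds multipliers
#'   (recycled to \code{n_units}).
#' @param distortions Named list of per-unit distortions; use
#'   \code{\link{inject_unit_distortion}} rather than writing it directly.
#' @return An object of class \code{registry_config}.
#' @export
registry_config <- function(n_units = 6, years = 2015:2017,
                            admissions_per_unit_year = 1600,
                            neuro_fraction = 0.217,
                            neuro_mix = c(NONTRAUMATIC_ICH = 0.408,
                                          SAH = 0.226,
                                          TBI_MULTITRAUMA = 0.132,
                                          TBI_ISOLATED = 0.234),
                            mortality_model = recalibrated_saps2_risk(),
                            los_saps_slope = 0.02,
                            nonsurvivor_los_shift = -0.4,
                            tiss_saps_loading = 0.003,
                            tiss_sdlog = 0.35,
                            cost_level_meanlog = log(50),
                            cost_level_sdlog = 0.15,
                            cost_noise_sdlog = 0.05,
                            donor_fraction = 0.011,
                            elective_fraction = 0.18,
                            transfer_fraction = 0.02,
                            readmission_fraction = 0.04,
                            unknown_outcome_fraction = 0.004,
                            missing_tiss_fraction = 0.008,
                            missing_sex_fraction = 0.002,
                            missing_gcs_fraction = 0.008,
                            beds_range = c(20, 40),
                            fte_per_bed_range = c(0.15, 0.45),
                            p_independent_org = 2 / 3,
                            unit_mortality_odds = 1,
                            distortions = list()) {
  cfg <- as.list(environment())
  if (cfg$n_units < 1 || length(cfg$years) < 1) {
    stop("need at least one unit and one year")
  }
  if (any(cfg$admissions_per_unit_year <= 0) ||
      !length(cfg$admissions_per_unit_year) %in% 1:2) {
    stop("admissions_per_unit_year must be a positive count or range")
  }
  if (abs(sum(cfg$neuro_mix) - 1) > 1e-8) stop("neuro_mix must sum to 1")
  if (cfg$neuro_fraction < 0 || cfg$neuro_fraction > 1) {
    stop("neuro_fraction must be in [0, 1]")
  }
  fracs <- c(cfg$donor_fraction, cfg$elective_fraction,
             cfg$transfer_fraction, cfg$readmission_fraction,
             cfg$unknown_outcome_fraction, cfg$missing_tiss_fraction,
             cfg$missing_sex_fraction, cfg$missing_gcs_fraction)
  if (any(fracs < 0) || any(fracs >= 1)) stop("fractions must be in [0, 1)")
  if (any(c(cfg$tiss_sdlog, cfg$cost_level_sdlog) < 0) ||
      cfg$cost_noise_sdlog < 0) {
    stop("scale parameters must be non-negative")
  }
  if (!inherits(cfg$mortality_model, "risk_model")) {
    stop("mortality_model must be a risk_model")
  }
  cfg$unit_mortality_odds <- rep_len(cfg$unit_mortality_odds, cfg$n_units)
  if (any(cfg$unit_mortality_odds <= 0)) {
    stop("mortality odds multipliers must be positive")
  }
  structure(cfg, class = "registry_config")
}

#' @export
print.registry_config <- function(x, ...) {
  cat(sprintf("Synthetic registry config: %d unit(s) x %d year(s), ~%s/unit-year\n",
              x$n_units, length(x$years),
              paste(x$admissions_per_unit_year, collapse = "-")))
  if (length(x$distortions)) {
    cat("  distorted units:", paste(names(x$distortions), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Inject a unit-level distortion into a generator configuration
#'
#' Marks one unit so that every admission's length of stay and TISS total
#' (and hence, through the cost model, the unit's annual costs) are scaled
#' by \code{cost_inflation}, and/or its death odds are multiplied by
#' \code{mortality_odds}. The injected factors are recorded in the truth
#' table of the generated registry for recovery assertions.
#'
#' @param config A \code{registry_config}.
#' @param unit_id Unit to distort (\code{"U1"} .. \code{"Un"}).
#' @param cost_inflation Multiplier on per-admission resource and cost
#'   accrual (> 0).
#' @param mortality_odds Multiplier on the unit's death odds (> 0).
#' @return The modified configuration.
#' @export
inject_unit_distortion <- function(config, unit_id, cost_inflation = 1,
                                   mortality_odds = 1) {
  stopifnot(inherits(config, "registry_config"))
  known <- sprintf("U%d", seq_len(config$n_units))
  if (!unit_id %in% known) stop("unknown unit: ", unit_id)
  if (cost_inflation <= 0 || mortality_odds <= 0) {
    stop("distortion factors must be positive")
  }
  config$distortions[[unit_id]] <- list(cost_inflation = cost_inflation,
                                        mortality_odds = mortality_odds)
  config
}

# deterministic substream seed per unit-year (documented scheme: the master
# seed plus fixed primes times the unit and year indices, mod 2^31 - 19)
.substream_seed <- function(seed, u, y) {
  as.integer((as.numeric(seed) + 7919 * u + 104729 * y) %% 2147483629)
}

.sim_unit_year <- function(cfg, unit_id, u, year, yi, n, seed, mort_mult,
                           inflation) {
  set.seed(.substream_seed(seed, u, yi * 1000 + 0))
  gp <- .GROUP_PARAMS
  p_group <- c(cfg$neuro_fraction * cfg$neuro_mix[gp$group[1:4]],
               OTHER = 1 - cfg$neuro_fraction)
  gi <- sample.int(5, n, replace = TRUE, prob = p_group)
  group <- gp$group[gi]
  saps2 <- pmin(as.integer(round(stats::rgamma(n, gp$saps_shape[gi],
                                               gp$saps_rate[gi]))), 163L)
  gcs <- as.integer(pmin(pmax(round(
    15 - 12 * stats::plogis((saps2 - 45) / 10) + stats::rnorm(n, 0, 1.5)),
    3), 15))
  age <- round(pmin(pmax(stats::rnorm(n, gp$age_mean[gi], gp$age_sd[gi]),
                         18), 100))
  sex <- ifelse(stats::runif(n) < gp$p_female[gi], "F", "M")
  operative <- stats::runif(n) < gp$p_operative[gi]
  premorbid <- vapply(group, function(g) {
    sample(c("NORMAL", "LIGHT", "MODERATE", "SEVERE"), 1,
           prob = .PREMORBID_P[[g]])
  }, character(1))

  organ_donor <- stats::runif(n) < cfg$donor_fraction
  p <- predict(cfg$mortality_model, data.frame(saps2 = saps2))
  odds <- p / (1 - p) * mort_mult
  p_unit <- odds / (1 + odds)
  died <- stats::runif(n) < p_unit
  died[organ_donor] <- TRUE

  mu <- log(gp$los_med[gi]) +
    cfg$los_saps_slope * (saps2 - gp$saps_med[gi]) +
    ifelse(died & !organ_donor, cfg$nonsurvivor_los_shift, 0)
  los <- stats::rlnorm(n, mu, gp$los_sdlog[gi])
  los[organ_donor] <- stats::rlnorm(sum(organ_donor), log(1), 0.5)
  los <- pmax(round(los * inflation, 1), 0.1)
  rate <- exp(log(gp$tiss_rate[gi]) + cfg$tiss_saps_loading * (saps2 - 31) +
                stats::rnorm(n, 0, cfg$tiss_sdlog))
  tiss <- round(los * rate)

  adm_type <- ifelse(stats::runif(n) < cfg$elective_fraction, "ELECTIVE",
                     "EMERGENCY")
  transfer <- stats::runif(n) < cfg$transfer_fraction
  readm <- stats::runif(n) < cfg$readmission_fraction

  died_rec <- died
  died_rec[stats::runif(n) < cfg$unknown_outcome_fraction] <- NA
  tiss_rec <- tiss
  tiss_rec[stats::runif(n) < cfg$missing_tiss_fraction] <- NA
  sex_rec <- sex
  sex_rec[stats::runif(n) < cfg$missing_sex_fraction] <- NA
  gcs_rec <- gcs
  gcs_rec[stats::runif(n) < cfg$missing_gcs_fraction] <- NA

  data.frame(
    admission_id = sprintf("%s-%d-%05d", unit_id, year, seq_len(n)),
    unit_id = unit_id, year = year, diagnosis_group = group,
    admission_type = adm_type, saps2 = saps2, gcs = gcs_rec, age = age,
    sex = sex_rec, operative = operative, premorbid_status = premorbid,
    los_days = los, tiss_total = tiss_rec, died_in_hospital = died_rec,
    organ_donor = organ_donor, readmission = readm,
    icu_transfer_in = transfer, tiss_true = tiss,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-unit ICU registry
#'
#' @param config A \code{\link{registry_config}}.
#' @param seed Integer master seed; the same config and seed always yield
#'   an identical registry. Unit-years are generated from independent
#'   substreams derived deterministically from the master seed.
#' @return An object of class \code{icu_registry}: list with
#'   \code{admissions} (validated data frame), \code{profiles}
#'   (\code{\link{unit_profiles}}) and \code{truth} (per-unit injected
#'   cost level, resource/cost inflation and mortality odds multiplier).
#' @export
simulate_registry <- function(config, seed = 1) {
  stopifnot(inherits(config, "registry_config"))
  set.seed(as.integer(seed))
  nu <- config$n_units
  unit_ids <- sprintf("U%d", seq_len(nu))
  beds <- as.integer(round(stats::runif(nu, config$beds_range[1],
                                        config$beds_range[2])))
  fte <- round(stats::runif(nu, config$fte_per_bed_range[1],
                            config$fte_per_bed_range[2]), 2)
  indep <- stats::runif(nu) < config$p_independent_org
  cost_level <- stats::rlnorm(nu, config$cost_level_meanlog,
                              config$cost_level_sdlog)
  currency <- c(rep("EUR", nu - 1), "CHF")
  if (nu == 1) currency <- "EUR"

  infl <- vapply(unit_ids, function(uid) {
    d <- config$distortions[[uid]]
    if (is.null(d)) 1 else d$cost_inflation
  }, numeric(1))
  mort <- config$unit_mortality_odds * vapply(unit_ids, function(uid) {
    d <- config$distortions[[uid]]
    if (is.null(d)) 1 else d$mortality_odds
  }, numeric(1))

  npy <- config$admissions_per_unit_year
  pieces <- list()
  costs <- list()
  for (u in seq_len(nu)) {
    for (yi in seq_along(config$years)) {
      year <- config$years[yi]
      set.seed(.substream_seed(seed, u, yi * 1000 + 500))
      n <- if (length(npy) == 2) {
        sample(seq(npy[1], npy[2]), 1)
      } else {
        as.integer(npy)
      }
      piece <- .sim_unit_year(config, unit_ids[u], u, year, yi, n, seed,
                              mort[u], infl[u])
      total_tiss <- sum(piece$tiss_true)
      set.seed(.substream_seed(seed, u, yi * 1000 + 999))
      eur <- cost_level[u] * total_tiss *
        exp(stats::rnorm(1, 0, config$cost_noise_sdlog))
      native <- if (currency[u] == "CHF") eur * 1.09 else eur
      costs[[length(costs) + 1]] <- data.frame(
        unit_id = unit_ids[u], year = year, amount = round(native, 2),
        stringsAsFactors = FALSE)
      piece$tiss_true <- NULL
      pieces[[length(pieces) + 1]] <- piece
    }
  }
  admissions <- validate_admissions(do.call(rbind, pieces))
  units <- data.frame(unit_id = unit_ids, beds = beds,
                      fte_physicians_per_bed = fte,
                      independent_org = indep, currency = currency,
                      ppp_factor = 1, stringsAsFactors = FALSE)
  truth <- data.frame(unit_id = unit_ids, cost_level = cost_level,
                      cost_inflation = unname(infl),
                      mortality_odds = unname(mort),
                      stringsAsFactors = FALSE)
  structure(list(admissions = admissions,
                 profiles = unit_profiles(units, do.call(rbind, costs)),
                 truth = truth, seed = as.integer(seed)),
            class = "icu_registry")
}

#' @export
print.icu_registry <- function(x, ...) {
  cat(sprintf("Synthetic ICU registry: %d admissions, %d unit(s), years %s (seed %d)\n",
              nrow(x$admissions), nrow(x$profiles$units),
              paste(range(x$admissions$year), collapse = "-"), x$seed))
  invisible(x)
}

#' Write a registry to disk in the registry-exchange formats
#'
#' Emits \code{admissions.csv} (the admission table),
#' \code{unit_profiles.yaml} (profile document keyed by unit id) and
#' \code{truth.json} (the injected-effect record). The files round-trip
#' losslessly through \code{\link{read_admissions}} and
#' \code{\link{read_unit_profiles}}.
#'
#' @param registry An \code{icu_registry}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "icu_registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  adm_path <- file.path(dir, "admissions.csv")
  utils::write.csv(registry$admissions, adm_path, row.names = FALSE,
                   na = "NA")
  prof <- registry$profiles
  doc <- lapply(seq_len(nrow(prof$units)), function(i) {
    u <- prof$units[i, ]
    cc <- prof$costs[prof$costs$unit_id == u$unit_id, ]
    amounts <- as.list(cc$amount)
    names(amounts) <- as.character(cc$year)
    list(beds = u$beds, fte_physicians_per_bed = u$fte_physicians_per_bed,
         independent_org = u$independent_org, currency = u$currency,
         ppp_factor = u$ppp_factor, annual_direct_costs = amounts)
  })
  names(doc) <- prof$units$unit_id
  prof_path <- file.path(dir, "unit_profiles.yaml")
  yaml::write_yaml(doc, prof_path, precision = 15)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(registry$truth, truth_path, dataframe = "rows",
                       digits = NA, pretty = TRUE)
  invisible(c(adm_path, prof_path, truth_path))
}
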