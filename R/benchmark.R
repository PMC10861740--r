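# Cost-based standardized resource use ratios (costSRUR) and standardized
# mortality ratios (SMR) by indirect standardization over SAPS II strata.
#
# The reference ("expected") side is built per calendar year from the
# pooled subgroup across all units: expected resource use per hospital
# survivor in each SAPS II stratum = stratum resource total / stratum
# survivors. A unit's expected cost is the sum over its survivors of their
# stratum rates times the pooled mean cost per resource unit; its observed
# cost is its share of annual direct costs allocated by resource share.
# Multi-year ratios are ratios of sums (sum observed / sum expected), which
# keeps the pooled ratio exactly 1 within every subgroup x measure.

MEASURES <- c("LOS", "TISS")

.resource <- function(adm, measure) {
  switch(measure, LOS = adm$los_days, TISS = adm$tiss_total,
         stop("unknown measure: ", measure))
}

# organ donors retained under the resources-only policy: counted in
# resource totals, never as survivors / deaths / predicted deaths
.donor_masked <- function(cohort) {
  if (identical(attr(cohort, "donor_policy"), "resources_only")) {
    cohort$organ_donor
  } else {
    rep(FALSE, nrow(cohort))
  }
}

#' Convert native-currency costs to PPP-adjusted euros
#'
#' Swiss franc amounts are converted at a fixed rate (default 1.09 CHF per
#' EUR, no inflation adjustment) and all amounts are multiplied by the
#' unit's purchasing power parity factor.
#'
#' @param amount Numeric vector of non-negative native-currency amounts.
#' @param currency \code{"EUR"} or \code{"CHF"} (recycled).
#' @param ppp_factor Positive PPP multiplier (recycled).
#' @param chf_per_eur Fixed CHF/EUR exchange rate.
#' @return Amounts in PPP-adjusted EUR.
#' @examples
#' ppp_adjust(109, "CHF", 1.0)  # 100
#' @export
ppp_adjust <- function(amount, currency, ppp_factor = 1,
                       chf_per_eur = 1.09) {
  if (any(amount < 0)) stop("amount must be non-negative")
  if (!all(currency %in% c("EUR", "CHF"))) {
    stop("unknown currency: ", paste(setdiff(currency, c("EUR", "CHF")),
                                     collapse = ", "))
  }
  if (any(ppp_factor <= 0)) stop("ppp_factor must be positive")
  eur <- ifelse(currency == "CHF", amount / chf_per_eur, amount)
  eur * ppp_factor
}

#' Allocate a unit's direct costs to a subgroup by resource share
#'
#' Direct costs are apportioned in proportion to the subgroup's share of
#' the unit's total length of stay (or TISS points).
#'
#' @param unit_total_cost Unit direct costs (EUR).
#' @param subgroup_resource Subgroup resource total in the unit.
#' @param unit_resource Unit resource total (> 0).
#' @return \code{unit_total_cost * subgroup_resource / unit_resource}.
#' @export
allocate_cost <- function(unit_total_cost, subgroup_resource, unit_resource) {
  if (any(unit_resource <= 0)) {
    stop("degenerate unit-year: unit resource total is zero")
  }
  if (any(subgroup_resource < 0) ||
      any(subgroup_resource > unit_resource + 1e-9)) {
    stop("subgroup resource must lie in [0, unit resource]")
  }
  unit_total_cost * subgroup_resource / unit_resource
}

# group zero-survivor strata with the adjacent lower stratum (leading
# zero-survivor strata merge upward into the first stratum with survivors)
.merge_strata <- function(stratum, survivors) {
  if (all(survivors == 0)) {
    stop("no hospital survivors in the pooled subgroup; expected resource ",
         "use per survivor is undefined")
  }
  grp <- integer(length(stratum))
  running <- 0L
  for (i in order(stratum)) {
    if (survivors[i] > 0) running <- running + 1L
    grp[i] <- running
  }
  grp[grp == 0L] <- 1L
  grp
}

#' Pooled per-stratum expected resource use per survivor
#'
#' Builds the reference table of indirect standardization: for each SAPS II
#' stratum of the pooled subgroup (all units together), the total resource
#' use (LOS days or TISS points) and the number of hospital survivors,
#' giving the expected resource use per survivor as their ratio. Strata
#' without survivors are merged with the adjacent lower stratum (resources
#' and survivors pooled) before division, so no resource use is dropped;
#' organ donors retained under the resources-only policy contribute
#' resources but never survivors.
#'
#' @param pooled Admissions data frame: the pooled subgroup (typically one
#'   calendar year across all units).
#' @param measure \code{"LOS"} or \code{"TISS"}.
#' @return An object of class \code{stratum_table}: data frame with
#'   \code{stratum}, \code{resource}, \code{survivors}, \code{group} (the
#'   merged block) and \code{expected_per_survivor}.
#' @export
stratum_table <- function(pooled, measure = c("LOS", "TISS")) {
  measure <- match.arg(measure)
  if (!nrow(pooled)) stop("empty subgroup")
  res <- .resource(pooled, measure)
  if (any(is.na(res))) stop("missing ", measure, " values in cohort")
  masked <- .donor_masked(pooled)
  surv_flag <- !pooled$died_in_hospital & !masked
  s <- saps_stratum(pooled$saps2)
  strata <- sort(unique(s))
  resource <- as.numeric(tapply(res, factor(s, strata), sum))
  survivors <- as.integer(tapply(surv_flag, factor(s, strata), sum))
  grp <- .merge_strata(strata, survivors)
  g_res <- tapply(resource, grp, sum)
  g_sur <- tapply(survivors, grp, sum)
  eps <- as.numeric((g_res / g_sur)[as.character(grp)])
  out <- data.frame(stratum = strata, resource = resource,
                    survivors = survivors, group = grp,
                    expected_per_survivor = eps)
  structure(out, class = c("stratum_table", "data.frame"),
            measure = measure)
}

#' @export
print.stratum_table <- function(x, ...) {
  cat("Expected", attr(x, "measure"),
      "per hospital survivor by SAPS II stratum\n")
  y <- as.data.frame(x)
  y$stratum <- saps_stratum_labels()[y$stratum + 1]
  print(y, row.names = FALSE)
  invisible(x)
}

# PPP-adjusted annual direct costs per unit-year, as a lookup table
.adjusted_costs <- function(profiles, chf_per_eur = 1.09) {
  cc <- merge(profiles$costs, profiles$units[c("unit_id", "currency",
                                               "ppp_factor")],
              by = "unit_id")
  cc$eur <- ppp_adjust(cc$amount, cc$currency, cc$ppp_factor, chf_per_eur)
  cc
}

# observed (allocated) subgroup cost per unit for one calendar year;
# denominators are the unit's total resource over all admissions in the
# allocation base (rows with a missing resource value contribute nothing)
.observed_costs_year <- function(base_y, sub_y, costs_y, measure) {
  unit_res <- tapply(.resource(base_y, measure), base_y$unit_id,
                     sum, na.rm = TRUE)
  sub_res <- tapply(.resource(sub_y, measure), sub_y$unit_id, sum)
  units <- names(unit_res)
  sr <- ifelse(units %in% names(sub_res), sub_res[units], 0)
  total <- costs_y$eur[match(units, costs_y$unit_id)]
  if (any(is.na(total))) {
    stop("missing annual cost for unit(s): ",
         paste(units[is.na(total)], collapse = ", "))
  }
  data.frame(unit_id = units,
             observed_cost = allocate_cost(total, sr, as.numeric(unit_res)),
             observed_resource = as.numeric(sr),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cost-based standardized resource use ratio per unit
#'
#' For one subgroup and one resource measure, computes each unit's
#' observed and expected PPP-adjusted direct costs and their ratio
#' (costSRUR). Observed costs are the unit's annual direct costs allocated
#' to the subgroup by the subgroup's share of the unit's cohort resource
#' use. Expected costs are the unit's survivors, stratum by stratum, times
#' the pooled expected resource use per survivor, times the pooled mean
#' cost per resource unit (subgroup allocated costs over all units divided
#' by subgroup resource total). Stratification and reference construction
#' are done per calendar year; a unit's multi-year ratio is the ratio of
#' its summed observed to summed expected costs.
#'
#' @param cohort Filtered admissions (see \code{\link{apply_exclusions}}).
#' @param profiles A \code{unit_profiles} object.
#' @param subgroup Subgroup label (see \code{\link{subgroup_labels}}).
#' @param measure \code{"LOS"} or \code{"TISS"}.
#' @param chf_per_eur Fixed CHF/EUR exchange rate.
#' @param allocation_base Admissions supplying the denominator of the cost
#'   allocation: the unit's total resource use. Defaults to \code{cohort};
#'   pass the full validated registry so that direct costs are first
#'   attributed to the analysis cohort as its share of the ICU's total
#'   activity (the unit totals then include excluded admissions).
#' @return Data frame, one row per unit: observed/expected cost and
#'   resource totals, \code{cost_srur}, and \code{srur_defined} (FALSE when
#'   the expected cost is zero, in which case \code{cost_srur} is NA rather
#'   than an infinity).
#' @export
compute_cost_srur <- function(cohort, profiles, subgroup = "ALL",
                              measure = c("LOS", "TISS"),
                              chf_per_eur = 1.09,
                              allocation_base = cohort) {
  measure <- match.arg(measure)
  check_profile_coverage(profiles, cohort)
  sub <- subgroup_filter(cohort, subgroup)
  units <- sort(unique(cohort$unit_id))
  acc <- data.frame(unit_id = units, observed_cost = 0, expected_cost = 0,
                    observed_resource = 0, stringsAsFactors = FALSE)
  costs <- .adjusted_costs(profiles, chf_per_eur)
  for (y in sort(unique(cohort$year))) {
    base_y <- allocation_base[allocation_base$year == y, , drop = FALSE]
    sub_y <- sub[sub$year == y, , drop = FALSE]
    attr(sub_y, "donor_policy") <- attr(cohort, "donor_policy")
    if (!nrow(sub_y)) next
    obs <- .observed_costs_year(base_y, sub_y, costs[costs$year == y, ],
                                measure)
    obs <- obs[obs$unit_id %in% units, , drop = FALSE]
    tab <- stratum_table(sub_y, measure)
    mean_cost <- sum(obs$observed_cost) / sum(.resource(sub_y, measure))
    masked <- .donor_masked(sub_y)
    surv <- sub_y[!sub_y$died_in_hospital & !masked, , drop = FALSE]
    eps <- tab$expected_per_survivor[match(saps_stratum(surv$saps2),
                                           tab$stratum)]
    exp_cost <- tapply(eps * mean_cost, factor(surv$unit_id, units), sum)
    exp_cost[is.na(exp_cost)] <- 0
    i <- match(obs$unit_id, acc$unit_id)
    acc$observed_cost[i] <- acc$observed_cost[i] + obs$observed_cost
    acc$observed_resource[i] <- acc$observed_resource[i] +
      obs$observed_resource
    acc$expected_cost <- acc$expected_cost + as.numeric(exp_cost)
  }
  acc$srur_defined <- acc$expected_cost > 0
  acc$cost_srur <- ifelse(acc$srur_defined,
                          acc$observed_cost / acc$expected_cost, NA_real_)
  acc$subgroup <- subgroup
  acc$measure <- measure
  acc
}

#' Standardized mortality ratio per unit
#'
#' Observed hospital deaths divided by the sum of model-predicted death
#' probabilities, per unit, for one subgroup. Organ donors retained under
#' the resources-only policy contribute neither deaths nor predictions.
#'
#' @param cohort Filtered admissions.
#' @param subgroup Subgroup label.
#' @param model A \code{\link{risk_model}}.
#' @return Data frame, one row per unit: \code{n_admissions},
#'   \code{n_survivors}, \code{observed_deaths}, \code{expected_deaths},
#'   \code{smr} and \code{smr_defined} (FALSE when expected deaths are 0).
#' @export
compute_smr <- function(cohort, subgroup = "ALL",
                        model = saps2_risk_model()) {
  sub <- subgroup_filter(cohort, subgroup)
  units <- sort(unique(cohort$unit_id))
  masked <- .donor_masked(sub)
  out <- data.frame(unit_id = units, stringsAsFactors = FALSE)
  f <- factor(sub$unit_id, units)
  cnt <- function(x) {
    v <- tapply(x, f, sum)
    ifelse(is.na(v), 0, as.numeric(v))
  }
  out$n_admissions <- cnt(rep(1, nrow(sub)))
  out$n_survivors <- cnt(!sub$died_in_hospital & !masked)
  out$observed_deaths <- cnt(sub$died_in_hospital & !masked)
  p <- predict(model, sub)
  out$expected_deaths <- cnt(p * !masked)
  out$smr_defined <- out$expected_deaths > 0
  out$smr <- ifelse(out$smr_defined,
                    out$observed_deaths / out$expected_deaths, NA_real_)
  out$subgroup <- subgroup
  out
}

#' Severity-adjusted benchmarking of ICU resource use and mortality
#'
#' The main fitting function: applies the exclusion cascade under each
#' requested organ-donor policy, then computes per unit and subgroup the
#' cost-based standardized resource use ratios (costSRUR, with direct
#' costs separated by LOS share and/or TISS share) and the standardized
#' mortality ratio (SMR) under the supplied risk model. Ratios use
#' indirect standardization over SAPS II strata built from the pooled
#' cohort, per calendar year (see \code{\link{compute_cost_srur}}).
#'
#' @param admissions Validated admissions data frame (raw registry rows;
#'   the exclusion cascade is applied internally).
#' @param profiles A \code{\link{unit_profiles}} object covering every
#'   unit-year.
#' @param subgroups Character vector of subgroup labels to benchmark.
#' @param measures Resource measures: \code{"LOS"}, \code{"TISS"} or both.
#' @param donor_policies Organ-donor policies to run side by side;
#'   \code{"exclude"} is the primary analysis, \code{"resources_only"} and
#'   \code{"include"} the sensitivity variants.
#' @param risk_model A \code{\link{risk_model}} for expected mortality.
#' @param chf_per_eur Fixed CHF/EUR exchange rate.
#' @return An object of class \code{icu_benchmark}: list with
#'   \code{results} (one row per unit x subgroup x measure x donor policy,
#'   with observed/expected costs and deaths, \code{cost_srur},
#'   \code{smr}, counts and defined-flags), \code{exclusions} (the
#'   exclusion log per policy), \code{risk_model} and \code{call}. Cells
#'   whose subgroup is empty for a unit are reported with zero counts and
#'   NA ratios; the run continues.
#' @seealso \code{\link{summary.icu_benchmark}},
#'   \code{\link{plot.icu_benchmark}}, \code{\link{run_association_suite}}
#' @examples
#' reg <- simulate_registry(registry_config(n_units = 3,
#'   admissions_per_unit_year = 300, years = 2015), seed = 1)
#' bm <- icu_benchmark(reg$admissions, reg$profiles,
#'                     subgroups = c("ALL", "NEURO_ALL"))
#' bm
#' @export
icu_benchmark <- function(admissions, profiles,
                          subgroups = c(diagnosis_groups(), "NEURO_ALL",
                                        "NON_NEURO", "ALL"),
                          measures = c("LOS", "TISS"),
                          donor_policies = "exclude",
                          risk_model = saps2_risk_model(),
                          chf_per_eur = 1.09) {
  stopifnot(inherits(profiles, "unit_profiles"),
            inherits(risk_model, "risk_model"))
  measures <- match.arg(measures, MEASURES, several.ok = TRUE)
  donor_policies <- match.arg(donor_policies,
                              c("exclude", "resources_only", "include"),
                              several.ok = TRUE)
  bad <- setdiff(subgroups, SUBGROUP_LABELS)
  if (length(bad)) stop("unknown subgroup(s): ", paste(bad, collapse = ", "))

  rows <- list()
  logs <- list()
  base <- admissions  # allocation denominators: the ICU's total activity
  for (pol in donor_policies) {
    filt <- apply_exclusions(admissions, pol)
    logs[[pol]] <- filt$log
    cohort <- filt$cohort
    if (!nrow(cohort)) stop("no admissions remain after exclusions")
    for (g in subgroups) {
      smr <- tryCatch(compute_smr(cohort, g, risk_model),
                      error = function(e) {
                        stop("SMR for subgroup ", g, " [", pol, "]: ",
                             conditionMessage(e), call. = FALSE)
                      })
      for (m in measures) {
        cs <- tryCatch(compute_cost_srur(cohort, profiles, g, m, chf_per_eur,
                                         allocation_base = base),
                       error = function(e) {
                         stop("costSRUR for subgroup ", g, " [", pol, "/", m,
                              "]: ", conditionMessage(e), call. = FALSE)
                       })
        merged <- merge(cs[c("unit_id", "observed_cost", "expected_cost",
                             "observed_resource", "cost_srur",
                             "srur_defined")],
                        smr[c("unit_id", "n_admissions", "n_survivors",
                              "observed_deaths", "expected_deaths", "smr",
                              "smr_defined")],
                        by = "unit_id")
        merged$subgroup <- g
        merged$measure <- m
        merged$donor_policy <- pol
        rows[[length(rows) + 1]] <- merged
      }
    }
  }
  results <- do.call(rbind, rows)
  front <- c("unit_id", "subgroup", "measure", "donor_policy")
  results <- results[c(front, setdiff(names(results), front))]
  rownames(results) <- NULL
  structure(list(results = results, exclusions = logs,
                 risk_model = risk_model$name,
                 subgroups = subgroups, measures = measures,
                 donor_policies = donor_policies,
                 chf_per_eur = chf_per_eur, call = match.call()),
            class = "icu_benchmark")
}

#' @export
print.icu_benchmark <- function(x, digits = 3, ...) {
  r <- x$results
  cat("Severity-adjusted ICU benchmark (risk model:", x$risk_model, ")\n")
  cat(sprintf("  %d unit(s), %d subgroup(s), measures: %s, donor policies: %s\n",
              length(unique(r$unit_id)), length(unique(r$subgroup)),
              paste(x$measures, collapse = "/"),
              paste(x$donor_policies, collapse = "/")))
  prim <- r[r$donor_policy == x$donor_policies[1], ]
  show <- prim[c("unit_id", "subgroup", "measure", "n_admissions",
                 "cost_srur", "smr")]
  show$cost_srur <- round(show$cost_srur, digits)
  show$smr <- round(show$smr, digits)
  print(utils::head(show, 20), row.names = FALSE)
  if (nrow(show) > 20) cat("  ...", nrow(show) - 20, "more row(s)\n")
  invisible(x)
}

#' Per-subgroup cost summary of a benchmark
#'
#' Descriptive cost quantities per subgroup and cost-separation scheme:
#' total allocated direct costs (PPP-adjusted EUR), mean cost per
#' admission, cost per LOS day / per TISS point, and the subgroup's share
#' of the direct costs of the whole benchmarked cohort. Shares are
#' computed against the \code{ALL} subgroup when present, otherwise
#' against the sum over the five diagnosis groups.
#'
#' @param object An \code{icu_benchmark}.
#' @param donor_policy Which policy's results to summarize.
#' @param ... Unused.
#' @return Object of class \code{summary.icu_benchmark}: a data frame with
#'   one row per subgroup x measure.
#' @export
summary.icu_benchmark <- function(object,
                                  donor_policy = object$donor_policies[1],
                                  ...) {
  r <- object$results
  r <- r[r$donor_policy == donor_policy, ]
  out <- list()
  for (m in unique(r$measure)) {
    rm_ <- r[r$measure == m, ]
    tot_all <- if ("ALL" %in% rm_$subgroup) {
      sum(rm_$observed_cost[rm_$subgroup == "ALL"])
    } else {
      sum(rm_$observed_cost[rm_$subgroup %in% DIAGNOSIS_GROUPS])
    }
    for (g in unique(rm_$subgroup)) {
      rg <- rm_[rm_$subgroup == g, ]
      tot <- sum(rg$observed_cost)
      n <- sum(rg$n_admissions)
      out[[length(out) + 1]] <- data.frame(
        subgroup = g, measure = m, n_admissions = n,
        total_cost_eur = tot,
        mean_cost_per_admission = if (n > 0) tot / n else NA_real_,
        cost_per_resource_unit = if (sum(rg$observed_resource) > 0)
          tot / sum(rg$observed_resource) else NA_real_,
        cost_share = if (tot_all > 0) tot / tot_all else NA_real_,
        pooled_cost_srur = sum(rg$observed_cost) / sum(rg$expected_cost),
        pooled_smr = sum(rg$observed_deaths) / sum(rg$expected_deaths),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("summary.icu_benchmark", "data.frame"),
            donor_policy = donor_policy)
}

#' @export
print.summary.icu_benchmark <- function(x, ...) {
  cat("Cost summary by subgroup (donor policy:",
      attr(x, "donor_policy"), ")\n")
  y <- as.data.frame(x)
  y$total_cost_eur <- round(y$total_cost_eur)
  y$mean_cost_per_admission <- round(y$mean_cost_per_admission)
  y$cost_per_resource_unit <- round(y$cost_per_resource_unit, 1)
  y$cost_share <- sprintf("%s%%", fmt_pct(y$cost_share * 100))
  y$pooled_cost_srur <- round(y$pooled_cost_srur, 3)
  y$pooled_smr <- round(y$pooled_smr, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Plot costSRUR against SMR per unit
#'
#' Scatter of each unit's cost-based standardized resource use ratio
#' against its standardized mortality ratio for one subgroup and measure,
#' with reference lines at 1 and an ordinary least squares trend
#' (descriptive overlay only; formal unit-factor estimates come from
#' \code{\link{run_association_suite}}).
#'
#' @param x An \code{icu_benchmark}.
#' @param subgroup Subgroup to plot.
#' @param measure Cost-separation measure.
#' @param donor_policy Donor policy.
#' @param ... Passed to \code{plot}.
#' @export
plot.icu_benchmark <- function(x, subgroup = "ALL", measure = "LOS",
                               donor_policy = x$donor_policies[1], ...) {
  r <- x$results
  r <- r[r$subgroup == subgroup & r$measure == measure &
           r$donor_policy == donor_policy & r$srur_defined & r$smr_defined, ]
  if (!nrow(r)) stop("nothing to plot for this cell")
  plot(r$smr, r$cost_srur, pch = 19,
       cex = 0.6 + 1.6 * sqrt(r$n_admissions / max(r$n_admissions)),
       xlab = "SMR", ylab = paste0("costSRUR_", measure),
       main = paste("Subgroup", subgroup), ...)
  graphics::abline(h = 1, v = 1, lty = 3)
  if (nrow(r) >= 3) {
    graphics::abline(stats::lm(cost_srur ~ smr, data = r), lty = 2)
  }
  graphics::text(r$smr, r$cost_srur, r$unit_id, pos = 3, cex = 0.7)
  invisible(x)
}
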