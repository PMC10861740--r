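# Bivariable gamma regression of unit-level structural factors against the
# benchmarking ratios. One exposure at a time plus an intercept, gamma
# family with log link, so exponentiated coefficients are relative risks
# (multiplicative effects on the ratio). Continuous exposures are
# standardized to mean 0, SD 1 before fitting; effects are per 1 SD.

UNIT_EXPOSURES <- c("beds", "fte_physicians_per_bed", "independent_org",
                    "median_saps2", "smr")
ASSOC_OUTCOMES <- c("cost_srur_LOS", "cost_srur_TISS", "smr")

#' Standardize a continuous exposure
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), so regression coefficients are per 1 SD increase.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return The standardized vector.
#' @export
standardize <- function(x) {
  if (any(is.na(x))) stop("missing values in exposure")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Fit one bivariable gamma model
#'
#' Regresses a strictly positive unit-level outcome (a costSRUR or SMR) on
#' a single exposure with a gamma GLM and logarithmic link. The relative
#' risk is the exponentiated exposure coefficient; 95% confidence bounds
#' are Wald intervals on the linear predictor scale, exponentiated, with
#' the gamma dispersion estimated by the Pearson estimator.
#'
#' @param data Data frame of unit-level rows.
#' @param outcome Name of the outcome column (strictly positive).
#' @param exposure Name of the exposure column. Continuous exposures are
#'   standardized internally (logical/binary ones are not).
#' @return One-row data frame: \code{outcome}, \code{exposure},
#'   \code{rr}, \code{ci_low}, \code{ci_high}, \code{n_units},
#'   \code{converged}. Non-convergence or an unestimable standard error is
#'   flagged (\code{converged = FALSE}, NA interval), never silently
#'   reported as an estimate.
#' @export
fit_bivariable_gamma <- function(data, outcome, exposure) {
  d <- data[stats::complete.cases(data[c(outcome, exposure)]), , drop = FALSE]
  n <- nrow(d)
  empty <- data.frame(outcome = outcome, exposure = exposure, rr = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, n_units = n,
                      converged = FALSE, stringsAsFactors = FALSE)
  if (n < 3) return(empty)
  y <- d[[outcome]]
  if (any(y <= 0)) stop("outcome '", outcome, "' must be strictly positive")
  x <- d[[exposure]]
  if (is.logical(x)) {
    x <- as.numeric(x)
    if (length(unique(x)) < 2) return(empty)
  } else {
    if (length(unique(x)) < 2) return(empty)
    x <- standardize(x)
  }
  fit <- tryCatch(
    stats::glm(y ~ x, family = stats::Gamma(link = "log")),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !fit$converged) return(empty)
  sm <- summary(fit)  # Gamma dispersion: Pearson chi-square / df
  if (!"x" %in% rownames(sm$coefficients)) return(empty)
  est <- sm$coefficients["x", "Estimate"]
  se <- sm$coefficients["x", "Std. Error"]
  if (!is.finite(se) || se <= 0) return(empty)
  z <- stats::qnorm(0.975)
  data.frame(outcome = outcome, exposure = exposure, rr = exp(est),
             ci_low = exp(est - z * se), ci_high = exp(est + z * se),
             n_units = n, converged = TRUE, stringsAsFactors = FALSE)
}

#' Unit-level factor table for one subgroup
#'
#' Joins the structural unit factors (beds, FTE physicians per bed,
#' organization type) with the per-unit median SAPS II of the subgroup
#' cohort and the unit's benchmarking ratios, giving the rows the
#' bivariable models are fitted on.
#'
#' @param benchmark An \code{\link{icu_benchmark}} whose subgroups include
#'   \code{subgroup}.
#' @param profiles A \code{unit_profiles} object.
#' @param cohort The filtered cohort the benchmark was computed on (used
#'   for per-unit median SAPS II).
#' @param subgroup Subgroup label.
#' @param donor_policy Donor policy to extract.
#' @return Data frame, one row per unit: exposures plus
#'   \code{cost_srur_LOS}, \code{cost_srur_TISS}, \code{smr} (NA where
#'   undefined).
#' @export
unit_factor_table <- function(benchmark, profiles, cohort, subgroup,
                              donor_policy = benchmark$donor_policies[1]) {
  r <- benchmark$results
  r <- r[r$subgroup == subgroup & r$donor_policy == donor_policy, ]
  if (!nrow(r)) stop("subgroup not present in benchmark: ", subgroup)
  sub <- subgroup_filter(cohort, subgroup)
  med <- tapply(sub$saps2, sub$unit_id, stats::median)
  out <- profiles$units[c("unit_id", "beds", "fte_physicians_per_bed",
                          "independent_org")]
  out$median_saps2 <- as.numeric(med[out$unit_id])
  smr_rows <- r[!duplicated(r$unit_id), ]
  out$smr <- ifelse(smr_rows$smr_defined, smr_rows$smr,
                    NA_real_)[match(out$unit_id, smr_rows$unit_id)]
  for (m in intersect(c("LOS", "TISS"), unique(r$measure))) {
    rm_ <- r[r$measure == m, ]
    out[[paste0("cost_srur_", m)]] <-
      ifelse(rm_$srur_defined, rm_$cost_srur,
             NA_real_)[match(out$unit_id, rm_$unit_id)]
  }
  rownames(out) <- NULL
  out
}

#' Bivariable association suite across subgroups
#'
#' Fits, for each diagnosis subgroup (the four neurosurgical groups, the
#' non-neurosurgical group and the combined neurosurgical group), every
#' a-priori unit factor (beds, FTE physicians-to-bed ratio, independent
#' organization, median SAPS II, SMR) against costSRUR_LOS, costSRUR_TISS
#' and SMR with bivariable gamma models. SMR is used as an exposure for
#' the costSRUR outcomes only. Units with an undefined outcome in a cell
#' are dropped from that fit and the remaining count reported; no estimate
#' is emitted on fewer than 3 usable units. With few units (the realistic
#' registry scale is 6) estimates are fragile; a warning is attached.
#'
#' @param benchmark An \code{\link{icu_benchmark}} covering the subgroups.
#' @param profiles A \code{unit_profiles} object.
#' @param cohort The filtered cohort (for per-unit median SAPS II).
#' @param subgroups Subgroups to analyse.
#' @param donor_policy Donor policy to analyse.
#' @return Object of class \code{srur_association}: data frame with one
#'   row per subgroup x outcome x exposure.
#' @export
run_association_suite <- function(benchmark, profiles, cohort,
                                  subgroups = c(diagnosis_groups()[1:4],
                                                "NON_NEURO", "NEURO_ALL"),
                                  donor_policy =
                                    benchmark$donor_policies[1]) {
  rows <- list()
  for (g in subgroups) {
    tab <- unit_factor_table(benchmark, profiles, cohort, g, donor_policy)
    for (oc in intersect(ASSOC_OUTCOMES, names(tab))) {
      # units with an undefined or zero ratio cannot enter a gamma fit;
      # they are dropped from this cell and n_units records the remainder
      tab_oc <- tab
      tab_oc[[oc]][!is.na(tab_oc[[oc]]) & tab_oc[[oc]] <= 0] <- NA
      exps <- setdiff(UNIT_EXPOSURES, if (oc == "smr") "smr" else character())
      for (ex in exps) {
        est <- fit_bivariable_gamma(tab_oc, oc, ex)
        est$subgroup <- g
        rows[[length(rows) + 1]] <- est
      }
    }
  }
  res <- do.call(rbind, rows)
  res <- res[c("subgroup", "outcome", "exposure", "rr", "ci_low", "ci_high",
               "n_units", "converged")]
  rownames(res) <- NULL
  if (any(res$n_units < 10 & res$converged)) {
    warning("associations estimated on fewer than 10 units; ",
            "interpret with caution", call. = FALSE)
  }
  structure(res, class = c("srur_association", "data.frame"),
            donor_policy = donor_policy)
}

#' @export
print.srur_association <- function(x, digits = 3, ...) {
  cat("Bivariable gamma associations (RR per 1 SD / vs reference level)\n")
  y <- as.data.frame(x)
  for (v in c("rr", "ci_low", "ci_high")) y[[v]] <- round(y[[v]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Descriptive linear trend of costSRUR against SMR
#'
#' Ordinary Gaussian least-squares slope of a unit-level costSRUR on SMR
#' for one subgroup — the descriptive overlay used in scatter displays,
#' distinct from the gamma-model relative risks of
#' \code{\link{run_association_suite}}.
#'
#' @param benchmark An \code{\link{icu_benchmark}}.
#' @param subgroup Subgroup label.
#' @param measure \code{"LOS"} or \code{"TISS"}.
#' @param donor_policy Donor policy.
#' @return One-row data frame: \code{slope}, \code{ci_low},
#'   \code{ci_high}, \code{n_units}.
#' @export
srur_smr_trend <- function(benchmark, subgroup, measure = "LOS",
                           donor_policy = benchmark$donor_policies[1]) {
  r <- benchmark$results
  r <- r[r$subgroup == subgroup & r$measure == measure &
           r$donor_policy == donor_policy & r$srur_defined & r$smr_defined, ]
  if (nrow(r) < 3) {
    return(data.frame(subgroup = subgroup, measure = measure,
                      slope = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n_units = nrow(r)))
  }
  fit <- stats::lm(cost_srur ~ smr, data = r)
  ci <- stats::confint(fit)["smr", ]
  data.frame(subgroup = subgroup, measure = measure,
             slope = unname(stats::coef(fit)["smr"]),
             ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             n_units = nrow(r))
}
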