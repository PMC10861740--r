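# Hand-built micro-cohorts and profile builders used across the tests.

# a minimal valid admission row; override any field via ...
adm_row <- function(id, unit = "A", year = 2015, group = "OTHER",
                    saps2 = 30, los = 2, tiss = 60, died = FALSE, ...) {
  out <- data.frame(
    admission_id = id, unit_id = unit, year = year,
    diagnosis_group = group, admission_type = "EMERGENCY",
    saps2 = saps2, gcs = 13L, age = 60, sex = "M", operative = FALSE,
    premorbid_status = "NORMAL", los_days = los, tiss_total = tiss,
    died_in_hospital = died, organ_donor = FALSE, readmission = FALSE,
    icu_transfer_in = FALSE, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

make_cohort <- function(...) {
  rows <- list(...)
  co <- validate_admissions(do.call(rbind, rows))
  attr(co, "donor_policy") <- "exclude"
  co
}

# flat profiles: every unit-year gets the same cost unless a named vector
make_profiles <- function(unit_ids, years, amount = 1e6, currency = "EUR",
                          ppp = 1) {
  units <- data.frame(unit_id = unit_ids, beds = 25L,
                      fte_physicians_per_bed = 0.3,
                      independent_org = rep_len(c(TRUE, FALSE),
                                                length(unit_ids)),
                      currency = rep_len(currency, length(unit_ids)),
                      ppp_factor = rep_len(ppp, length(unit_ids)),
                      stringsAsFactors = FALSE)
  costs <- expand.grid(unit_id = unit_ids, year = years,
                       stringsAsFactors = FALSE)
  costs$amount <- if (length(amount) == length(unit_ids)) {
    amount[match(costs$unit_id, unit_ids)]
  } else {
    amount
  }
  unit_profiles(units, costs)
}

# random small single-year cohort exercising sparse strata and donors
random_cohort <- function(n, n_units = 3, seed) {
  set.seed(seed)
  units <- paste0("U", seq_len(n_units))
  co <- do.call(rbind, lapply(seq_len(n), function(i) {
    adm_row(sprintf("r%03d", i), unit = sample(units, 1),
            group = sample(diagnosis_groups(), 1),
            saps2 = sample(0:99, 1),
            los = round(stats::rlnorm(1, 0.5, 1), 1) + 0.1,
            tiss = round(stats::rlnorm(1, 3.5, 0.8)),
            died = stats::runif(1) < 0.3,
            organ_donor = stats::runif(1) < 0.05)
  }))
  co <- validate_admissions(co)
  attr(co, "donor_policy") <- "exclude"
  co
}

# Independent brute-force reference for expected subgroup costs: plain
# loops over admissions and strata, with its own zero-survivor merging.
brute_force_expected <- function(cohort, observed_by_unit, measure,
                                 resources_only_donors = FALSE) {
  res <- if (measure == "LOS") cohort$los_days else cohort$tiss_total
  strat <- ifelse(cohort$saps2 >= 90, 9, cohort$saps2 %/% 10)
  masked <- if (resources_only_donors) cohort$organ_donor else
    rep(FALSE, nrow(cohort))
  surv <- !cohort$died_in_hospital & !masked
  present <- sort(unique(strat))
  r_tot <- s_tot <- numeric(length(present))
  for (k in seq_along(present)) {
    for (i in seq_len(nrow(cohort))) {
      if (strat[i] == present[k]) {
        r_tot[k] <- r_tot[k] + res[i]
        s_tot[k] <- s_tot[k] + as.numeric(surv[i])
      }
    }
  }
  # merge zero-survivor strata downward; leading block merges upward
  grp <- integer(length(present))
  g <- 0
  for (k in seq_along(present)) {
    if (s_tot[k] > 0) g <- g + 1
    grp[k] <- g
  }
  grp[grp == 0] <- 1
  eps <- numeric(length(present))
  for (k in seq_along(present)) {
    eps[k] <- sum(r_tot[grp == grp[k]]) / sum(s_tot[grp == grp[k]])
  }
  mean_cost <- sum(observed_by_unit) / sum(res)
  units <- sort(unique(cohort$unit_id))
  expected <- setNames(numeric(length(units)), units)
  for (i in seq_len(nrow(cohort))) {
    if (surv[i]) {
      k <- which(present == strat[i])
      expected[cohort$unit_id[i]] <- expected[cohort$unit_id[i]] +
        eps[k] * mean_cost
    }
  }
  expected
}
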