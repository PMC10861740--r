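test_that("currency and PPP adjustment follow the fixed-rate rule", {
  expect_equal(ppp_adjust(109, "CHF", 1.0), 100)
  expect_equal(ppp_adjust(100, "EUR", 1.0), 100)
  expect_equal(ppp_adjust(100, "EUR", 0.9), 90)
  expect_equal(ppp_adjust(218, "CHF", 0.5), 100)
  expect_error(ppp_adjust(10, "USD"), "currency")
  expect_error(ppp_adjust(-1, "EUR"), "non-negative")
})

test_that("cost allocation is proportional to resource share", {
  expect_equal(allocate_cost(1e6, 25, 100), 250000)
  expect_equal(allocate_cost(5e5, 80, 80), 5e5)
  expect_equal(allocate_cost(5e5, 0, 80), 0)
  expect_error(allocate_cost(1e6, 1, 0), "degenerate")
  expect_error(allocate_cost(1e6, 120, 100), "subgroup resource")
})

test_that("stratum table divides pooled resource by pooled survivors", {
  co <- make_cohort(
    adm_row("1", saps2 = 5, los = 10), adm_row("2", saps2 = 8, los = 12),
    adm_row("3", saps2 = 3, los = 8, died = TRUE),
    adm_row("4", saps2 = 22, los = 20), adm_row("5", saps2 = 25, los = 4))
  tab <- stratum_table(co, "LOS")
  expect_equal(tab$expected_per_survivor[tab$stratum == 0], 30 / 2)
  expect_equal(tab$expected_per_survivor[tab$stratum == 2], 24 / 2)
  expect_equal(sum(tab$resource), sum(co$los_days))
})

test_that("zero-survivor strata merge downward before division", {
  co <- make_cohort(
    adm_row("1", saps2 = 85, tiss = 44), adm_row("2", saps2 = 88, tiss = 44),
    adm_row("3", saps2 = 95, tiss = 12, died = TRUE))
  tab <- stratum_table(co, "TISS")
  # stratum 9 (no survivors) pools with stratum 8: (12 + 88) / 2 survivors
  expect_equal(tab$expected_per_survivor, c(50, 50))
  expect_equal(tab$group, c(1, 1))
  # leading zero-survivor stratum merges upward instead
  co2 <- make_cohort(
    adm_row("1", saps2 = 5, tiss = 12, died = TRUE),
    adm_row("2", saps2 = 15, tiss = 88), adm_row("3", saps2 = 12, tiss = 10))
  tab2 <- stratum_table(co2, "TISS")
  expect_equal(tab2$expected_per_survivor, c(55, 55))
  expect_error(stratum_table(make_cohort(adm_row("1", died = TRUE)), "LOS"),
               "undefined")
})

test_that("a single-unit dataset has costSRUR exactly 1", {
  co <- make_cohort(adm_row("1", saps2 = 10), adm_row("2", saps2 = 35),
                    adm_row("3", saps2 = 35, died = TRUE),
                    adm_row("4", saps2 = 60))
  prof <- make_profiles("A", 2015)
  for (m in c("LOS", "TISS")) {
    r <- compute_cost_srur(co, prof, "ALL", m)
    expect_equal(r$cost_srur, 1, tolerance = 1e-12)
  }
})

test_that("observed and expected costs conserve within each subgroup", {
  reg <- simulate_registry(registry_config(n_units = 4, years = 2015:2016,
                                           admissions_per_unit_year = 400),
                           seed = 11)
  co <- apply_exclusions(reg$admissions)$cohort
  for (g in c("ALL", "NEURO_ALL", "SAH")) {
    for (m in c("LOS", "TISS")) {
      r <- compute_cost_srur(co, reg$profiles, g, m,
                             allocation_base = reg$admissions)
      expect_equal(sum(r$observed_cost), sum(r$expected_cost),
                   tolerance = 1e-9)
      # expected-cost-weighted mean of the ratios is exactly 1
      expect_equal(sum(r$cost_srur * r$expected_cost) / sum(r$expected_cost),
                   1, tolerance = 1e-9)
    }
  }
})

test_that("costSRUR is invariant to a common cost rescaling", {
  reg <- simulate_registry(registry_config(n_units = 3, years = 2015,
                                           admissions_per_unit_year = 300),
                           seed = 5)
  co <- apply_exclusions(reg$admissions)$cohort
  r1 <- compute_cost_srur(co, reg$profiles, "NEURO_ALL", "LOS")
  scaled <- reg$profiles
  scaled$costs$amount <- scaled$costs$amount * 7.3
  r2 <- compute_cost_srur(co, scaled, "NEURO_ALL", "LOS")
  expect_equal(r1$cost_srur, r2$cost_srur, tolerance = 1e-12)
})

test_that("expected costs equal the brute-force reference on small cohorts", {
  for (seed in 1:30) {
    co <- random_cohort(sample(20:200, 1), seed = seed)
    co <- apply_exclusions(co, "exclude")$cohort
    if (!any(!co$died_in_hospital)) next
    prof <- make_profiles(sort(unique(co$unit_id)), 2015,
                          amount = 1e6 + 1e5 * seq_along(unique(co$unit_id)))
    m <- if (seed %% 2) "LOS" else "TISS"
    r <- compute_cost_srur(co, prof, "ALL", m)
    oracle <- brute_force_expected(
      co, setNames(r$observed_cost, r$unit_id), m)
    expect_equal(r$expected_cost, unname(oracle[r$unit_id]),
                 tolerance = 1e-9)
  }
})

test_that("proportional TISS and LOS give identical costSRURs", {
  cfg <- registry_config(n_units = 4, years = 2015,
                         admissions_per_unit_year = 500,
                         missing_tiss_fraction = 0)
  reg <- simulate_registry(cfg, seed = 2)
  reg$admissions$tiss_total <- reg$admissions$los_days * 31.7
  bm <- icu_benchmark(reg$admissions, reg$profiles,
                      subgroups = c("ALL", "SAH"))
  r <- bm$results
  for (g in unique(r$subgroup)) {
    los <- r[r$subgroup == g & r$measure == "LOS", ]
    tis <- r[r$subgroup == g & r$measure == "TISS", ]
    expect_equal(los$cost_srur, tis$cost_srur[match(los$unit_id,
                                                    tis$unit_id)],
                 tolerance = 1e-9)
  }
})

test_that("SMR is observed over model-predicted deaths per unit", {
  co <- make_cohort(
    adm_row("1", unit = "A", saps2 = 40, died = TRUE),
    adm_row("2", unit = "A", saps2 = 40),
    adm_row("3", unit = "B", saps2 = 40),
    adm_row("4", unit = "B", saps2 = 40))
  m <- risk_model("flat25", function(adm) rep(0.25, nrow(adm)))
  r <- compute_smr(co, "ALL", m)
  expect_equal(r$smr[r$unit_id == "A"], 1 / 0.5)
  expect_equal(r$smr[r$unit_id == "B"], 0)
  # pooled SMR = 1 under the empirical stratum model
  emp <- empirical_stratum_risk(co)
  re <- compute_smr(co, "ALL", emp)
  expect_equal(sum(re$observed_deaths) / sum(re$expected_deaths), 1,
               tolerance = 1e-9)
})

test_that("donor policies shift resources but never survivors", {
  # donors concentrated in unit A consume resources there
  rows <- c(
    lapply(1:8, function(i) adm_row(paste0("a", i), unit = "A",
                                    saps2 = 30 + i, los = 2, tiss = 60)),
    lapply(1:8, function(i) adm_row(paste0("b", i), unit = "B",
                                    saps2 = 30 + i, los = 2, tiss = 60)),
    list(adm_row("don1", unit = "A", saps2 = 70, los = 3, tiss = 90,
                 died = TRUE, organ_donor = TRUE),
         adm_row("don2", unit = "A", saps2 = 75, los = 3, tiss = 90,
                 died = TRUE, organ_donor = TRUE)))
  adm <- validate_admissions(do.call(rbind, rows))
  prof <- make_profiles(c("A", "B"), 2015)
  bm <- icu_benchmark(adm, prof, subgroups = "ALL",
                      donor_policies = c("exclude", "resources_only",
                                         "include"))
  r <- bm$results[bm$results$measure == "LOS" & bm$results$unit_id == "A", ]
  ex <- r[r$donor_policy == "exclude", ]
  ro <- r[r$donor_policy == "resources_only", ]
  expect_gte(ro$cost_srur, ex$cost_srur)
  # resources-only keeps donor resource but no donor deaths/survivors
  expect_equal(ro$n_survivors, ex$n_survivors)
  expect_equal(ro$observed_deaths, ex$observed_deaths)
  expect_gt(ro$observed_cost, ex$observed_cost)
  # with zero donors all policies coincide
  nod <- adm[!adm$organ_donor, ]
  bm2 <- icu_benchmark(nod, prof, subgroups = "ALL",
                       donor_policies = c("exclude", "include"))
  r2 <- bm2$results
  expect_equal(r2[r2$donor_policy == "exclude",
                  setdiff(names(r2), "donor_policy")],
               r2[r2$donor_policy == "include",
                  setdiff(names(r2), "donor_policy")],
               ignore_attr = TRUE)
})

test_that("empty subgroup cells are reported absent and the run continues", {
  co <- rbind(adm_row("1", unit = "A", group = "SAH"),
              adm_row("2", unit = "A", group = "OTHER", saps2 = 45),
              adm_row("3", unit = "B", group = "OTHER", saps2 = 44))
  prof <- make_profiles(c("A", "B"), 2015)
  bm <- icu_benchmark(validate_admissions(co), prof,
                      subgroups = c("SAH", "NON_NEURO"))
  r <- bm$results[bm$results$subgroup == "SAH" & bm$results$measure == "LOS", ]
  b_row <- r[r$unit_id == "B", ]
  expect_equal(b_row$n_admissions, 0)
  expect_false(b_row$srur_defined)
  expect_true(is.na(b_row$cost_srur))
  expect_false(b_row$smr_defined)
})

test_that("multi-year ratios are ratios of sums across per-year references", {
  # one unit deteriorates in year 2; pooled conservation must still hold
  rows <- list()
  for (u in c("A", "B")) for (y in 2015:2016) for (i in 1:6) {
    los <- if (u == "A" && y == 2016) 6 else 2
    rows[[length(rows) + 1]] <- adm_row(paste(u, y, i, sep = "_"), unit = u,
                                        year = y, saps2 = 20 + i, los = los,
                                        died = i == 1)
  }
  adm <- validate_admissions(do.call(rbind, rows))
  prof <- make_profiles(c("A", "B"), 2015:2016)
  r <- compute_cost_srur(apply_exclusions(adm)$cohort, prof, "ALL", "LOS")
  expect_equal(sum(r$observed_cost), sum(r$expected_cost), tolerance = 1e-9)
  expect_gt(r$cost_srur[r$unit_id == "A"], 1)
  # manual ratio-of-sums for unit A from single-year runs
  per_year <- lapply(2015:2016, function(y) {
    co_y <- apply_exclusions(adm[adm$year == y, ])$cohort
    compute_cost_srur(co_y, prof, "ALL", "LOS")
  })
  obs_a <- sum(vapply(per_year, function(p)
    p$observed_cost[p$unit_id == "A"], numeric(1)))
  exp_a <- sum(vapply(per_year, function(p)
    p$expected_cost[p$unit_id == "A"], numeric(1)))
  expect_equal(r$cost_srur[r$unit_id == "A"], obs_a / exp_a,
               tolerance = 1e-12)
})
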