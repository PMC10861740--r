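test_that("the generator is deterministic under a seed", {
  cfg <- registry_config(n_units = 3, years = 2015:2016,
                         admissions_per_unit_year = 150)
  a <- simulate_registry(cfg, seed = 42)
  b <- simulate_registry(cfg, seed = 42)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$profiles$costs, b$profiles$costs)
  c <- simulate_registry(cfg, seed = 43)
  expect_false(identical(a$admissions, c$admissions))
})

test_that("invalid configurations are rejected", {
  expect_error(registry_config(neuro_mix = c(NONTRAUMATIC_ICH = 0.5,
                                             SAH = 0.2,
                                             TBI_MULTITRAUMA = 0.2,
                                             TBI_ISOLATED = 0.2)),
               "sum to 1")
  expect_error(registry_config(admissions_per_unit_year = -5), "positive")
  expect_error(registry_config(neuro_fraction = 1.4), "neuro_fraction")
  expect_error(registry_config(donor_fraction = -0.1), "fractions")
  expect_error(inject_unit_distortion(registry_config(n_units = 2), "U9"),
               "unknown unit")
  expect_error(inject_unit_distortion(registry_config(), "U1",
                                      cost_inflation = 0), "positive")
})

test_that("diagnosis mix and per-group medians hit their targets", {
  # tolerances fixed in the methods vignette: mix +-0.01 at n = 50,000,
  # per-group median SAPS II +-2 points, median LOS +-0.5 days
  cfg <- registry_config(n_units = 2, years = 2015,
                         admissions_per_unit_year = 25000)
  reg <- simulate_registry(cfg, seed = 17)
  co <- apply_exclusions(reg$admissions)$cohort
  neuro <- co[co$diagnosis_group != "OTHER", ]
  mix <- prop.table(table(neuro$diagnosis_group))
  targets <- c(NONTRAUMATIC_ICH = 0.408, SAH = 0.226,
               TBI_MULTITRAUMA = 0.132, TBI_ISOLATED = 0.234)
  for (g in names(targets)) {
    expect_lt(abs(mix[[g]] - targets[[g]]), 0.01)
  }
  saps_t <- c(NONTRAUMATIC_ICH = 34, SAH = 28, TBI_MULTITRAUMA = 31,
              TBI_ISOLATED = 29, OTHER = 36)
  los_t <- c(NONTRAUMATIC_ICH = 1.7, SAH = 3.4, TBI_MULTITRAUMA = 2.3,
             TBI_ISOLATED = 1.5, OTHER = 1.5)
  for (g in names(saps_t)) {
    sg <- co[co$diagnosis_group == g, ]
    expect_lt(abs(median(sg$saps2) - saps_t[[g]]), 2.5)
    expect_lt(abs(median(sg$los_days) - los_t[[g]]), 0.5)
  }
})

test_that("observed mortality agrees with the generating model", {
  cfg <- registry_config(n_units = 2, years = 2015,
                         admissions_per_unit_year = 8000,
                         donor_fraction = 0)
  reg <- simulate_registry(cfg, seed = 8)
  co <- apply_exclusions(reg$admissions)$cohort
  p <- predict(cfg$mortality_model, co)
  se <- sqrt(sum(p * (1 - p))) / nrow(co)
  expect_lt(abs(mean(co$died_in_hospital) - mean(p)), 3 * se)
})

test_that("injected distortions are recorded and change only their unit", {
  cfg <- registry_config(n_units = 3, years = 2015,
                         admissions_per_unit_year = 2500)
  base <- simulate_registry(cfg, seed = 5)
  cfg2 <- inject_unit_distortion(cfg, "U2", cost_inflation = 1.5,
                                 mortality_odds = 2)
  dist <- simulate_registry(cfg2, seed = 5)
  expect_equal(dist$truth$cost_inflation, c(1, 1.5, 1))
  expect_equal(dist$truth$mortality_odds, c(1, 2, 1))
  # identity injection changes nothing but bookkeeping
  cfg3 <- inject_unit_distortion(cfg, "U2")
  same <- simulate_registry(cfg3, seed = 5)
  expect_identical(base$admissions, same$admissions)
  # inflation scales that unit's resource accrual, not its peers'
  m_base <- tapply(base$admissions$los_days, base$admissions$unit_id, mean)
  m_dist <- tapply(dist$admissions$los_days, dist$admissions$unit_id, mean)
  expect_equal(unname(m_dist["U2"] / m_base["U2"]), 1.5, tolerance = 0.1)
  expect_equal(unname(m_dist["U1"] / m_base["U1"]), 1, tolerance = 0.05)
  # doubled odds visible as a frequency shift in the distorted unit only
  d_base <- tapply(base$admissions$died_in_hospital,
                   base$admissions$unit_id, mean, na.rm = TRUE)
  d_dist <- tapply(dist$admissions$died_in_hospital,
                   dist$admissions$unit_id, mean, na.rm = TRUE)
  expect_gt(d_dist[["U2"]], d_base[["U2"]] * 1.3)
  expect_equal(d_dist[["U3"]], d_base[["U3"]], tolerance = 0.05)
})

test_that("written fixtures round-trip losslessly", {
  dir <- withr::local_tempdir()
  reg <- simulate_registry(registry_config(n_units = 2, years = 2015:2016,
                                           admissions_per_unit_year = 120),
                           seed = 30)
  paths <- write_registry(reg, dir)
  expect_true(all(file.exists(paths)))
  back_adm <- read_admissions(file.path(dir, "admissions.csv"))
  expect_equal(back_adm, reg$admissions, ignore_attr = TRUE)
  back_prof <- read_unit_profiles(file.path(dir, "unit_profiles.yaml"))
  expect_equal(back_prof$units, reg$profiles$units, ignore_attr = TRUE)
  expect_equal(back_prof$costs, reg$profiles$costs, ignore_attr = TRUE,
               tolerance = 1e-12)
  # rewriting the same registry yields byte-identical files
  dir2 <- withr::local_tempdir()
  write_registry(reg, dir2)
  expect_identical(unname(tools::md5sum(file.path(dir, "admissions.csv"))),
                   unname(tools::md5sum(file.path(dir2, "admissions.csv"))))
  # a 6-unit 3-year default covers all unit-years in one profile document
  reg6 <- simulate_registry(registry_config(admissions_per_unit_year = 20),
                            seed = 1)
  expect_silent(check_profile_coverage(reg6$profiles, reg6$admissions))
})
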