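test_that("a zero-variance adherent cohort produces all-zero deltas", {
  cfg <- study_config(
    n_patients = 3, seed = 5,
    pk = pk_population_spec(sd_ln_ke = 0, sd_ln_ka_ir = 0, sd_ln_ka_xr = 0,
                            sd_ln_v = 0),
    pd = pd_population_spec(sd_ln_bprs0 = 0, sd_alpha = 0, sd_ln_emax = 0,
                            sd_ln_ec50 = 0),
    scenarios = "adherence")
  res <- run_trial(cfg)
  s <- res$summaries
  expect_true(all(s$delta_cmax == 0))
  expect_true(all(s$delta_cmin == 0))
  expect_true(all(s$delta_dbprs_max == 0))
  expect_true(all(s$delta_dbprs_min == 0))
})

test_that("trial results are deterministic under a fixed seed", {
  cfg <- study_config(n_patients = 8, seed = 123,
                      scenarios = c("adherence", "delay", "omission"),
                      delay_fractions = c(0.5, 1))
  r1 <- run_trial(cfg)
  r2 <- run_trial(cfg)
  expect_identical(r1$summaries, r2$summaries)
  expect_identical(r1$table_delay, r2$table_delay)
  cfg2 <- study_config(n_patients = 8, seed = 124,
                       scenarios = c("adherence", "delay", "omission"),
                       delay_fractions = c(0.5, 1))
  expect_false(identical(run_trial(cfg2)$summaries$cmax, r1$summaries$cmax))
})

test_that("the trial table covers every arm with the right sample sizes", {
  cfg <- study_config(n_patients = 12, seed = 9)
  res <- run_trial(cfg)
  s <- res$summaries
  labels <- c("adherence", "delay_25", "delay_50", "delay_75", "delay_100",
              "omission", "doubling", "discontinuation")
  expect_setequal(unique(s$scenario), labels)
  expect_equal(nrow(s), 12 * 2 * length(labels))
  # delay table: mean delta Cmax increases with the delay fraction
  td <- res$table_delay
  for (form in c("IR", "XR")) {
    m <- td$mean[td$parameter == "dCmax" & td$formulation == form]
    expect_true(all(diff(m[order(c(25, 50, 75, 100))]) > 0))
  }
  # omission deltas negative, doubling deltas positive (PK rows)
  t2 <- res$table_single_dose
  expect_true(all(t2$mean[t2$scenario == "omission" &
                            t2$parameter %in% c("dCmax", "dCmin")] < 0))
  expect_true(all(t2$mean[t2$scenario == "doubling" &
                            t2$parameter %in% c("dCmax", "dCmin")] > 0))
  # recovery and duration columns populated only for their scenarios
  expect_true(all(is.na(s$t_recovery[s$scenario != "omission"])))
  expect_true(all(is.finite(s$t_recovery[s$scenario == "omission"])))
  expect_true(all(is.na(s$duration[s$scenario != "discontinuation"])))
  # proportions in [0, 1]
  expect_true(all(res$proportions$proportion >= 0 &
                    res$proportions$proportion <= 1))
})

test_that("monte-carlo means are consistent across cohort sizes", {
  # delay-50 IR delta Cmax: a small trial's mean lies within 3 SE bands of
  # a larger trial's mean
  cfg_small <- study_config(n_patients = 150, seed = 77,
                            scenarios = "delay", delay_fractions = 0.5,
                            formulations = "IR")
  cfg_big <- study_config(n_patients = 900, seed = 78,
                          scenarios = "delay", delay_fractions = 0.5,
                          formulations = "IR")
  s1 <- run_trial(cfg_small)$summaries
  s2 <- run_trial(cfg_big)$summaries
  m1 <- mean(s1$delta_cmax); se1 <- sd(s1$delta_cmax) / sqrt(nrow(s1))
  m2 <- mean(s2$delta_cmax); se2 <- sd(s2$delta_cmax) / sqrt(nrow(s2))
  expect_lt(abs(m1 - m2), 3 * sqrt(se1^2 + se2^2))
})

test_that("tables render to CSV files and round-trip numerically", {
  cfg <- study_config(n_patients = 6, seed = 21,
                      scenarios = c("adherence", "delay", "omission",
                                    "discontinuation"),
                      delay_fractions = 0.5)
  res <- run_trial(cfg)
  dir <- withr::local_tempdir()
  paths <- render_tables(res, dir)
  expect_true(all(file.exists(paths)))
  tab <- utils::read.csv(file.path(dir, "delay_table.csv"))
  expect_true(all(c("scenario", "parameter", "formulation", "mean", "cv",
                    "ks_p", "display") %in% names(tab)))
  expect_equal(tab$mean, res$table_delay$mean)
  sums <- utils::read.csv(file.path(dir, "patient_summaries.csv"))
  expect_equal(nrow(sums), nrow(res$summaries))
  # mean(CV) display strings match the numeric columns
  expect_equal(tab$display[1], sprintf("%.1f(%.1f)", tab$mean[1], tab$cv[1]))
})

test_that("configuration files round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 25",
    "seed: 99",
    "scenarios: [adherence, delay]",
    "delay_fractions: [0.25, 1.0]",
    "population:",
    "  pk:",
    "    mu_ka_xr: 0.157",
    "    v_mode: as_printed",
    "  pd:",
    "    sd_alpha: 0.0001"), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$n_patients, 25L)
  expect_equal(cfg$pk$mu_ka_xr, 0.157)
  expect_equal(cfg$pk$typical_v, 73.7)
  expect_equal(cfg$pd$sd_alpha, 0.0001)
  expect_equal(cfg$delay_fractions, c(0.25, 1))
  # unknown fields rejected before any simulation
  writeLines("bogus_field: 3", path)
  expect_error(read_study_config(path), "unknown configuration field")
  # invalid values rejected by the schema
  expect_error(study_config(n_patients = 0), "positive integer")
  expect_error(study_config(delay_fractions = c(0.5, 1.5)), "delay_fractions")
})
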