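make_profiles <- function(scenario, form = "IR", horizon = NULL,
                          delay_fraction = NULL, patients = typ) {
  reg <- build_regimen(form, scenario, delay_fraction = delay_fraction,
                       horizon = horizon)
  conc <- concentration_profile(reg, patients)
  list(reg = reg, conc = conc, resp = bprs_profile(conc, patients))
}

test_that("window extrema and trough minima follow their definitions", {
  ad <- make_profiles("adherence")
  we <- window_extrema(ad$conc, c(192, 216))
  expect_equal(we$max, 349.55, tolerance = 1e-4)
  expect_gte(we$max, we$min)
  expect_equal(trough_minima(ad$conc, c(192, 216), 12), 110.16,
               tolerance = 1e-4)
  # trough minima = profile values at the pre-dose instants
  expect_equal(trough_minima(ad$conc, c(192, 216), 12),
               min(profile_at(ad$conc, c(204, 216))))
  expect_error(window_extrema(ad$conc, c(300, 301)), "no grid points")
  expect_error(profile_at(ad$conc, 204.013), "grid")
})

test_that("typical-patient percent changes match the superposition oracle", {
  ad <- make_profiles("adherence")
  ref_max <- window_extrema(ad$conc, c(192, 216))$max
  ref_min <- trough_minima(ad$conc, c(192, 216), 12)

  d100 <- make_profiles("delay", delay_fraction = 1)
  expect_equal(delta_parameters(window_extrema(d100$conc, c(192, 216))$max,
                                ref_max), 54.94, tolerance = 1e-3)
  expect_equal(window_extrema(d100$conc, c(192, 216))$max, 541.6,
               tolerance = 1e-3)
  expect_equal(delta_parameters(trough_minima(d100$conc, c(192, 216), 12),
                                ref_min), 13.80, tolerance = 1e-3)

  om <- make_profiles("omission", horizon = 216)
  w <- om$reg$windows$scenario_window
  expect_equal(w, c(180, 216))
  expect_equal(delta_parameters(trough_minima(om$conc, w, 12),
                                trough_minima(ad$conc, w, 12)),
               -76.31, tolerance = 1e-3)
  expect_equal(delta_parameters(window_extrema(om$conc, w)$max,
                                window_extrema(ad$conc, w)$max),
               -4.66, tolerance = 1e-3)

  db <- make_profiles("doubling")
  expect_equal(delta_parameters(window_extrema(db$conc, c(192, 216))$max,
                                ref_max), 19.85, tolerance = 1e-3)
  expect_equal(delta_parameters(trough_minima(db$conc, c(192, 216), 12),
                                ref_min), 4.28, tolerance = 1e-3)
})

test_that("delta of identical summaries is zero; bad references go missing", {
  x <- c(10, 20, 30)
  expect_equal(delta_parameters(x, x), c(0, 0, 0))
  expect_true(is.na(delta_parameters(5, 0)))
  expect_true(is.na(delta_parameters(5, -2)))
})

test_that("recovery time matches the closed-form decay of the missing dose", {
  ad <- make_profiles("adherence", horizon = 504)
  om <- make_profiles("omission")
  # identical profiles -> zero
  r0 <- recovery_time(ad$conc, ad$conc, t0 = 180)
  expect_equal(r0$t_recovery, 0)
  expect_false(r0$censored)

  # typical IR: the omission deviation is exactly the missing dose's
  # contribution; the 1 ug/L band is left for good at its decay time
  r <- recovery_time(om$conc, ad$conc, t0 = 180)
  expected <- oracle_recovery_typical(200000, typ$ka_ir, typ$ke, typ$v, 1)
  expect_equal(r$t_recovery, expected, tolerance = 0.06 / expected)

  ad_xr <- make_profiles("adherence", form = "XR", horizon = 504)
  om_xr <- make_profiles("omission", form = "XR")
  r_xr <- recovery_time(om_xr$conc, ad_xr$conc, t0 = 168)
  expected_xr <- oracle_recovery_typical(400000, typ$ka_xr, typ$ke, typ$v, 1)
  expect_equal(r_xr$t_recovery, expected_xr, tolerance = 0.06 / expected_xr)
  # XR recovery takes longer than IR (slower absorption)
  expect_gt(r_xr$t_recovery, r$t_recovery)

  # monotone non-increasing in the band width (relative banding)
  tols <- c(0.01, 0.02, 0.05, 0.1)
  recs <- vapply(tols, function(tl)
    recovery_time(om$conc, ad$conc, t0 = 180, tol = tl,
                  type = "relative")$t_recovery, numeric(1))
  expect_true(all(diff(recs) <= 0))
})

test_that("therapeutic duration and hangover behave under both criteria", {
  disc <- make_profiles("discontinuation")
  # fixed-threshold mode: typical patient crosses its borderline
  # concentration on the post-dose decay
  dh <- therapeutic_duration_and_hangover(disc$conc, 180, 12, patients = typ)
  c14 <- threshold_concentration(typ, t_ref = 192)
  cross <- disc$conc$times[disc$conc$times >= 180][
    which(disc$conc$cp[disc$conc$times >= 180, 1] < c14)[1]]
  expect_equal(dh$duration, cross - 180)
  expect_equal(dh$hangover, dh$duration - 12)
  expect_false(dh$censored); expect_false(dh$excluded)

  # time-varying mode reproduces the ~17 h typical duration
  dh_tv <- therapeutic_duration_and_hangover(disc$resp, 180, 12,
                                             mode = "time_varying")
  expect_equal(dh_tv$duration, 17.0, tolerance = 0.01)
  expect_equal(dh_tv$hangover, 5.0, tolerance = 0.05)

  # sub-therapeutic patient: duration 0, hangover -tau
  weak <- typ; weak$emax <- 0.01; weak$alpha <- 0
  disc_w <- make_profiles("discontinuation", patients = weak)
  dh_w <- therapeutic_duration_and_hangover(disc_w$resp, 180, 12,
                                            mode = "time_varying")
  expect_equal(dh_w$duration, 0)
  expect_equal(dh_w$hangover, -12)

  # always-therapeutic patient censors at the horizon
  strong <- typ; strong$alpha <- -0.2
  disc_s <- make_profiles("discontinuation", patients = strong)
  dh_s <- therapeutic_duration_and_hangover(disc_s$resp, 180, 12,
                                            mode = "time_varying")
  expect_true(dh_s$censored)
  expect_equal(dh_s$duration, 504 - 180)

  # unreachable fixed threshold is excluded, not zero
  dh_x <- therapeutic_duration_and_hangover(disc_w$conc, 180, 12,
                                            patients = weak)
  expect_true(dh_x$excluded)
  expect_true(is.na(dh_x$duration))

  # duration is monotone non-increasing in the response threshold
  durs <- vapply(c(5, 10, 14, 20), function(th)
    therapeutic_duration_and_hangover(disc$resp, 180, 12,
                                      mode = "time_varying",
                                      threshold = th)$duration, numeric(1))
  expect_true(all(diff(durs) <= 0))
})

test_that("risk outcomes flag therapeutic-window violations", {
  ad <- make_profiles("adherence")
  ev <- risk_outcomes(ad$conc, ad$resp, c(192, 216), 12)
  expect_false(ev$event_high)  # typical peak ~350 < 500
  expect_false(ev$event_low)   # typical trough reduction ~17% > 14%

  d100 <- make_profiles("delay", delay_fraction = 1)
  ev100 <- risk_outcomes(d100$conc, d100$resp, c(192, 216), 12)
  expect_true(ev100$event_high)  # ~540 > 500

  # an all-zero profile is sub-therapeutic and not supra-threshold
  pat0 <- typ; pat0$alpha <- 0
  reg0 <- build_regimen("IR", "adherence")
  reg0$events <- reg0$events[0, ]
  conc0 <- concentration_profile(reg0, pat0)
  ev0 <- risk_outcomes(conc0, bprs_profile(conc0, pat0), c(192, 216), 12)
  expect_true(ev0$event_low)
  expect_false(ev0$event_high)
})
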