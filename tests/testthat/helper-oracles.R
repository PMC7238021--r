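# Shared fixtures and independent oracles used across the suite.
# The oracles deliberately avoid the package's superposition/grid machinery:
# closed forms, brute-force ECDF sweeps and glm fits only.

default_pk <- pk_population_spec()
default_pd <- pd_population_spec()
typ <- typical_patient(default_pk, default_pd)

# direct evaluation of the single-dose formula (no limit handling)
oracle_single_cp <- function(t, dose, ka, ke, v) {
  dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

# geometric-series steady-state concentration, t in [0, tau) since a dose
oracle_css <- function(t, dose, ka, ke, v, tau) {
  a <- dose * ka / (v * (ka - ke))
  a * (exp(-ke * t) / (1 - exp(-ke * tau)) -
         exp(-ka * t) / (1 - exp(-ka * tau)))
}

# brute-force two-sample KS statistic: sweep the ECDF difference over all
# observed values
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# odds ratio via a binomial-logit glm on the 2x2 layout
oracle_or_glm <- function(events_xr, n_xr, events_ir, n_ir) {
  fit <- stats::glm(
    cbind(events = c(events_xr, events_ir),
          non_events = c(n_xr - events_xr, n_ir - events_ir)) ~ arm,
    family = stats::binomial(),
    data = data.frame(arm = factor(c("XR", "IR"), levels = c("IR", "XR"))))
  unname(exp(stats::coef(fit)["armXR"]))
}

# time at which the single missing-dose contribution decays to `band` ug/L
# (the recovery time of the typical patient, since by superposition the
# omission deviation IS the missing dose's contribution, monotone beyond
# its absorption peak)
oracle_recovery_typical <- function(dose, ka, ke, v, band) {
  stats::uniroot(function(a) oracle_single_cp(a, dose, ka, ke, v) - band,
                 c(log(ka / ke) / (ka - ke) + 1, 5000), tol = 1e-10)$root
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
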