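#' BPRS response profiles from concentration profiles
#'
#' Applies the exposure-response model
#' `BPRS(t) = BPRS0 + alpha * t - Emax * Cp(t) / (EC50 + Cp(t))`
#' with time measured from treatment start, and derives the percent
#' reduction from baseline
#' `pct_reduction(t) = 100 * (BPRS0 - BPRS(t)) / BPRS0`.
#' BPRS is not clamped at zero (the model is linear in the placebo term);
#' the number of patients whose score goes negative anywhere on the grid is
#' recorded in the `n_negative_bprs` diagnostic.
#'
#' @param conc A [concentration_profile()] for the same cohort.
#' @param patients The `patient_cohort` the profile was simulated for.
#' @return An object of class `response_profile`: list with `times`, `bprs`
#'   (points), `pct_reduction` (% of baseline), `patient_id`,
#'   `n_negative_bprs`, plus the formulation/scenario tags of the source
#'   profile.
#' @export
bprs_profile <- function(conc, patients) {
  stopifnot(inherits(conc, "concentration_profile"),
            inherits(patients, "patient_cohort"))
  if (ncol(conc$cp) != nrow(patients) ||
      !identical(conc$patient_id, patients$id))
    stop("concentration profile and cohort do not match", call. = FALSE)
  if (any(patients$ec50 <= 0))
    stop("EC50 must be positive", call. = FALSE)
  nt <- length(conc$times)
  drug <- conc$cp * rep(patients$emax, each = nt) /
    (conc$cp + rep(patients$ec50, each = nt))
  placebo <- tcrossprod(conc$times, patients$alpha)
  bprs <- rep(patients$bprs0, each = nt) + placebo - drug
  pct <- 100 * (drug - placebo) / rep(patients$bprs0, each = nt)
  structure(list(times = conc$times, bprs = bprs, pct_reduction = pct,
                 patient_id = patients$id,
                 formulation = conc$formulation, scenario = conc$scenario,
                 step = conc$step,
                 n_negative_bprs = sum(apply(bprs < 0, 2, any))),
            class = "response_profile")
}

#' Concentration at the 14% therapeutic borderline
#'
#' Solves, per patient, for the plasma concentration at which the percent
#' reduction in BPRS from baseline equals `threshold` (default 14%, the
#' conventional boundary between genuine and placebo-level response), with
#' the linear placebo term frozen at a reference time:
#' `threshold = 100 * (-alpha * t_ref + Emax * C / (EC50 + C)) / BPRS0`.
#'
#' Returns `0` when the placebo term alone already achieves the threshold
#' (always therapeutic) and `NA` when the required drug effect exceeds
#' `Emax` (the borderline concentration does not exist for that patient).
#'
#' @param patients A `patient_cohort`.
#' @param t_ref Reference time for the placebo term, h (default 168, the
#'   start of the steady-state evaluation days).
#' @param threshold Percent reduction defining the borderline (default 14).
#' @return Numeric vector (ug/L), with `0` for placebo-sufficient patients
#'   and `NA` where the threshold is unreachable.
#' @export
#' @examples
#' pat <- typical_patient(pk_population_spec(), pd_population_spec())
#' threshold_concentration(pat)  # ~67 ug/L
threshold_concentration <- function(patients, t_ref = 168, threshold = 14) {
  stopifnot(inherits(patients, "patient_cohort"), t_ref >= 0)
  e_req <- threshold / 100 * patients$bprs0 + patients$alpha * t_ref
  out <- patients$ec50 * e_req / (patients$emax - e_req)
  out[e_req <= 0] <- 0
  out[e_req >= patients$emax] <- NA_real_
  out
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf("<response_profile> %s %s: %d patients, 0-%g h by %g h\n",
              x$formulation, x$scenario, ncol(x$bprs), max(x$times), x$step))
  if (x$n_negative_bprs > 0)
    cat(sprintf("  note: %d patient(s) with BPRS < 0 somewhere on the grid\n",
                x$n_negative_bprs))
  invisible(x)
}
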