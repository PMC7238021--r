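#' Extrema of a profile over a time window
#'
#' Maximum and minimum (with their times) of each patient's trace over grid
#' points falling in `[window[1], window[2]]`. For concentration profiles
#' the trace is `cp`; for response profiles it is `pct_reduction`.
#'
#' @param profile A `concentration_profile` or `response_profile`.
#' @param window Numeric length-2 `[start, end]` in h, inside the grid.
#' @return Data frame with `patient_id`, `max`, `min`, `argmax`, `argmin`.
#' @export
window_extrema <- function(profile, window) {
  m <- .profile_matrix(profile)
  stopifnot(length(window) == 2L, window[1] < window[2])
  rows <- which(profile$times >= window[1] - 1e-9 &
                profile$times <= window[2] + 1e-9)
  if (!length(rows))
    stop("window [", window[1], ", ", window[2], "] contains no grid points",
         call. = FALSE)
  sub <- m[rows, , drop = FALSE]
  imax <- max.col(t(sub), ties.method = "first")
  imin <- max.col(t(-sub), ties.method = "first")
  data.frame(patient_id = profile$patient_id,
             max = sub[cbind(imax, seq_len(ncol(sub)))],
             min = sub[cbind(imin, seq_len(ncol(sub)))],
             argmax = profile$times[rows][imax],
             argmin = profile$times[rows][imin])
}

#' Profile values at specific grid instants
#'
#' @param profile A `concentration_profile` or `response_profile`.
#' @param at Times (h); each must lie on the profile grid.
#' @return Matrix with one row per requested time, one column per patient.
#' @export
profile_at <- function(profile, at) {
  m <- .profile_matrix(profile)
  idx <- round(at / profile$step) + 1L
  if (any(idx < 1L | idx > length(profile$times)) ||
      any(abs(profile$times[idx] - at) > 1e-6))
    stop("requested times must lie on the profile grid", call. = FALSE)
  m[idx, , drop = FALSE]
}

.profile_matrix <- function(profile) {
  if (inherits(profile, "concentration_profile")) return(profile$cp)
  if (inherits(profile, "response_profile")) return(profile$pct_reduction)
  stop("`profile` must be a concentration or response profile", call. = FALSE)
}

#' Steady-state trough (pre-dose) minima
#'
#' The trough parameter is the minimum of the profile over the pre-dose
#' instants implied by the regular schedule within the window (see
#' [trough_times()]); a dose administered at `t` contributes nothing at `t`
#' itself, so the grid value at a scheduled dose time is the pre-dose value.
#'
#' @inheritParams window_extrema
#' @param tau Dosing interval of the regular schedule, h.
#' @return Numeric vector, one trough value per patient.
#' @export
trough_minima <- function(profile, window, tau) {
  vals <- profile_at(profile, trough_times(tau, window))
  apply(vals, 2, min)
}

#' Percent change of scenario summaries relative to adherent dosing
#'
#' Signed percent change `100 * (irregular - regular) / regular` per
#' patient. Entries with a non-positive reference value are undefined and
#' returned as `NA`.
#'
#' @param scenario_value,reference_value Numeric vectors (same patients,
#'   same formulation): the summary under the irregular and the adherent
#'   regimen.
#' @return Numeric vector of signed percent changes.
#' @export
delta_parameters <- function(scenario_value, reference_value) {
  stopifnot(length(scenario_value) == length(reference_value))
  out <- 100 * (scenario_value - reference_value) / reference_value
  out[!is.finite(reference_value) | reference_value <= 0] <- NA_real_
  out
}

#' Time to restore the adherent steady-state profile after an omitted dose
#'
#' The recovery time is the earliest instant after which the omission
#' profile stays within a band around the same patient's adherent profile
#' for every remaining grid point up to the horizon, measured from the
#' scheduled time of the omitted dose. The default band is absolute,
#' 1 ug/L, reflecting recovery of the *same* steady-state level;
#' `type = "relative"` uses `tol` as a fraction of the adherent
#' concentration instead.
#'
#' @param omission_profile,adherent_profile `concentration_profile`s for the
#'   same cohort on a common grid reaching the analysis horizon.
#' @param t0 Scheduled time of the omitted dose, h.
#' @param tol Band width: ug/L for `type = "absolute"` (default 1), a
#'   fraction for `type = "relative"`.
#' @param type `"absolute"` (default) or `"relative"`.
#' @return Data frame with `patient_id`, `t_recovery` (h; equals the
#'   censoring span when censored) and `censored` (band never entered for
#'   good before the horizon).
#' @export
recovery_time <- function(omission_profile, adherent_profile, t0,
                          tol = 1, type = c("absolute", "relative")) {
  type <- match.arg(type)
  stopifnot(inherits(omission_profile, "concentration_profile"),
            inherits(adherent_profile, "concentration_profile"),
            tol > 0, t0 >= 0)
  if (!isTRUE(all.equal(omission_profile$times, adherent_profile$times)) ||
      !identical(omission_profile$patient_id, adherent_profile$patient_id))
    stop("profiles must share grid and cohort", call. = FALSE)
  rows <- which(omission_profile$times >= t0 - 1e-9)
  ad <- adherent_profile$cp[rows, , drop = FALSE]
  om <- omission_profile$cp[rows, , drop = FALSE]
  if (any(ad <= 0))
    stop("adherent concentration is zero in the comparison region",
         call. = FALSE)
  dev <- abs(om - ad)
  if (type == "relative") dev <- dev / ad
  bad <- dev > tol
  last_bad <- apply(bad, 2, function(z) {
    w <- which(z)
    if (length(w)) w[length(w)] else 0L
  })
  tt <- omission_profile$times[rows]
  censored <- last_bad >= length(tt)
  t_star <- ifelse(last_bad == 0L, t0, tt[pmin(last_bad + 1L, length(tt))])
  data.frame(patient_id = omission_profile$patient_id,
             t_recovery = ifelse(censored, tt[length(tt)] - t0, t_star - t0),
             censored = censored)
}

#' Therapeutic duration and hangover after treatment discontinuation
#'
#' The therapeutic duration is how long, counted from the last administered
#' dose, the response stays at or above the 14% reduction-from-baseline
#' borderline; the hangover is the duration minus the dosing interval (the
#' grace period beyond the dose the patient skipped).
#'
#' Two criteria are available. The default, `mode = "threshold_conc"`,
#' mirrors the borderline-concentration construction: each patient's fixed
#' threshold concentration (see [threshold_concentration()], placebo term
#' frozen at `t_ref`, by default the scheduled-but-missed next dose
#' `last_dose_time + tau`) is compared against the concentration profile;
#' patients whose threshold is unreachable have no borderline and are
#' flagged `excluded`. `mode = "time_varying"` instead applies the 14%
#' criterion to the full time-varying percent reduction (drug + placebo) and
#' excludes nobody.
#'
#' @param profile A `concentration_profile` (`threshold_conc` mode) or
#'   `response_profile` (`time_varying` mode) simulated under the
#'   discontinuation regimen, horizon >= 504 h recommended.
#' @param patients The cohort (required for `threshold_conc`).
#' @param last_dose_time Time of the last administered dose, h.
#' @param tau Dosing interval, h.
#' @param threshold Percent reduction defining therapeutic response
#'   (default 14).
#' @param mode `"threshold_conc"` (default) or `"time_varying"`.
#' @param t_ref Placebo reference time for the fixed threshold; default
#'   `last_dose_time + tau`.
#' @return Data frame with `patient_id`, `duration` (h), `hangover` (h,
#'   signed; `duration - tau`), `censored` (still therapeutic at the
#'   horizon) and `excluded` (no attainable borderline; duration `NA`).
#' @export
therapeutic_duration_and_hangover <- function(profile, last_dose_time, tau,
                                              patients = NULL,
                                              threshold = 14,
                                              mode = c("threshold_conc",
                                                       "time_varying"),
                                              t_ref = NULL) {
  mode <- match.arg(mode)
  rows <- which(profile$times >= last_dose_time - 1e-9)
  tt <- profile$times[rows]
  if (mode == "threshold_conc") {
    stopifnot(inherits(profile, "concentration_profile"),
              inherits(patients, "patient_cohort"))
    if (is.null(t_ref)) t_ref <- last_dose_time + tau
    c14 <- threshold_concentration(patients, t_ref = t_ref,
                                   threshold = threshold)
    excluded <- is.na(c14)
    cp <- profile$cp[rows, , drop = FALSE]
    below <- cp < rep(ifelse(excluded, Inf, c14), each = length(tt))
    below[, !excluded & c14 == 0] <- FALSE   # always-therapeutic patients
  } else {
    stopifnot(inherits(profile, "response_profile"))
    excluded <- rep(FALSE, ncol(profile$pct_reduction))
    below <- profile$pct_reduction[rows, , drop = FALSE] < threshold
  }
  first_below <- apply(below, 2, function(z) which(z)[1])
  censored <- is.na(first_below) & !excluded
  duration <- ifelse(is.na(first_below), tt[length(tt)] - last_dose_time,
                     tt[first_below] - last_dose_time)
  duration[excluded] <- NA_real_
  data.frame(patient_id = profile$patient_id,
             duration = duration,
             hangover = duration - tau,
             censored = censored,
             excluded = excluded)
}

#' Binary therapeutic-window violations over an evaluation window
#'
#' `event_low`: the steady-state trough of the percent reduction (read at
#' the pre-dose instants, as for the trough parameters) falls below the
#' therapeutic borderline. `event_high`: the peak concentration in the
#' window exceeds the toxicity threshold.
#'
#' @param conc A `concentration_profile`.
#' @param resp The matching `response_profile`.
#' @param window Evaluation window `[start, end]`, h.
#' @param tau Dosing interval, h.
#' @param low_threshold Percent-reduction borderline (default 14).
#' @param high_threshold Concentration threshold, ug/L (default 500).
#' @return Data frame with `patient_id`, `event_low`, `event_high`.
#' @export
risk_outcomes <- function(conc, resp, window, tau,
                          low_threshold = 14, high_threshold = 500) {
  stopifnot(inherits(conc, "concentration_profile"),
            inherits(resp, "response_profile"))
  data.frame(patient_id = conc$patient_id,
             event_low = trough_minima(resp, window, tau) < low_threshold,
             event_high = window_extrema(conc, window)$max > high_threshold)
}
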