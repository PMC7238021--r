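#' Build a dose-event schedule for a non-adherence scenario
#'
#' Constructs the explicit list of dose events implied by one of five
#' scenarios applied to regular dosing of quetiapine IR (200 mg every 12 h)
#' or XR (400 mg every 24 h), together with the evaluation windows used for
#' the steady-state summary parameters. Regular dosing runs from t = 0;
#' days 7-9 (168-216 h) are treated as steady state and the single dose
#' irregularity occurs on day 8, affecting the last scheduled day-8 dose
#' (IR: 180 h, XR: 168 h). Regular dosing resumes with the next scheduled
#' dose at 192 h.
#'
#' Scenarios: `adherence` (no irregularity), `delay` (the day-8 dose is
#' administered `delay_fraction * tau` hours late; at 100% delay it coincides
#' with the 192 h dose), `omission` (the dose is skipped without
#' replacement), `doubling` (double the amount is taken at the scheduled
#' time) and `discontinuation` (no doses after the day-8 dose).
#'
#' @param formulation `"IR"` or `"XR"`.
#' @param scenario One of `"adherence"`, `"delay"`, `"omission"`,
#'   `"doubling"`, `"discontinuation"`.
#' @param delay_fraction Fraction of the dosing interval in (0, 1]; required
#'   when `scenario = "delay"` (the study grid is 0.25, 0.5, 0.75, 1).
#' @param dose Dose amount in ug per administration. Defaults: IR 200000
#'   (200 mg), XR 400000 (400 mg).
#' @param tau Dosing interval in h. Defaults: IR 12, XR 24.
#' @param horizon Simulation horizon in h. Defaults to 216 h (end of day 9)
#'   for `adherence`, `delay` and `doubling`, and 504 h (three weeks) for
#'   `omission` and `discontinuation`, whose recovery and hangover analyses
#'   need the longer tail.
#' @return An object of class `regimen`: a list with `formulation`, `tau`,
#'   `dose`, `scenario`, `delay_fraction`, `horizon`, `irregular_time` (the
#'   scheduled time of the affected dose), `last_dose_time` and `events`
#'   (data frame with columns `time` and `amount`, sorted by time), plus the
#'   evaluation `windows` (see [evaluation_windows()]).
#' @export
#' @examples
#' reg <- build_regimen("IR", "delay", delay_fraction = 0.5)
#' reg$events[reg$events$time > 168 & reg$events$time < 216, ]
build_regimen <- function(formulation = c("IR", "XR"),
                          scenario = c("adherence", "delay", "omission",
                                       "doubling", "discontinuation"),
                          delay_fraction = NULL,
                          dose = NULL, tau = NULL, horizon = NULL) {
  formulation <- match.arg(formulation)
  scenario <- match.arg(scenario)
  if (is.null(dose)) dose <- if (formulation == "IR") 200000 else 400000
  if (is.null(tau)) tau <- if (formulation == "IR") 12 else 24
  if (!tau %in% c(12, 24))
    stop("`tau` must be 12 or 24 h", call. = FALSE)
  if (is.null(horizon))
    horizon <- if (scenario %in% c("omission", "discontinuation")) 504 else 216
  if (scenario == "delay") {
    if (is.null(delay_fraction) || length(delay_fraction) != 1L ||
        !is.finite(delay_fraction) || delay_fraction <= 0 || delay_fraction > 1)
      stop("`delay_fraction` must be a single value in (0, 1] for the delay scenario",
           call. = FALSE)
  } else {
    delay_fraction <- NULL
  }

  # last scheduled dose of day 8 ([168, 192) h)
  irregular_time <- tau * floor((192 - 1e-9) / tau)
  times <- tau * seq(0, floor((horizon - 1e-9) / tau))
  amounts <- rep(dose, length(times))

  if (scenario == "delay") {
    times[times == irregular_time] <- irregular_time + delay_fraction * tau
  } else if (scenario == "omission") {
    keep <- times != irregular_time
    times <- times[keep]; amounts <- amounts[keep]
  } else if (scenario == "doubling") {
    amounts[times == irregular_time] <- 2 * dose
  } else if (scenario == "discontinuation") {
    keep <- times <= irregular_time
    times <- times[keep]; amounts <- amounts[keep]
  }

  ord <- order(times)
  reg <- list(formulation = formulation, tau = tau, dose = dose,
              scenario = scenario, delay_fraction = delay_fraction,
              horizon = horizon, irregular_time = irregular_time,
              last_dose_time = max(times),
              events = data.frame(time = times[ord], amount = amounts[ord]))
  class(reg) <- "regimen"
  reg$windows <- evaluation_windows(reg)
  reg
}

#' Evaluation windows for the steady-state summary parameters
#'
#' The reference window is day 9 under adherent dosing, `[192, 216]` h. The
#' scenario window over which the post-irregularity extrema are taken is
#' `[192, 216]` for delay and doubling (parameters are read after the next
#' scheduled dose), `[scheduled time of the omitted dose, 216]` for omission
#' (so the pre-resumption undershoot is captured) and
#' `[last dose, horizon]` for discontinuation.
#'
#' @param regimen A [build_regimen()] object.
#' @return A list of class `evaluation_windows` with `reference_window`,
#'   `scenario_window` and `last_dose_time` (all in h).
#' @export
evaluation_windows <- function(regimen) {
  stopifnot(inherits(regimen, "regimen"))
  ref <- c(192, 216)
  sc <- switch(regimen$scenario,
    adherence = ref,
    delay = ref,
    doubling = ref,
    omission = c(regimen$irregular_time, 216),
    discontinuation = c(regimen$last_dose_time, regimen$horizon))
  sc[2] <- min(sc[2], regimen$horizon)
  w <- list(reference_window = ref, scenario_window = sc,
            last_dose_time = regimen$last_dose_time)
  class(w) <- "evaluation_windows"
  w
}

#' Pre-dose trough instants within a window
#'
#' Steady-state trough concentrations are read at the instants at which a
#' dose is scheduled under regular dosing (the concentration immediately
#' before a dose; a dose administered at `t` contributes nothing at `t`
#' itself) plus the window end. The window start itself is excluded: for the
#' delay scenarios the resumption dose at the window start sits on top of
#' the transient pre-resumption dip, which the steady-state trough parameter
#' deliberately does not measure. For omission windows, which open at the
#' omitted dose, the undershoot trough at the next scheduled dose (192 h) is
#' included.
#'
#' @param tau Dosing interval in h.
#' @param window Numeric length-2 window `[start, end]` in h.
#' @return Sorted vector of trough evaluation times in h.
#' @export
trough_times <- function(tau, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  first <- ceiling((window[1] + 1e-9) / tau) * tau
  if (first <= window[1]) first <- first + tau
  sort(unique(c(seq(first, window[2], by = tau), window[2])))
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s %s: %g mg every %g h, horizon %g h\n",
              x$formulation, x$scenario, x$dose / 1000, x$tau, x$horizon))
  if (!is.null(x$delay_fraction))
    cat(sprintf("  day-8 dose (%g h) delayed by %g%% of the interval\n",
                x$irregular_time, 100 * x$delay_fraction))
  cat(sprintf("  %d dose events, last at %g h\n",
              nrow(x$events), x$last_dose_time))
  invisible(x)
}
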