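#' Study configuration for a virtual trial
#'
#' Collects every tunable of the virtual-trial pipeline with the study's
#' default conditions: 1000 virtual patients per trial, both formulations,
#' all five scenarios with the 25/50/75/100% delay grid, a 0.05 h profile
#' grid, the 14% response borderline and 500 ug/L concentration threshold,
#' an absolute 1 ug/L steady-state recovery band and the 168 h placebo
#' reference time for the borderline-concentration spot check.
#'
#' @param n_patients Cohort size per trial (default 1000).
#' @param seed Integer seed for cohort sampling.
#' @param pk,pd Population specs ([pk_population_spec()],
#'   [pd_population_spec()]).
#' @param formulations Subset of `c("IR", "XR")`.
#' @param scenarios Subset of the five scenario names.
#' @param delay_fractions Delay grid, fractions of the dosing interval.
#' @param step Profile grid step, h.
#' @param low_threshold Percent-reduction borderline (default 14).
#' @param high_threshold Concentration threshold, ug/L (default 500).
#' @param recovery_tol,recovery_type Recovery band (see [recovery_time()]).
#' @param hangover_mode Duration criterion (see
#'   [therapeutic_duration_and_hangover()]).
#' @param t_ref Placebo reference time for [threshold_concentration()], h.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_patients = 1000,
                         seed = 2020L,
                         pk = pk_population_spec(),
                         pd = pd_population_spec(),
                         formulations = c("IR", "XR"),
                         scenarios = c("adherence", "delay", "omission",
                                       "doubling", "discontinuation"),
                         delay_fractions = c(0.25, 0.5, 0.75, 1),
                         step = 0.05,
                         low_threshold = 14,
                         high_threshold = 500,
                         recovery_tol = 1,
                         recovery_type = c("absolute", "relative"),
                         hangover_mode = c("threshold_conc", "time_varying"),
                         t_ref = 168) {
  recovery_type <- match.arg(recovery_type)
  hangover_mode <- match.arg(hangover_mode)
  formulations <- match.arg(formulations, c("IR", "XR"), several.ok = TRUE)
  scenarios <- match.arg(scenarios,
                         c("adherence", "delay", "omission", "doubling",
                           "discontinuation"), several.ok = TRUE)
  if (n_patients < 1 || n_patients != round(n_patients))
    stop("`n_patients` must be a positive integer", call. = FALSE)
  if (any(delay_fractions <= 0 | delay_fractions > 1))
    stop("`delay_fractions` must lie in (0, 1]", call. = FALSE)
  if (step <= 0 || low_threshold <= 0 || high_threshold <= 0 ||
      recovery_tol <= 0 || t_ref < 0)
    stop("grid step, thresholds and tolerances must be positive",
         call. = FALSE)
  stopifnot(inherits(pk, "pk_population_spec"),
            inherits(pd, "pd_population_spec"))
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 pk = pk, pd = pd, formulations = formulations,
                 scenarios = scenarios, delay_fractions = delay_fractions,
                 step = step, low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 recovery_tol = recovery_tol, recovery_type = recovery_type,
                 hangover_mode = hangover_mode, t_ref = t_ref),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' The file may set any argument of [study_config()] at the top level, and
#' population hyperparameters under `population: pk:` / `population: pd:`
#' blocks using the argument names of [pk_population_spec()] and
#' [pd_population_spec()]. Unset fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pop <- raw$population
  raw$population <- NULL
  args <- raw
  if (!is.null(pop$pk)) args$pk <- do.call(pk_population_spec, pop$pk)
  if (!is.null(pop$pd)) args$pd <- do.call(pd_population_spec, pop$pd)
  unknown <- setdiff(names(args), names(formals(study_config)))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(study_config, args)
}

# scenario grid: one row per simulated scenario arm
.scenario_grid <- function(config) {
  rows <- list()
  for (sc in config$scenarios) {
    if (sc == "delay") {
      for (f in config$delay_fractions)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = "delay", delay_fraction = f,
          label = sprintf("delay_%g", 100 * f))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, delay_fraction = NA_real_, label = sc)
    }
  }
  grid <- do.call(rbind, rows)
  grid$delay_fraction <- ifelse(is.na(grid$delay_fraction), NA_real_,
                                grid$delay_fraction)
  grid
}

#' @export
print.study_config <- function(x, ...) {
  cat("Virtual-trial study configuration\n")
  cat(sprintf("  %d patients/trial, seed %d, grid %g h\n",
              x$n_patients, x$seed, x$step))
  cat(sprintf("  formulations: %s; scenarios: %s\n",
              paste(x$formulations, collapse = ", "),
              paste(x$scenarios, collapse = ", ")))
  cat(sprintf("  delays: %s of the interval\n",
              paste(sprintf("%g%%", 100 * x$delay_fractions), collapse = ", ")))
  cat(sprintf("  thresholds: %g%% reduction, %g ug/L; recovery band %g %s\n",
              x$low_threshold, x$high_threshold, x$recovery_tol,
              if (x$recovery_type == "absolute") "ug/L" else "(relative)"))
  invisible(x)
}
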