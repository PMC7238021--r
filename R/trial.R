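#' Run a full virtual trial
#'
#' Samples one cohort per trial (shared between formulations and scenarios,
#' so every comparison is within-patient), simulates concentration and BPRS
#' response profiles for each scenario arm, summarises each patient against
#' their own adherent reference, and aggregates the population tables:
#' delay/omission/doubling percent-change matrices with Kolmogorov-Smirnov
#' IR-vs-XR comparisons, day-9 therapeutic-window event counts, hangover
#' (discontinuation) and steady-state recovery (omission) distributions.
#'
#' @param config A [study_config()].
#' @return An object of class `trial_result`: list with `summaries` (one row
#'   per patient x formulation x scenario arm; `delta_*` columns censor
#'   non-positive references to `NA`, `raw_delta_*` columns keep the plain
#'   ratio for every patient), `table_delay` (the delay
#'   percent-change matrix, averaging the raw ratios as the published
#'   tables do), `table_single_dose` (omission and doubling),
#'   `proportions` (hangover < 24 h and recovery < 48 h shares),
#'   `histograms` (hangover and recovery bin counts), `events` (day-9 event
#'   counts per arm), `diagnostics` and `config`.
#' @export
#' @examples
#' cfg <- study_config(n_patients = 20, seed = 7,
#'                     scenarios = c("adherence", "delay"),
#'                     delay_fractions = 0.5)
#' res <- run_trial(cfg)
#' head(res$summaries)
run_trial <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- sample_patients(config$pk, config$pd, config$n_patients,
                            seed = config$seed)
  grid <- .scenario_grid(config)
  long_ref <- any(grid$scenario %in% c("omission", "discontinuation"))
  rows <- list(); diag <- list()

  for (form in config$formulations) {
    ad_reg <- build_regimen(form, "adherence",
                            horizon = if (long_ref) 504 else 216)
    ad_conc <- concentration_profile(ad_reg, cohort, step = config$step)
    ad_resp <- bprs_profile(ad_conc, cohort)
    diag[[paste0(form, "_adherence_negative_bprs")]] <- ad_resp$n_negative_bprs

    for (i in seq_len(nrow(grid))) {
      sc <- grid$scenario[i]
      reg <- build_regimen(form, sc, delay_fraction = grid$delay_fraction[i])
      if (sc == "adherence") {
        conc <- ad_conc; resp <- ad_resp
      } else {
        conc <- concentration_profile(reg, cohort, step = config$step)
        resp <- bprs_profile(conc, cohort)
      }
      w <- reg$windows$scenario_window
      ref_w <- reg$windows$reference_window

      if (sc == "discontinuation") {
        dh <- therapeutic_duration_and_hangover(
          conc, reg$last_dose_time, reg$tau, patients = cohort,
          threshold = config$low_threshold, mode = config$hangover_mode,
          t_ref = if (config$hangover_mode == "threshold_conc")
            reg$last_dose_time + reg$tau else NULL)
        row <- data.frame(formulation = form, scenario = grid$label[i],
                          delay_fraction = grid$delay_fraction[i],
                          patient_id = cohort$id,
                          cmax = NA_real_, cmin = NA_real_,
                          dbprs_max = NA_real_, dbprs_min = NA_real_,
                          delta_cmax = NA_real_, delta_cmin = NA_real_,
                          delta_dbprs_max = NA_real_,
                          delta_dbprs_min = NA_real_,
                          raw_delta_cmax = NA_real_,
                          raw_delta_cmin = NA_real_,
                          raw_delta_dbprs_max = NA_real_,
                          raw_delta_dbprs_min = NA_real_,
                          t_recovery = NA_real_, recovery_censored = NA,
                          duration = dh$duration, hangover = dh$hangover,
                          duration_censored = dh$censored,
                          duration_excluded = dh$excluded,
                          event_low = NA, event_high = NA)
        rows[[length(rows) + 1L]] <- row
        next
      }

      # window summaries for the scenario and the matched adherent reference
      sc_cmax <- window_extrema(conc, w)$max
      sc_cmin <- trough_minima(conc, w, reg$tau)
      sc_dmax <- window_extrema(resp, w)$max
      sc_dmin <- trough_minima(resp, w, reg$tau)
      rf_cmax <- window_extrema(ad_conc, w)$max
      rf_cmin <- trough_minima(ad_conc, w, reg$tau)
      rf_dmax <- window_extrema(ad_resp, w)$max
      rf_dmin <- trough_minima(ad_resp, w, reg$tau)

      ev <- risk_outcomes(conc, resp, ref_w, reg$tau,
                          config$low_threshold, config$high_threshold)

      rec <- rec_cens <- rep(NA_real_, nrow(cohort))
      if (sc == "omission") {
        r <- recovery_time(conc, ad_conc, t0 = reg$irregular_time,
                           tol = config$recovery_tol,
                           type = config$recovery_type)
        rec <- r$t_recovery; rec_cens <- r$censored
      }

      rows[[length(rows) + 1L]] <- data.frame(
        formulation = form, scenario = grid$label[i],
        delay_fraction = grid$delay_fraction[i],
        patient_id = cohort$id,
        cmax = sc_cmax, cmin = sc_cmin,
        dbprs_max = sc_dmax, dbprs_min = sc_dmin,
        delta_cmax = delta_parameters(sc_cmax, rf_cmax),
        delta_cmin = delta_parameters(sc_cmin, rf_cmin),
        delta_dbprs_max = delta_parameters(sc_dmax, rf_dmax),
        delta_dbprs_min = delta_parameters(sc_dmin, rf_dmin),
        raw_delta_cmax = 100 * (sc_cmax - rf_cmax) / rf_cmax,
        raw_delta_cmin = 100 * (sc_cmin - rf_cmin) / rf_cmin,
        raw_delta_dbprs_max = 100 * (sc_dmax - rf_dmax) / rf_dmax,
        raw_delta_dbprs_min = 100 * (sc_dmin - rf_dmin) / rf_dmin,
        t_recovery = rec, recovery_censored = as.logical(rec_cens),
        duration = NA_real_, hangover = NA_real_,
        duration_censored = NA, duration_excluded = NA,
        event_low = ev$event_low, event_high = ev$event_high)
      diag[[paste0(form, "_", grid$label[i], "_negative_bprs")]] <-
        resp$n_negative_bprs
    }
  }

  summaries <- do.call(rbind, rows)
  res <- list(summaries = summaries,
              table_delay = .delta_table(summaries, grepl("^delay", summaries$scenario)),
              table_single_dose = .delta_table(
                summaries, summaries$scenario %in% c("omission", "doubling")),
              proportions = .trial_proportions(summaries),
              histograms = .trial_histograms(summaries),
              events = .event_counts(summaries),
              diagnostics = diag,
              config = config)
  class(res) <- "trial_result"
  res
}

# mean(CV) matrix of the four delta parameters with IR-vs-XR KS p-values.
# Uses the as-published estimator: the raw percent-change ratio averaged
# over every patient, non-positive references included (the per-patient
# delta_* columns censor those to NA instead).
.delta_table <- function(summaries, keep) {
  s <- summaries[keep, , drop = FALSE]
  if (!nrow(s)) return(NULL)
  pars <- c(raw_delta_cmax = "dCmax", raw_delta_cmin = "dCmin",
            raw_delta_dbprs_max = "dBPRSmax", raw_delta_dbprs_min = "dBPRSmin")
  out <- list()
  for (lab in unique(s$scenario)) {
    for (p in names(pars)) {
      sub <- s[s$scenario == lab, ]
      for (form in unique(sub$formulation)) {
        x <- sub[[p]][sub$formulation == form]
        out[[length(out) + 1L]] <- data.frame(
          scenario = lab, parameter = pars[[p]], formulation = form,
          mean = mean(x, na.rm = TRUE),
          cv = stats::sd(x, na.rm = TRUE) / abs(mean(x, na.rm = TRUE)),
          n = sum(is.finite(x)))
      }
      both <- c("IR", "XR") %in% sub$formulation
      ks_p <- if (all(both))
        ks_two_sample(sub[[p]][sub$formulation == "IR"],
                      sub[[p]][sub$formulation == "XR"])$p else NA_real_
      k <- length(out)
      out[[k]]$ks_p <- ks_p
      if (all(both)) out[[k - 1L]]$ks_p <- ks_p
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

.trial_proportions <- function(summaries) {
  out <- list()
  for (form in unique(summaries$formulation)) {
    disc <- summaries[summaries$scenario == "discontinuation" &
                        summaries$formulation == form, ]
    om <- summaries[summaries$scenario == "omission" &
                      summaries$formulation == form, ]
    if (nrow(disc)) {
      dur <- disc$duration[!disc$duration_excluded]
      out[[length(out) + 1L]] <- data.frame(
        formulation = form, metric = "duration_lt_24h",
        proportion = mean(dur < 24), n = length(dur))
    }
    if (nrow(om)) {
      out[[length(out) + 1L]] <- data.frame(
        formulation = form, metric = "recovery_lt_48h",
        proportion = mean(!om$recovery_censored & om$t_recovery < 48),
        n = nrow(om))
    }
  }
  if (!length(out)) return(NULL)
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

.trial_histograms <- function(summaries) {
  out <- list()
  for (form in unique(summaries$formulation)) {
    disc <- summaries[summaries$scenario == "discontinuation" &
                        summaries$formulation == form, ]
    om <- summaries[summaries$scenario == "omission" &
                      summaries$formulation == form, ]
    if (nrow(disc)) {
      hang <- pmax(disc$hangover[!disc$duration_excluded], 0)
      out[[length(out) + 1L]] <- .bin_counts(hang, 10, form, "hangover")
    }
    if (nrow(om)) {
      rec <- om$t_recovery[!om$recovery_censored]
      out[[length(out) + 1L]] <- .bin_counts(rec, 50, form, "recovery")
    }
  }
  if (!length(out)) return(NULL)
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

# fixed-width histogram bins [k*width, (k+1)*width)
.bin_counts <- function(x, width, form, metric) {
  x <- x[is.finite(x)]
  top <- max(width, ceiling(max(c(x, 0)) / width) * width + width)
  edges <- seq(0, top, by = width)
  idx <- pmin(findInterval(x, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(formulation = form, metric = metric,
             bin_low = edges[-length(edges)], bin_high = edges[-1],
             count = counts)
}

.event_counts <- function(summaries) {
  s <- summaries[!is.na(summaries$event_low), , drop = FALSE]
  if (!nrow(s)) return(NULL)
  agg <- stats::aggregate(cbind(event_low, event_high) ~ formulation + scenario,
                          data = s, FUN = sum)
  n <- stats::aggregate(patient_id ~ formulation + scenario, data = s,
                        FUN = length)
  names(n)[3] <- "n"
  merge(agg, n, by = c("formulation", "scenario"))
}

#' Write the trial tables to CSV files
#'
#' Writes the per-patient summary table, the delay and single-dose
#' percent-change tables (both raw numeric columns and `mean(CV)` display
#' strings), the event counts, the proportions and the histogram bins.
#'
#' @param result A [run_trial()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(result, dir) {
  stopifnot(inherits(result, "trial_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$summaries, "patient_summaries.csv")
  for (nm in c("table_delay", "table_single_dose")) {
    tab <- result[[nm]]
    if (is.null(tab)) {
      wr(data.frame(scenario = character(), parameter = character(),
                    formulation = character(), mean = numeric(),
                    cv = numeric(), n = integer(), ks_p = numeric(),
                    display = character()),
         paste0(sub("^table_", "", nm), "_table.csv"))
      next
    }
    tab$display <- sprintf("%.1f(%.1f)", tab$mean, tab$cv)
    wr(tab, paste0(sub("^table_", "", nm), "_table.csv"))
  }
  if (!is.null(result$events)) wr(result$events, "event_counts.csv")
  if (!is.null(result$proportions)) wr(result$proportions, "proportions.csv")
  if (!is.null(result$histograms)) wr(result$histograms, "histograms.csv")
  invisible(paths)
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Virtual-trial result\n")
  cat(sprintf("  %d patients; formulations: %s\n", x$config$n_patients,
              paste(unique(x$summaries$formulation), collapse = ", ")))
  cat(sprintf("  scenario arms: %s\n",
              paste(unique(x$summaries$scenario), collapse = ", ")))
  if (!is.null(x$proportions)) {
    cat("  proportions:\n")
    for (i in seq_len(nrow(x$proportions)))
      cat(sprintf("    %s %s: %.1f%% (n = %d)\n",
                  x$proportions$formulation[i], x$proportions$metric[i],
                  100 * x$proportions$proportion[i], x$proportions$n[i]))
  }
  invisible(x)
}

#' Export a profile as a tidy data frame
#'
#' One row per patient and grid point, suitable for CSV export or plotting.
#' For response profiles the BPRS and percent-reduction columns are
#' included.
#'
#' @param x A `concentration_profile` or `response_profile`.
#' @param ... Unused.
#' @return A data frame in long format.
#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  n <- ncol(x$cp)
  data.frame(patient_id = rep(x$patient_id, each = length(x$times)),
             formulation = x$formulation, scenario = x$scenario,
             time_h = rep(x$times, n), cp_ug_L = as.vector(x$cp))
}

#' @rdname as.data.frame.concentration_profile
#' @export
as.data.frame.response_profile <- function(x, ...) {
  n <- ncol(x$bprs)
  data.frame(patient_id = rep(x$patient_id, each = length(x$times)),
             formulation = x$formulation, scenario = x$scenario,
             time_h = rep(x$times, n), bprs = as.vector(x$bprs),
             pct_reduction = as.vector(x$pct_reduction))
}
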