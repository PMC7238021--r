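#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' the asymptotic Kolmogorov distribution evaluated at the effective sample
#' size `n1 * n2 / (n1 + n2)` (exact small-sample p-values are immaterial at
#' the trial sizes used here). `NA` values are dropped.
#'
#' @param x,y Numeric samples (each with at least 2 non-missing values).
#' @return List of class `ks_result` with `D`, `p`, `n1`, `n2`.
#' @export
#' @examples
#' ks_two_sample(rnorm(100), rnorm(100, mean = 1))
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 finite values", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(D = unname(kt$statistic), p = unname(kt$p.value),
                 n1 = length(x), n2 = length(y)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS two-sample: D = %.4f, p = %.3g (n1 = %d, n2 = %d)\n",
              x$D, x$p, x$n1, x$n2))
  invisible(x)
}

#' Odds ratio of an event on XR relative to IR
#'
#' Closed-form odds ratio from the 2x2 events/non-events by XR/IR table,
#' algebraically identical to `exp(beta)` from a binomial-logit GLM with a
#' single formulation indicator, with a Wald 95% confidence interval
#' `exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the Haldane-Anscombe 0.5 correction is applied to all four cells;
#' a table with an all-zero margin is returned as undefined (`NA`) with
#' `degenerate = TRUE`.
#'
#' @param events_xr,n_xr Event count and arm size on the XR formulation.
#' @param events_ir,n_ir Event count and arm size on the IR formulation.
#' @return List of class `or_result` with `or`, `ci_low`, `ci_high`,
#'   `table` (the uncorrected 2x2 counts), `corrected`, `degenerate`.
#' @export
#' @examples
#' odds_ratio(10, 100, 20, 100)  # (10/90)/(20/80) = 0.444
odds_ratio <- function(events_xr, n_xr, events_ir, n_ir) {
  stopifnot(n_xr >= 1, n_ir >= 1,
            events_xr >= 0, events_ir >= 0,
            events_xr <= n_xr, events_ir <= n_ir)
  a <- events_xr; b <- n_xr - events_xr
  c_ <- events_ir; d <- n_ir - events_ir
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(c("event", "no_event"), c("XR", "IR")))
  degenerate <- (a + c_) == 0 || (b + d) == 0
  corrected <- FALSE
  if (!degenerate && any(tab == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  if (degenerate) {
    or <- ci_low <- ci_high <- NA_real_
  } else {
    or <- (a / b) / (c_ / d)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    ci_low <- exp(log(or) - 1.96 * se)
    ci_high <- exp(log(or) + 1.96 * se)
  }
  structure(list(or = or, ci_low = ci_low, ci_high = ci_high, table = tab,
                 corrected = corrected, degenerate = degenerate),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Odds ratio: undefined (all-zero margin)\n")
  } else {
    cat(sprintf("Odds ratio (XR vs IR): %.3f [%.3f, %.3f]%s\n",
                x$or, x$ci_low, x$ci_high,
                if (x$corrected) " (Haldane-Anscombe corrected)" else ""))
  }
  invisible(x)
}

#' Replicate-averaged odds-ratio panel
#'
#' Runs `n_replicates` independent virtual trials (fresh cohorts seeded
#' `seed + 1, ..., seed + R`) and, for each scenario, computes the odds
#' ratio of the sub-therapeutic (`event_low`) and supra-threshold
#' (`event_high`) outcomes on XR relative to IR over the day-9 evaluation
#' window. Reported per scenario and endpoint: the mean odds ratio across
#' replicates and the across-replicate mean of the per-replicate Wald 95%
#' bounds.
#'
#' @param config A [study_config()]. Scenario set, cohort size and
#'   thresholds are taken from it; delay scenarios use its
#'   `delay_fractions`.
#' @param n_replicates Number of replicate trials (default 20).
#' @return Data frame of class `or_panel`: one row per scenario x endpoint
#'   with `or_mean`, `ci_low_mean`, `ci_high_mean`, `n_replicates`, plus
#'   the per-replicate odds ratios in the `"replicates"` attribute.
#' @export
risk_analysis <- function(config, n_replicates = 20) {
  stopifnot(inherits(config, "study_config"), n_replicates >= 1)
  scen <- .scenario_grid(config)
  scen <- scen[scen$scenario != "discontinuation", , drop = FALSE]
  acc <- list()
  for (r in seq_len(n_replicates)) {
    cohort <- sample_patients(config$pk, config$pd, config$n_patients,
                              seed = config$seed + r)
    for (form in c("IR", "XR")) {
      for (i in seq_len(nrow(scen))) {
        reg <- build_regimen(form, scen$scenario[i],
                             delay_fraction = scen$delay_fraction[i],
                             horizon = 216)
        conc <- concentration_profile(reg, cohort, step = config$step)
        resp <- bprs_profile(conc, cohort)
        ev <- risk_outcomes(conc, resp, reg$windows$reference_window,
                            reg$tau, config$low_threshold,
                            config$high_threshold)
        acc[[length(acc) + 1L]] <- data.frame(
          replicate = r, formulation = form,
          scenario = scen$label[i],
          n = nrow(cohort),
          events_low = sum(ev$event_low),
          events_high = sum(ev$event_high))
      }
    }
  }
  counts <- do.call(rbind, acc)
  out <- list(); reps <- list()
  for (lab in unique(counts$scenario)) {
    for (endp in c("low", "high")) {
      cs <- counts[counts$scenario == lab, ]
      ors <- vapply(seq_len(n_replicates), function(r) {
        xr <- cs[cs$replicate == r & cs$formulation == "XR", ]
        ir <- cs[cs$replicate == r & cs$formulation == "IR", ]
        o <- odds_ratio(xr[[paste0("events_", endp)]], xr$n,
                        ir[[paste0("events_", endp)]], ir$n)
        c(o$or, o$ci_low, o$ci_high)
      }, numeric(3))
      out[[length(out) + 1L]] <- data.frame(
        scenario = lab, endpoint = endp,
        or_mean = mean(ors[1, ]), ci_low_mean = mean(ors[2, ]),
        ci_high_mean = mean(ors[3, ]), n_replicates = n_replicates)
      reps[[paste(lab, endp)]] <- ors[1, ]
    }
  }
  panel <- do.call(rbind, out)
  attr(panel, "replicates") <- reps
  class(panel) <- c("or_panel", "data.frame")
  panel
}
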