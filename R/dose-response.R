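#' Welch two-sample t-test
#'
#' Two-sided t-test for independent samples with unequal variances
#' (Satterthwaite degrees of freedom), the comparison used for per-dose
#' activity contrasts against the control.  Thin wrapper over
#' [stats::t.test()] with one convention added: two groups with zero
#' variance and equal means return `t = 0, p = 1` instead of an error.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return A list of class `test_result`: `statistic`, `df`, `p_value`,
#'   `estimate` (mean difference a - b), `method`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need >= 2 values per group")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(statistic = 0, df = length(a) + length(b) - 2,
                            p_value = 1, estimate = 0,
                            method = "Welch t-test (degenerate)"),
                       class = "test_result"))
    }
    stop("both groups have zero variance with different means; ",
         "the t statistic is undefined")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  structure(list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    estimate = mean(a) - mean(b),
    method = "Welch t-test"
  ), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$method, "\n", sep = "")
  cat(sprintf("  t = %.4g, df = %.3g, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Classify a dose-response profile as flat, monotonic or biphasic
#'
#' For each modulator level, replicate activities are compared with the
#' control (modulator concentration 0) by a Welch test.  By default the
#' classification uses per-comparison decisions at `alpha` — the convention
#' of the assay figures this analysis mirrors — while Holm-adjusted
#' p-values across levels are always reported alongside (and drive the
#' classification when `adjust = "holm"`); with triplicate assays the Holm
#' correction costs substantial power at the observed effect sizes.  The
#' profile is `"biphasic"` (hormetic) when at least one level is
#' significantly above the control AND at least one strictly higher level is
#' significantly below it; otherwise `"monotonic_up"` / `"monotonic_down"`
#' when all significant effects share a sign, and `"flat"` when nothing is
#' significant.  Mixed significant signs that lack the low-up/high-down
#' ordering (e.g. a U-shaped profile) do not meet the hormesis definition
#' and are reported as `"flat"` with the per-level table left to speak for
#' itself.
#'
#' @param data data frame with columns `modulator_conc` (0 = control) and
#'   `activity`; replicate rows.  A `dose_response_dataset` from
#'   [gen_dose_response()] is accepted.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default, per-comparison decisions) or `"holm"`;
#'   which decision drives the classification.
#' @return A list of class `dose_response_profile`: `levels` (data frame
#'   with mean relative activity, Welch statistics, raw and adjusted
#'   p-values, significance and direction per level), `classification`,
#'   `alpha`, `adjust`.
#' @export
biphasic_test <- function(data, alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (inherits(data, "dose_response_dataset")) data <- data$data
  data <- as.data.frame(data)
  stopifnot(all(c("modulator_conc", "activity") %in% names(data)))
  m <- as.numeric(data$modulator_conc)
  if (!0 %in% m) stop("control level (modulator_conc == 0) is required")
  doses <- sort(setdiff(unique(m), 0))
  if (length(doses) < 3L) {
    stop("need >= 3 non-control modulator levels; got ", length(doses))
  }
  counts <- table(m)
  if (any(counts < 2L)) {
    stop("need >= 2 replicates per level (variance undefined otherwise)")
  }
  ctrl <- data$activity[m == 0]
  ctrl_mean <- mean(ctrl)

  tests <- lapply(doses, function(d) welch_t(data$activity[m == d], ctrl))
  p_raw <- vapply(tests, `[[`, numeric(1L), "p_value")
  p_adj <- p.adjust(p_raw, method = "holm")
  lev <- data.frame(
    modulator_conc = doses,
    mean_activity = vapply(doses, function(d) mean(data$activity[m == d]),
                           numeric(1L)),
    stringsAsFactors = FALSE
  )
  lev$relative_activity <- lev$mean_activity / ctrl_mean
  lev$statistic <- vapply(tests, `[[`, numeric(1L), "statistic")
  lev$p_raw <- p_raw
  lev$p_holm <- p_adj
  lev$direction <- sign(lev$mean_activity - ctrl_mean)
  p_use <- if (adjust == "holm") lev$p_holm else lev$p_raw
  lev$significant <- p_use < alpha
  lev$significant_raw <- lev$p_raw < alpha

  sig_up <- lev$modulator_conc[lev$significant & lev$direction > 0]
  sig_down <- lev$modulator_conc[lev$significant & lev$direction < 0]
  classification <- if (length(sig_up) && length(sig_down) &&
                        any(outer(sig_up, sig_down, `<`))) {
    "biphasic"
  } else if (length(sig_up) && !length(sig_down)) {
    "monotonic_up"
  } else if (length(sig_down) && !length(sig_up)) {
    "monotonic_down"
  } else {
    "flat"
  }

  structure(list(
    levels = lev, classification = classification,
    control_mean = ctrl_mean, alpha = alpha, adjust = adjust
  ), class = "dose_response_profile")
}

#' @export
print.dose_response_profile <- function(x, ...) {
  cat("<dose_response_profile> classification: ", x$classification,
      " (alpha = ", x$alpha, ", ", x$adjust, "-adjusted)\n", sep = "")
  df <- x$levels
  df$modulator_nM <- df$modulator_conc * 1e9
  print(df[, c("modulator_nM", "relative_activity", "p_raw", "p_holm",
               "significant")],
        digits = 4, row.names = FALSE)
  invisible(x)
}
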