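#' Convert product amounts to specific hydrolysis rates
#'
#' Enzyme assays report product formed (pmol) over a fixed incubation by a
#' fixed protein mass; the specific rate is product / (time x mass), e.g.
#' 119 pmol over 20 min by 5 ug of protein is 1.19 pmol min^-1 ug^-1.
#'
#' @param product_pmol product formed, pmol (>= 0); vectorised.
#' @param time_min incubation time, minutes (> 0).
#' @param protein_ug protein mass in the reaction, micrograms (> 0).
#' @return Rate(s) in pmol min^-1 ug^-1.
#' @export
to_rate <- function(product_pmol, time_min, protein_ug) {
  if (any(!is.finite(time_min)) || any(time_min <= 0)) {
    stop("'time_min' must be positive")
  }
  if (any(!is.finite(protein_ug)) || any(protein_ug <= 0)) {
    stop("'protein_ug' must be positive")
  }
  if (any(product_pmol < 0)) stop("'product_pmol' must be non-negative")
  product_pmol / (time_min * protein_ug)
}

#' Fit Michaelis-Menten parameters to rate data at one modulator level
#'
#' Least-squares fit of \eqn{v = V_{max} S / (K_M + S)}.  Starting values
#' come from a Hanes-Woolf linearisation (\eqn{S/v} regressed on \eqn{S}),
#' refined by Levenberg-Marquardt; standard errors are asymptotic, from the
#' Jacobian.  When even the lowest substrate concentration is near
#' saturation at the fitted \eqn{K_M} the data carry no curvature
#' information and a `KM poorly identified` warning is raised.
#'
#' @param data data frame with columns `substrate_conc` (mol/L) and `rate`
#'   (pmol min^-1 ug^-1); replicates are rows.  Alternatively raw columns
#'   `product_pmol`, `time_min`, `protein_ug` are converted via [to_rate()].
#' @return An object of class `mm_fit`: `Vmax`, `KM` (mol/L), `se` (named),
#'   `rss`, `converged`, `km_identifiable`, `n_points`, `modulator_conc`
#'   (carried from the data if constant), `fitted`.
#' @examples
#' s <- c(1, 2, 5, 10, 20, 50, 100, 200) * 1e-6
#' d <- data.frame(substrate_conc = s, rate = 1.19 * s / (5.21e-6 + s))
#' fit_mm(d)
#' @export
fit_mm <- function(data) {
  data <- as.data.frame(data)
  if (!"rate" %in% names(data)) {
    stopifnot(all(c("product_pmol", "time_min", "protein_ug") %in%
                    names(data)))
    data$rate <- to_rate(data$product_pmol, data$time_min, data$protein_ug)
  }
  stopifnot("substrate_conc" %in% names(data))
  S <- as.numeric(data$substrate_conc)
  v <- as.numeric(data$rate)
  if (any(S <= 0) || anyNA(S) || anyNA(v)) {
    stop("substrate concentrations must be positive and rates non-missing")
  }
  if (any(v < 0)) stop("rates must be non-negative")
  if (length(unique(S)) < 4L) {
    stop("need >= 4 distinct substrate concentrations; got ",
         length(unique(S)))
  }

  # Hanes-Woolf: S/v = KM/Vmax + S/Vmax (guard zero rates)
  ok <- v > 0
  hw <- lm(I(S[ok] / v[ok]) ~ S[ok])
  slope <- coef(hw)[[2L]]
  inter <- coef(hw)[[1L]]
  Vmax0 <- if (slope > 0) 1 / slope else max(v)
  KM0 <- if (slope > 0 && inter > 0) inter / slope else stats::median(S)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ Vmax * S / (KM + S),
      start = list(Vmax = Vmax0, KM = KM0),
      lower = c(Vmax = 0, KM = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("Michaelis-Menten fit did not converge")
    return(structure(list(
      Vmax = NA_real_, KM = NA_real_,
      se = c(Vmax = NA_real_, KM = NA_real_), rss = NA_real_,
      converged = FALSE, km_identifiable = NA,
      n_points = length(v), modulator_conc = modulator_level_of(data)
    ), class = "mm_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[c("Vmax", "KM")],
                 error = function(e) c(Vmax = NA_real_, KM = NA_real_))
  # saturation fraction at the lowest substrate level
  km_identifiable <- min(S) / (cf[["KM"]] + min(S)) <= 0.9
  if (!km_identifiable) {
    warning("KM poorly identified: all substrate levels are >= 90% ",
            "saturating at the fitted KM")
  }
  structure(list(
    Vmax = cf[["Vmax"]], KM = cf[["KM"]], se = se,
    rss = sum(resid(fit)^2), converged = TRUE,
    km_identifiable = km_identifiable, n_points = length(v),
    modulator_conc = modulator_level_of(data),
    fitted = data.frame(substrate_conc = S, rate = v,
                        fitted = cf[["Vmax"]] * S / (cf[["KM"]] + S))
  ), class = "mm_fit")
}

modulator_level_of <- function(data) {
  if (!"modulator_conc" %in% names(data)) return(NA_real_)
  u <- unique(as.numeric(data$modulator_conc))
  if (length(u) == 1L) u else NA_real_
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>")
  if (!is.na(x$modulator_conc)) {
    cat(" modulator ", x$modulator_conc * 1e9, " nM", sep = "")
  }
  cat("\n")
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED\n")
    return(invisible(x))
  }
  cat(sprintf("  Vmax = %.4g pmol/min/ug (SE %.2g), KM = %.4g uM (SE %.2g)\n",
              x$Vmax, x$se[["Vmax"]], x$KM * 1e6, x$se[["KM"]] * 1e6))
  cat(sprintf("  RSS = %.4g, n = %d%s\n", x$rss, x$n_points,
              if (isFALSE(x$km_identifiable)) ", KM poorly identified" else ""))
  invisible(x)
}

#' Per-modulator-level Michaelis-Menten fits and fold changes
#'
#' Splits a kinetics dataset by modulator (e.g. ABA) concentration, fits
#' each level with [fit_mm()], and reports signed percent changes of Vmax
#' and KM relative to the control (modulator concentration exactly 0, which
#' must be present).
#'
#' @param data data frame with columns `substrate_conc` (mol/L),
#'   `modulator_conc` (mol/L; 0 = control) and `rate` (or raw product
#'   columns as in [fit_mm()]).  A `kinetics_dataset` from [gen_mm()] is
#'   also accepted.
#' @return A list of class `modulator_series`: `fits` (named list of
#'   `mm_fit`, names = modulator conc in mol/L, ascending), `summary` (data
#'   frame with per-level Vmax, KM, SEs and `vmax_change_pct`,
#'   `km_change_pct` vs control).
#' @export
modulator_series <- function(data) {
  if (inherits(data, "kinetics_dataset")) data <- data$data
  data <- as.data.frame(data)
  stopifnot("modulator_conc" %in% names(data))
  levels_m <- sort(unique(as.numeric(data$modulator_conc)))
  if (!0 %in% levels_m) {
    stop("control level (modulator_conc == 0) is required")
  }
  fits <- lapply(levels_m, function(m) {
    fit_mm(data[data$modulator_conc == m, , drop = FALSE])
  })
  names(fits) <- format(levels_m, scientific = TRUE, trim = TRUE)
  ctrl <- fits[[which(levels_m == 0)]]
  if (!isTRUE(ctrl$converged)) stop("control-level fit did not converge")
  summary <- data.frame(
    modulator_conc = levels_m,
    Vmax = vapply(fits, `[[`, numeric(1L), "Vmax"),
    Vmax_se = vapply(fits, function(f) f$se[["Vmax"]], numeric(1L)),
    KM = vapply(fits, `[[`, numeric(1L), "KM"),
    KM_se = vapply(fits, function(f) f$se[["KM"]], numeric(1L)),
    row.names = NULL
  )
  summary$vmax_change_pct <- 100 * (summary$Vmax - ctrl$Vmax) / ctrl$Vmax
  summary$km_change_pct <- 100 * (summary$KM - ctrl$KM) / ctrl$KM
  structure(list(fits = fits, summary = summary, control = ctrl),
            class = "modulator_series")
}

#' @export
print.modulator_series <- function(x, ...) {
  cat("<modulator_series> ", nrow(x$summary), " modulator levels\n", sep = "")
  df <- x$summary
  df$modulator_nM <- df$modulator_conc * 1e9
  df$KM_uM <- df$KM * 1e6
  print(df[, c("modulator_nM", "Vmax", "KM_uM",
               "vmax_change_pct", "km_change_pct")],
        digits = 4, row.names = FALSE)
  invisible(x)
}
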