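#' Fraction of receptor bound under ligand depletion (Morrison equation)
#'
#' In the tight-binding regime the protein concentration is comparable to
#' the dissociation constant, so free ligand cannot be approximated by total
#' ligand and the hyperbolic isotherm fails.  The bound fraction is then the
#' physical root of the mass-action equilibrium
#' \eqn{(P_t - PL)(L_a - PL) = K_d \cdot PL}:
#' \deqn{\frac{[PL]}{[P]_t} = \frac{(P_t + L_a + K_d) -
#'   \sqrt{(P_t + L_a + K_d)^2 - 4 P_t L_a}}{2 P_t}}
#' Computed in the cancellation-free form
#' \eqn{2 L_a / (b + \sqrt{b^2 - 4 P_t L_a})} with \eqn{b = P_t + L_a + K_d};
#' a tiny negative discriminant from rounding is clamped to zero.
#'
#' @param Pt total protein concentration, mol/L (> 0).
#' @param La total ligand concentration, mol/L (>= 0); vectorised.
#' @param Kd dissociation constant, mol/L (> 0).
#' @return Bound fraction(s) in \[0, 1\].
#' @examples
#' fraction_bound(2e-9, c(0, 1, 2, 4, 8, 12, 16) * 1e-9, 5.19e-10)
#' @export
fraction_bound <- function(Pt, La, Kd) {
  if (any(!is.finite(Pt)) || any(Pt <= 0)) {
    stop("'Pt' must be positive and finite")
  }
  if (any(!is.finite(Kd)) || any(Kd <= 0)) {
    stop("'Kd' must be positive and finite")
  }
  if (any(!is.finite(La)) || any(La < 0)) {
    stop("'La' must be non-negative and finite")
  }
  b <- Pt + La + Kd
  disc <- b^2 - 4 * Pt * La
  disc[disc < 0] <- 0
  f <- 2 * La / (b + sqrt(disc))
  pmin(pmax(f, 0), 1)
}

#' Fit the quadratic ligand-depletion model to a fluorescence titration
#'
#' The observed signal is modelled as an affine map of receptor occupancy,
#' \eqn{F(L_a) = F_0 + \Delta F \cdot f_b(P_t, L_a, K_d)}, fitted by
#' nonlinear least squares over \eqn{(K_d, F_0, \Delta F)}.  The amplitude
#' sign is free in `"auto"` mode, covering both fluorescence enhancement
#' (wild-type-like) and quenching (binding-pocket mutants) in one code path.
#' Replicates are fitted jointly with shared parameters.
#'
#' Fitting uses Levenberg-Marquardt least squares with multistart
#' initialisation: \eqn{K_d} starts on a log-spaced grid spanning
#' \eqn{[10^{-2}, 10^{2}] \times} the maximum ligand concentration,
#' \eqn{F_0} from the zero-ligand points and \eqn{\Delta F} from the signal
#' span.  The lowest final residual wins; ties go to the smaller \eqn{K_d}.
#'
#' @param data data frame with columns `ligand_conc` (mol/L) and
#'   `fluorescence` (arbitrary units); an optional `replicate` column is
#'   carried through.  A `titration_dataset` from [gen_titration()] is also
#'   accepted.
#' @param protein_conc total protein concentration \eqn{P_t}, mol/L.
#' @param signal_mode `"auto"` (sign of the amplitude free),
#'   `"enhancement"` (amplitude constrained positive) or `"quenching"`
#'   (negative).
#' @param ligand_name metadata label carried into the fit object.
#' @param n_boot number of seeded residual-bootstrap refits for resampling
#'   uncertainty (0 = asymptotic standard errors only).
#' @param seed RNG seed for the bootstrap (required when `n_boot > 0`).
#' @return An object of class `binding_fit` with elements `Kd` (mol/L),
#'   `Ka` (L/mol, the exact reciprocal), `F0`, `dF`, `se` (named asymptotic
#'   standard errors), `rss`, `converged`, `saturated`, `n_points`,
#'   `n_levels`, `fitted` (data with fitted values), and optionally `boot`.
#' @export
fit_titration <- function(data, protein_conc,
                          signal_mode = c("auto", "enhancement", "quenching"),
                          ligand_name = "ABA", n_boot = 0, seed = NULL) {
  signal_mode <- match.arg(signal_mode)
  if (inherits(data, "titration_dataset")) {
    if (missing(protein_conc)) protein_conc <- data$protein_conc
    data <- data$data
  }
  data <- as.data.frame(data)
  stopifnot(all(c("ligand_conc", "fluorescence") %in% names(data)))
  if (!is.numeric(protein_conc) || protein_conc <= 0) {
    stop("'protein_conc' must be a positive concentration in mol/L")
  }
  La <- as.numeric(data$ligand_conc)
  Fobs <- as.numeric(data$fluorescence)
  if (any(La < 0) || anyNA(La) || anyNA(Fobs)) {
    stop("ligand concentrations must be non-negative and signal non-missing")
  }
  levels_La <- sort(unique(La))
  if (length(levels_La) < 4L) {
    stop("need >= 4 distinct ligand concentrations to fit; got ",
         length(levels_La))
  }
  if (min(levels_La) > 0) {
    warning("no zero-ligand baseline point; F0 initialised from the lowest ",
            "ligand level")
  }

  F0_init <- mean(Fobs[La == min(La)])
  span <- mean(Fobs[La == max(La)]) - F0_init
  if (span == 0) span <- diff(range(Fobs))
  dF_init <- switch(signal_mode,
    auto = span,
    enhancement = abs(span),
    quenching = -abs(span)
  )
  if (dF_init == 0) dF_init <- 1

  Lmax <- max(La)
  kd_grid <- 10^seq(log10(1e-2 * Lmax), log10(1e2 * Lmax), length.out = 13L)
  starts <- lapply(kd_grid, function(kd) {
    c(lKd = log10(kd), F0 = F0_init, dF = dF_init)
  })
  if (signal_mode == "auto") {
    starts <- c(starts, lapply(kd_grid, function(kd) {
      c(lKd = log10(kd), F0 = F0_init, dF = -dF_init)
    }))
  }
  bounds <- switch(signal_mode,
    auto = list(lower = c(-Inf, -Inf, -Inf), upper = c(Inf, Inf, Inf)),
    enhancement = list(lower = c(-Inf, -Inf, 0), upper = c(Inf, Inf, Inf)),
    quenching = list(lower = c(-Inf, -Inf, -Inf), upper = c(Inf, Inf, 0))
  )

  # data-driven saturation check: if every non-zero ligand level already
  # sits at >= 95% of the maximal signal deviation from baseline, the curve
  # is a stoichiometric step and Kd is not identifiable from it
  lev_mean <- vapply(levels_La, function(l) mean(Fobs[La == l]), numeric(1L))
  dev <- abs(lev_mean - lev_mean[1L])[levels_La > 0]
  pre_saturated <- length(dev) > 0 && max(dev) > 0 && all(dev >= 0.95 * max(dev))

  model <- function(p, La) {
    p[["F0"]] + p[["dF"]] * fraction_bound(protein_conc, La, 10^p[["lKd"]])
  }
  fits <- lapply(starts, function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        Fobs ~ F0 + dF * fraction_bound(protein_conc, La, 10^lKd),
        start = as.list(st),
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    warning("titration fit did not converge from any start")
    if (pre_saturated) {
      warning("all non-zero ligand levels appear saturated; Kd is poorly ",
              "identified (stoichiometric titration)")
    }
    return(structure(list(
      Kd = NA_real_, Ka = NA_real_, F0 = NA_real_, dF = NA_real_,
      se = c(Kd = NA_real_, Ka = NA_real_, F0 = NA_real_, dF = NA_real_),
      rss = NA_real_, converged = FALSE, saturated = pre_saturated,
      n_points = length(Fobs), n_levels = length(levels_La),
      protein_conc = protein_conc, ligand_name = ligand_name,
      signal_mode = signal_mode
    ), class = "binding_fit"))
  }
  rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1L))
  kds <- vapply(fits, function(f) 10^coef(f)[["lKd"]], numeric(1L))
  best <- order(rss, kds)[1L]  # smallest RSS; ties broken by smaller Kd
  fit <- fits[[best]]

  cf <- coef(fit)
  Kd <- 10^cf[["lKd"]]
  se <- tryCatch({
    v <- sqrt(diag(vcov(fit)))
    se_lKd <- v[["lKd"]]
    c(Kd = log(10) * Kd * se_lKd,          # delta method from log10 scale
      Ka = log(10) * (1 / Kd) * se_lKd,
      F0 = v[["F0"]], dF = v[["dF"]])
  }, error = function(e) {
    c(Kd = NA_real_, Ka = NA_real_, F0 = NA_real_, dF = NA_real_)
  })

  fb <- fraction_bound(protein_conc, levels_La[levels_La > 0], Kd)
  saturated <- pre_saturated || (length(fb) > 0 && all(fb > 0.95))
  if (saturated) {
    warning("all non-zero ligand levels are > 95% saturated at the fitted ",
            "Kd; Kd is poorly identified (stoichiometric titration)")
  }

  fitted_df <- data.frame(
    ligand_conc = La,
    fluorescence = Fobs,
    fitted = model(cf, La)
  )
  if ("replicate" %in% names(data)) fitted_df$replicate <- data$replicate

  out <- structure(list(
    Kd = Kd, Ka = 1 / Kd, F0 = cf[["F0"]], dF = cf[["dF"]],
    se = se, rss = sum(resid(fit)^2),
    converged = TRUE, saturated = saturated,
    n_points = length(Fobs), n_levels = length(levels_La),
    protein_conc = protein_conc, ligand_name = ligand_name,
    signal_mode = signal_mode, fitted = fitted_df
  ), class = "binding_fit")

  if (n_boot > 0) {
    if (is.null(seed)) stop("'seed' is required when n_boot > 0")
    out$boot <- with_seed(seed, {
      res <- Fobs - fitted_df$fitted
      kd_b <- vapply(seq_len(n_boot), function(b) {
        Fb <- fitted_df$fitted + sample(res, replace = TRUE)
        fb <- tryCatch(
          minpack.lm::nlsLM(
            Fb ~ F0 + dF * fraction_bound(protein_conc, La, 10^lKd),
            start = as.list(cf),
            lower = bounds$lower, upper = bounds$upper,
            control = minpack.lm::nls.lm.control(maxiter = 100)
          ),
          error = function(e) NULL
        )
        if (is.null(fb)) NA_real_ else 10^coef(fb)[["lKd"]]
      }, numeric(1L))
      kd_b <- kd_b[is.finite(kd_b)]
      list(n = length(kd_b), Kd_sd = sd(kd_b),
           Kd_ci = stats::quantile(kd_b, c(0.025, 0.975), names = FALSE))
    })
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> ligand ", x$ligand_name, ", mode ", x$signal_mode, "\n",
      sep = "")
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED (", x$n_points, " points)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  Kd = %.3g nM (SE %.2g), Ka = %.4g x 10^8 L/mol\n",
              x$Kd * 1e9, x$se[["Kd"]] * 1e9, x$Ka / 1e8))
  cat(sprintf("  F0 = %.4g, dF = %+.4g (%s), RSS = %.4g, n = %d\n",
              x$F0, x$dF, if (x$dF >= 0) "enhancement" else "quenching",
              x$rss, x$n_points))
  if (isTRUE(x$saturated)) cat("  warning: stoichiometric regime, Kd weakly identified\n")
  invisible(x)
}

#' Fold change in association constant between two fits
#'
#' @param reference the reference (e.g. wild-type) [fit_titration()] result.
#' @param variant the comparison (e.g. binding-pocket mutant) fit.
#' @return `Ka_ref / Ka_var`; values > 1 mean the variant binds more weakly.
#' @export
compare_affinities <- function(reference, variant) {
  for (f in list(reference, variant)) {
    if (!inherits(f, "binding_fit") || !isTRUE(f$converged)) {
      stop("both fits must be converged binding_fit objects")
    }
  }
  reference$Ka / variant$Ka
}

#' Classify ligand binding as specific or residual
#'
#' Ligands whose association constant falls at or below
#' `Ka_reference / threshold_fold` are classified `"residual"`.  The default
#' 100-fold threshold separates high-affinity binding (~1e9 L/mol for the
#' cognate hormone) from the ~1e6 L/mol residual interactions seen with
#' structurally related hormones.
#'
#' @param fits named list mapping ligand name to a `binding_fit` (or to a
#'   bare Ka value in L/mol).
#' @param reference name of the reference ligand (must be present).
#' @param threshold_fold fold-reduction boundary (inclusive on the residual
#'   side).
#' @return Data frame with `ligand`, `Ka`, `fold_vs_reference`, `class`.
#' @export
specificity_report <- function(fits, reference = "ABA", threshold_fold = 100) {
  if (!reference %in% names(fits)) {
    stop("reference ligand '", reference, "' missing from fits")
  }
  ka_of <- function(f) {
    if (inherits(f, "binding_fit")) {
      if (!isTRUE(f$converged)) stop("non-converged fit supplied")
      f$Ka
    } else {
      as.numeric(f)
    }
  }
  kas <- vapply(fits, ka_of, numeric(1L))
  ref_ka <- kas[[reference]]
  data.frame(
    ligand = names(kas),
    Ka = unname(kas),
    fold_vs_reference = unname(ref_ka / kas),
    class = ifelse(unname(kas) <= ref_ka / threshold_fold,
                   "residual", "specific"),
    stringsAsFactors = FALSE
  )
}
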