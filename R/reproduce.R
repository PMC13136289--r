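#' Reference study conditions
#'
#' The printed headline values of the study the generator defaults emulate,
#' collected in one place: association constants (L/mol) for the wild type
#' and the two binding-pocket mutants, Michaelis-Menten parameters for the
#' control and the 2 nM / 50 nM modulator levels, and the residual-ligand
#' affinity scale.
#'
#' @return A named list of reference parameters.
#' @export
reference_conditions <- function() {
  list(
    Ka = c(WT = 19.27e8, E657A = 4.63e8, Y678A = 2.03e8),  # L/mol
    Ka_residual = 2e6,                                     # IAA/JA scale
    protein_conc = 2e-9,                                   # mol/L
    ligand_grid = c(0, 1, 2, 4, 8, 12, 16) * 1e-9,         # mol/L
    kinetics = data.frame(
      modulator_conc = c(0, 2e-9, 5e-8),                   # mol/L
      Vmax = c(1.19, 1.58, 0.75),                          # pmol/min/ug
      KM = c(5.21e-6, 5.21e-6, 5.21e-6)                    # mol/L
    ),
    KM_10nM = 2.18e-6,                                     # mol/L
    substrate_grid = c(1, 2, 5, 10, 20, 50, 100, 200) * 1e-6
  )
}

#' Run the full synthetic-reproduction pipeline
#'
#' Orchestrates every analysis stage at the reference study conditions:
#' generates a synthetic proteome and verifies planted-motif recall;
#' generates wild-type and mutant titrations at the reference binding
#' constants and refits them; generates the modulator kinetics series and
#' refits per-level Michaelis-Menten parameters with fold changes; and
#' generates and classifies a hormetic dose-response profile.  Every
#' stochastic step derives its sub-seed from `seed`, so a rerun with the
#' same seed reproduces identical numbers.
#'
#' @param seed master RNG seed.
#' @param conditions a list as returned by [reference_conditions()].
#' @param out_dir optional directory; when given, a JSON report and TSV
#'   tables are written there.
#' @return A list of class `reproduce_report` with elements `motif`,
#'   `binding`, `kinetics`, `dose_response`, `seed`.
#' @export
reproduce <- function(seed = 1L, conditions = reference_conditions(),
                      out_dir = NULL) {
  seed <- as.integer(seed)
  sub_seed <- function(k) seed * 8L + k   # distinct stream per stage

  ## -- motif scanning on a synthetic proteome ------------------------------
  prot <- gen_proteome(seed = sub_seed(0L))
  scan <- scan_fasta(prot$sequences, prot$pattern)
  found <- vapply(seq_len(nrow(prot$truth)), function(i) {
    hits <- scan$matches[scan$matches$protein_id == prot$truth$protein_id[i], ]
    any(vapply(hits$anchor_positions, function(p) {
      paste(p, collapse = ",") == prot$truth$anchor_positions[i]
    }, logical(1L)))
  }, logical(1L))
  motif <- list(
    n_proteins = scan$n_proteins,
    n_with_match = scan$n_with_match,
    fraction_with_match = scan$fraction_with_match,
    n_planted = nrow(prot$truth),
    planted_recall = mean(found)
  )

  ## -- binding: titration fits at reference constants ----------------------
  ka_ref <- conditions$Ka
  tit <- list(
    WT = gen_titration(seed = sub_seed(1L), Kd = 1 / ka_ref[["WT"]],
                       protein_conc = conditions$protein_conc,
                       ligand_conc = conditions$ligand_grid),
    E657A = gen_titration(seed = sub_seed(2L), Kd = 1 / ka_ref[["E657A"]],
                          protein_conc = conditions$protein_conc,
                          ligand_conc = conditions$ligand_grid,
                          dF = -120),  # quenching in this mutant
    Y678A = gen_titration(seed = sub_seed(3L), Kd = 1 / ka_ref[["Y678A"]],
                          protein_conc = conditions$protein_conc,
                          ligand_conc = conditions$ligand_grid)
  )
  fits <- lapply(tit, fit_titration)
  binding <- list(
    Ka_1e8 = vapply(fits, function(f) f$Ka / 1e8, numeric(1L)),
    Kd_nM = vapply(fits, function(f) f$Kd * 1e9, numeric(1L)),
    Ka_ref_1e8 = ka_ref / 1e8,
    fold_E657A = compare_affinities(fits$WT, fits$E657A),
    fold_Y678A = compare_affinities(fits$WT, fits$Y678A),
    specificity = specificity_report(
      list(ABA = fits$WT, IAA = conditions$Ka_residual,
           JA = conditions$Ka_residual)
    ),
    fits = fits
  )

  ## -- kinetics: per-level MM fits and fold changes -------------------------
  kin <- gen_mm_series(seed = sub_seed(4L), levels = conditions$kinetics,
                       substrate_conc = conditions$substrate_grid,
                       noise_frac = 0.01)
  series <- modulator_series(kin)
  kinetics <- list(
    summary = series$summary,
    reference = conditions$kinetics,
    vmax_change_2nM_pct =
      series$summary$vmax_change_pct[series$summary$modulator_conc == 2e-9],
    vmax_change_50nM_pct =
      series$summary$vmax_change_pct[series$summary$modulator_conc == 5e-8],
    series = series
  )

  ## -- biphasic dose-response classification --------------------------------
  dr <- gen_dose_response(seed = sub_seed(5L))
  profile <- biphasic_test(dr)
  dose_response <- list(
    classification = profile$classification,
    generating_classification = dr$truth$classification,
    levels = profile$levels
  )

  report <- structure(list(
    motif = motif, binding = binding, kinetics = kinetics,
    dose_response = dose_response, seed = seed
  ), class = "reproduce_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    slim <- list(
      seed = seed,
      motif = motif,
      binding = binding[c("Ka_1e8", "Kd_nM", "Ka_ref_1e8",
                          "fold_E657A", "fold_Y678A")],
      kinetics = kinetics[c("vmax_change_2nM_pct", "vmax_change_50nM_pct")],
      kinetics_summary = kinetics$summary,
      dose_response = dose_response[c("classification",
                                      "generating_classification")]
    )
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(kinetics$summary, file.path(out_dir, "kinetics_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(profile$levels, file.path(out_dir, "dose_response.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.reproduce_report <- function(x, ...) {
  cat("<reproduce_report> seed ", x$seed, "\n\n", sep = "")
  cat("Motif scan: ", x$motif$n_with_match, "/", x$motif$n_proteins,
      " proteins with a match; planted recall ",
      sprintf("%.0f%%", 100 * x$motif$planted_recall), "\n", sep = "")
  cat("\nBinding (Ka, 10^8 L/mol; fitted vs reference):\n")
  print(data.frame(fitted = round(x$binding$Ka_1e8, 2),
                   reference = x$binding$Ka_ref_1e8))
  cat(sprintf("Fold reduction: E657A %.2f, Y678A %.2f\n",
              x$binding$fold_E657A, x$binding$fold_Y678A))
  cat("\nKinetics (per modulator level):\n")
  df <- x$kinetics$summary
  df$modulator_nM <- df$modulator_conc * 1e9
  df$KM_uM <- df$KM * 1e6
  print(df[, c("modulator_nM", "Vmax", "KM_uM", "vmax_change_pct")],
        digits = 4, row.names = FALSE)
  cat("\nDose-response classification: ", x$dose_response$classification,
      " (generating: ", x$dose_response$generating_classification, ")\n",
      sep = "")
  invisible(x)
}
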