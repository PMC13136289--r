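#' Generate a synthetic fluorescence titration in the tight-binding regime
#'
#' Emulates the study design for hormone-receptor titrations followed by
#' intrinsic tryptophan fluorescence: protein at 2 nM, ligand titrated over
#' 0-16 nM (so total ligand is comparable to both protein and Kd, and
#' ligand depletion is substantial), three replicates.  The noise-free
#' signal is exactly `F0 + dF * fraction_bound(Pt, La, Kd)`; additive
#' Gaussian noise with sd equal to `noise_frac` of the amplitude `|dF|` (or
#' an absolute `noise_sd`) is added per observation.
#'
#' @param seed RNG seed (mandatory; the caller's RNG state is untouched).
#' @param Kd generating dissociation constant, mol/L.  The default is the
#'   reciprocal of the wild-type association constant 19.27e8 L/mol
#'   (~0.52 nM).
#' @param protein_conc total protein, mol/L.
#' @param ligand_conc vector of total ligand concentrations, mol/L.
#' @param F0 baseline fluorescence, a.u.
#' @param dF signed amplitude, a.u. (negative = quenching).
#' @param noise_frac Gaussian noise sd as a fraction of `|dF|`.
#' @param noise_sd absolute noise sd (overrides `noise_frac` when given).
#' @param replicates replicate curves.
#' @param ligand_name metadata label.
#' @return A list of class `titration_dataset`: `data` (data frame
#'   `ligand_conc`, `replicate`, `fluorescence`), `protein_conc`,
#'   `ligand_name`, and `truth` (the generating parameters).
#' @export
gen_titration <- function(seed,
                          Kd = 1 / 19.27e8,
                          protein_conc = 2e-9,
                          ligand_conc = c(0, 1, 2, 4, 8, 12, 16) * 1e-9,
                          F0 = 100, dF = 180,
                          noise_frac = 0.01, noise_sd = NULL,
                          replicates = 3, ligand_name = "ABA") {
  stopifnot(Kd > 0, protein_conc > 0, all(ligand_conc >= 0), replicates >= 1)
  sd_abs <- if (is.null(noise_sd)) noise_frac * abs(dF) else noise_sd
  if (sd_abs < 0) stop("noise sd must be non-negative")
  grid <- expand.grid(ligand_conc = ligand_conc,
                      replicate = seq_len(replicates))
  mu <- F0 + dF * fraction_bound(protein_conc, grid$ligand_conc, Kd)
  eps <- with_seed(seed, rnorm(nrow(grid), 0, sd_abs))
  structure(list(
    data = data.frame(ligand_conc = grid$ligand_conc,
                      replicate = grid$replicate,
                      fluorescence = mu + eps),
    protein_conc = protein_conc,
    ligand_name = ligand_name,
    truth = list(Kd = Kd, Ka = 1 / Kd, F0 = F0, dF = dF,
                 noise_sd = sd_abs, seed = seed)
  ), class = "titration_dataset")
}

#' Generate synthetic Michaelis-Menten rate data
#'
#' Emulates the phosphodiesterase assay: rates on a substrate grid spanning
#' well below to well above KM (the default grid reaches down to 1 uM so a
#' ~5 uM KM is identifiable), three replicates, additive Gaussian noise
#' with sd a fraction of the generating Vmax.
#'
#' @param seed RNG seed (mandatory).
#' @param Vmax generating maximal rate, pmol min^-1 ug^-1 (control
#'   default 1.19).
#' @param KM generating Michaelis constant, mol/L (control default
#'   5.21 uM).
#' @param substrate_conc substrate grid, mol/L.
#' @param modulator_conc modulator (e.g. ABA) concentration for this level,
#'   mol/L.
#' @param noise_frac noise sd as a fraction of `Vmax`.
#' @param noise_sd absolute noise sd (overrides `noise_frac`).
#' @param replicates replicates per substrate level.
#' @return A list of class `kinetics_dataset`: `data` (data frame
#'   `substrate_conc`, `modulator_conc`, `replicate`, `rate`) and `truth`.
#' @export
gen_mm <- function(seed, Vmax = 1.19, KM = 5.21e-6,
                   substrate_conc = c(1, 2, 5, 10, 20, 50, 100, 200) * 1e-6,
                   modulator_conc = 0,
                   noise_frac = 0.02, noise_sd = NULL, replicates = 3) {
  stopifnot(Vmax > 0, KM > 0, all(substrate_conc > 0), replicates >= 1)
  sd_abs <- if (is.null(noise_sd)) noise_frac * Vmax else noise_sd
  if (sd_abs < 0) stop("noise sd must be non-negative")
  grid <- expand.grid(substrate_conc = substrate_conc,
                      replicate = seq_len(replicates))
  mu <- Vmax * grid$substrate_conc / (KM + grid$substrate_conc)
  eps <- with_seed(seed, rnorm(nrow(grid), 0, sd_abs))
  rate <- pmax(mu + eps, 0)  # physical rates are non-negative
  structure(list(
    data = data.frame(substrate_conc = grid$substrate_conc,
                      modulator_conc = modulator_conc,
                      replicate = grid$replicate,
                      rate = rate),
    truth = list(Vmax = Vmax, KM = KM, modulator_conc = modulator_conc,
                 noise_sd = sd_abs, seed = seed)
  ), class = "kinetics_dataset")
}

#' Generate a multi-level kinetics dataset for a modulator series
#'
#' One [gen_mm()] design per modulator level, combined into a single
#' dataset suitable for [modulator_series()].  The default levels mirror
#' the biphasic study conditions: control (Vmax 1.19), stimulation at 2 nM
#' (Vmax 1.58) and inhibition at 50 nM (Vmax 0.75), all at the control KM
#' of 5.21 uM except where a level-specific KM is supplied.
#'
#' @param seed RNG seed; level k uses `seed + k - 1`.
#' @param levels data frame with columns `modulator_conc` (mol/L), `Vmax`,
#'   `KM` (mol/L).
#' @param ... further arguments passed to [gen_mm()] (grid, noise,
#'   replicates).
#' @return A `kinetics_dataset` whose `data` spans all levels and whose
#'   `truth` is the `levels` table (plus noise and seed).
#' @export
gen_mm_series <- function(seed,
                          levels = data.frame(
                            modulator_conc = c(0, 2e-9, 5e-8),
                            Vmax = c(1.19, 1.58, 0.75),
                            KM = c(5.21e-6, 5.21e-6, 5.21e-6)
                          ),
                          ...) {
  stopifnot(all(c("modulator_conc", "Vmax", "KM") %in% names(levels)))
  parts <- lapply(seq_len(nrow(levels)), function(k) {
    gen_mm(seed = seed + k - 1L,
           Vmax = levels$Vmax[k], KM = levels$KM[k],
           modulator_conc = levels$modulator_conc[k], ...)$data
  })
  structure(list(
    data = do.call(rbind, parts),
    truth = list(levels = levels, seed = seed)
  ), class = "kinetics_dataset")
}

#' Generate replicate activities for a dose-response profile
#'
#' Per-dose effects are multiplicative on the control mean (the study
#' reports percent changes); noise is Gaussian with a constant coefficient
#' of variation.  The default profile is the observed hormetic pattern:
#' +30% at 2 nM, +15% at 10 nM, -30% at 50 and 100 nM.
#'
#' @param seed RNG seed.
#' @param control_mean control activity (arbitrary units).
#' @param effects data frame with columns `modulator_conc` (mol/L) and
#'   `effect` (signed fractional change vs control).
#' @param cv coefficient of variation of the Gaussian noise.
#' @param replicates replicates per level (control included).
#' @return A list of class `dose_response_dataset`: `data` (data frame
#'   `modulator_conc`, `replicate`, `activity`) and `truth` (effects table,
#'   the generating classification under the hormesis rule, cv, seed).
#' @export
gen_dose_response <- function(seed, control_mean = 1,
                              effects = data.frame(
                                modulator_conc = c(2, 10, 50, 100) * 1e-9,
                                effect = c(0.30, 0.15, -0.30, -0.30)
                              ),
                              cv = 0.05, replicates = 3) {
  stopifnot(control_mean > 0, cv >= 0, replicates >= 1)
  stopifnot(all(c("modulator_conc", "effect") %in% names(effects)))
  if (any(effects$modulator_conc <= 0)) {
    stop("effect levels must have positive modulator_conc (0 is the control)")
  }
  means <- c(control_mean, control_mean * (1 + effects$effect))
  conc <- c(0, effects$modulator_conc)
  grid <- expand.grid(level = seq_along(conc), replicate = seq_len(replicates))
  mu <- means[grid$level]
  eps <- with_seed(seed, rnorm(nrow(grid), 0, cv * mu))
  up <- effects$modulator_conc[effects$effect > 0]
  down <- effects$modulator_conc[effects$effect < 0]
  true_class <- if (length(up) && length(down) &&
                    any(outer(up, down, `<`))) {
    "biphasic"
  } else if (length(up) && !length(down)) {
    "monotonic_up"
  } else if (length(down) && !length(up)) {
    "monotonic_down"
  } else {
    "flat"
  }
  structure(list(
    data = data.frame(modulator_conc = conc[grid$level],
                      replicate = grid$replicate,
                      activity = mu + eps),
    truth = list(effects = effects, classification = true_class,
                 control_mean = control_mean, cv = cv, seed = seed)
  ), class = "dose_response_dataset")
}

#' Generate a background proteome with planted motif instances
#'
#' Background sequences are i.i.d. draws from a residue frequency vector
#' (uniform over the 20 standard amino acids by default, which keeps the
#' analytic per-position match probability simple).  Planted motif
#' instances are constructed anchor-by-anchor with spacer lengths drawn
#' uniformly within the gap bounds and written over a random window of the
#' chosen sequences; the exact planted anchor positions are recorded as
#' ground truth.
#'
#' @param seed RNG seed.
#' @param n_seq number of sequences.
#' @param length_range min/max sequence length (uniform).
#' @param n_planted number of sequences receiving one planted instance
#'   each (must be <= n_seq).
#' @param pattern the [motif_pattern()] to plant.
#' @param aa_freq named residue probability vector over the 20 standard
#'   amino acids (default uniform).
#' @return A list of class `proteome_dataset`: `sequences` (named character
#'   vector), `truth` (data frame `protein_id`, `start`, `end`,
#'   `anchor_positions` comma-joined), `pattern`.
#' @export
gen_proteome <- function(seed, n_seq = 50, length_range = c(200, 400),
                         n_planted = 10, pattern = aba_motif(),
                         aa_freq = NULL) {
  stopifnot(n_seq >= 1, n_planted >= 0, n_planted <= n_seq)
  if (is.null(aa_freq)) {
    aa_freq <- setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  stopifnot(all(names(aa_freq) %in% AA_STANDARD),
            abs(sum(aa_freq) - 1) < 1e-8)
  span_max <- motif_span_range(pattern)[2L]
  if (length_range[1L] < span_max) {
    stop("minimum sequence length must be >= the maximal motif span (",
         span_max, ")")
  }
  with_seed(seed, {
    lens <- length_range[1L] +
      sample.int(length_range[2L] - length_range[1L] + 1L, n_seq,
                 replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(names(aa_freq), L, replace = TRUE, prob = aa_freq),
            collapse = "")
    }, character(1L))
    names(seqs) <- sprintf("synthetic_%03d", seq_len(n_seq))
    planted_idx <- if (n_planted > 0) sample(n_seq, n_planted) else integer(0)
    truth_rows <- list()
    for (i in planted_idx) {
      gaps <- vapply(pattern$gaps, function(g) {
        g[1L] + sample.int(g[2L] - g[1L] + 1L, 1L) - 1L
      }, integer(1L))
      anchors <- vapply(pattern$anchors, function(a) {
        if (length(a) == 1L) a else sample(a, 1L)
      }, character(1L))
      k <- length(anchors)
      span <- if (k > 1L) sum(gaps) + k else 1L
      inst <- character(span)
      pos <- 1L
      positions <- integer(k)
      for (j in seq_len(k)) {
        inst[pos] <- anchors[j]
        positions[j] <- pos
        if (j < k) {
          if (gaps[j] > 0L) {
            inst[pos + seq_len(gaps[j])] <-
              sample(names(aa_freq), gaps[j], replace = TRUE, prob = aa_freq)
          }
          pos <- pos + gaps[j] + 1L
        }
      }
      start <- sample.int(nchar(seqs[i]) - span + 1L, 1L)
      substr(seqs[i], start, start + span - 1L) <- paste(inst, collapse = "")
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        protein_id = names(seqs)[i],
        start = start, end = start + span - 1L,
        anchor_positions = paste(start + positions - 1L, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
    truth <- if (length(truth_rows)) {
      do.call(rbind, truth_rows)
    } else {
      data.frame(protein_id = character(0), start = integer(0),
                 end = integer(0), anchor_positions = character(0))
    }
    structure(list(sequences = seqs, truth = truth, pattern = pattern,
                   seed = seed),
              class = "proteome_dataset")
  })
}

#' Write a synthetic proteome to FASTA
#'
#' @param proteome a `proteome_dataset` from [gen_proteome()].
#' @param file output FASTA path.
#' @return `file`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, file) {
  aa <- Biostrings::AAStringSet(proteome$sequences)
  Biostrings::writeXStringSet(aa, file)
  invisible(file)
}
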