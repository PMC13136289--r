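---
title: "Methods: motif scanning, tight-binding titrations and modulated enzyme kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scanning, tight-binding titrations and modulated enzyme kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abamod)
```

## Scientific setting

Abscisic acid (ABA), the central plant stress hormone, binds not only its
canonical PYR/PYL receptors but a growing set of multidomain proteins that
carry a conserved four-anchor binding signature.  One such protein is the
*Arabidopsis* K⁺-uptake permease AtKUP5, whose C-terminal cytoplasmic
domain is a phosphodiesterase (PDE) hydrolysing 3′,5′-cAMP to 5′-AMP.  ABA
binds this PDE with nanomolar affinity and tunes its activity biphasically:
stimulation at low nanomolar ABA, inhibition at 50 nM and above — a
hormetic dose–response.

`abamod` implements the quantitative layer of such a study as reusable,
tested components:

1. **Motif scanning** — locating the gapped ABA-binding signature
   `[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]` in protein sequences;
2. **Binding analysis** — fitting the quadratic ligand-depletion (Morrison)
   model to fluorescence titrations in the tight-binding regime;
3. **Kinetics** — Michaelis–Menten fits per modulator concentration, fold
   changes, biphasic classification, and the associated statistics (Welch
   tests, two-way ANOVA with Tukey compact letter displays);
4. **Synthetic data** — seeded generators with recorded ground truth,
   standing in for raw measurements that are not publicly deposited.

The exported functions are the interface; `reproduce()` chains all stages
into one seeded end-to-end run.

## Gapped-motif scanning

A motif is an ordered list of anchor residue classes separated by
variable-length spacers.  `scan_sequence()` enumerates **every** anchor
position tuple satisfying all gap bounds rather than reporting a single
leftmost match: the signature can span multiple binding pockets, so
alternative placements are informative.  A per-protein boolean is derived
for proteome-level counting, so overlapping alternatives never inflate the
number of motif-positive proteins.

Coordinates are 1-based inclusive throughout, matching residue numbering
conventions (E657, Y678, K685); `to_zero_based()` / `to_one_based()`
convert at I/O boundaries.  Sequences are uppercased on input; trailing
`*` terminators are stripped with a warning; ambiguity letters (X, B, Z,
U, O, J) are tolerated but deliberately never match an anchor class — a
conservative choice, since an ambiguous residue cannot be confirmed to be
a functional anchor.  The pattern is supplied as data (`parse_motif()`),
not hard-coded; `aba_motif()` is merely the default.

The overlap of a match span with an annotated feature (e.g. a PDE
catalytic center) is plain interval arithmetic:
`max(0, min(ends) - max(starts) + 1)`.  For the reference coordinates —
binding site 657–685, catalytic center 669–706 — this gives 17 residues.

## Tight-binding titration analysis

With receptor at 2 nM and ligand titrated over 0–16 nM, free ligand is
substantially depleted by binding, so the hyperbolic isotherm
\(L/(L+K_d)\) is invalid.  The bound fraction is instead the physical root
of the mass-action equilibrium \((P_t-PL)(L_a-PL) = K_d\,PL\):

\[
\frac{[PL]}{[P]_t} \;=\;
\frac{(P_t+L_a+K_d)-\sqrt{(P_t+L_a+K_d)^2-4P_tL_a}}{2P_t}.
\]

`fraction_bound()` evaluates this in the cancellation-free form
\(2L_a/(b+\sqrt{b^2-4P_tL_a})\), clamping tiny negative discriminants from
rounding to zero.  The test suite checks it against an independent
bisection solver of the mass-action equation to 1e-10 relative error on
1000 random parameter triples, and verifies convergence to the hyperbolic
isotherm in the dilute-receptor limit.

How fluorescence maps to occupancy is rarely stated in assay write-ups; we
adopt the affine model \(F = F_0 + \Delta F \cdot f_b\) with the amplitude
sign free (`signal_mode = "auto"`), so tryptophan-fluorescence
*enhancement* (wild-type-like) and *quenching* (binding-pocket mutants)
share one code path.  Negating a dataset's amplitude leaves the fitted
\(K_d\) unchanged, and the tests assert this symmetry.

Numerical choices in `fit_titration()`:

* **Parameterisation**: \(K_d\) is fitted on the log10 scale, which
  enforces positivity and makes the multistart grid natural; standard
  errors are mapped back by the delta method.
* **Multistart**: Levenberg–Marquardt from 13 log-spaced \(K_d\) starts
  spanning \(10^{-2}\)–\(10^{2}\) times the maximum ligand concentration
  (both amplitude signs in auto mode); lowest residual sum of squares
  wins, ties broken toward the smaller \(K_d\).
* **Uncertainty**: asymptotic standard errors from the Jacobian; an
  optional seeded residual bootstrap (`n_boot`) gives resampling-based
  intervals.  Published ± values rarely name their method, so both routes
  are available.
* **Diagnostics**: fewer than 4 distinct ligand levels is an error; a
  titration whose every non-zero level sits at ≥95% of the maximal signal
  deviation is flagged `saturated` (stoichiometric regime — the data bound
  \(K_d\) from above only).  Non-convergence returns a flagged object with
  `NA` parameters, never silent numbers.
* **Replicates** are fitted jointly with shared \((K_d, F_0, \Delta F)\);
  per-replicate baselines are out of scope.

Units are mol/L internally; reports express \(K_a\) in \(10^8\) L/mol and
\(K_d\) in nM, the scales used in the binding literature.

## Michaelis–Menten kinetics under a modulator series

`fit_mm()` fits \(v = V_{max} S/(K_M+S)\) by Levenberg–Marquardt with
starting values from a Hanes–Woolf linearisation (\(S/v\) on \(S\)), which
is robust for initialisation though never used for the final estimates.
The published assay used 10–200 µM substrate, which sits well above the
~5 µM \(K_M\) it reports; a grid confined to that range carries almost no
curvature information.  The synthetic default grid therefore extends down
to 1 µM so \(K_M\) is identifiable, and `fit_mm()` warns whenever even the
lowest substrate level is ≥90% saturating at the fitted \(K_M\).

`modulator_series()` fits each modulator (ABA) level separately — the
control is modulator concentration exactly 0 and must be present — and
reports signed percent changes of \(V_{max}\) and \(K_M\) against it.  At
the reference parameters (control \(V_{max}\) 1.19, 2 nM level 1.58,
50 nM level 0.75 pmol·min⁻¹·µg⁻¹) the arithmetic gives +32.8% and −37.0%.
\(K_M\) is only published for the control (5.21 µM) and the 10 nM level
(2.18 µM); the generator defaults use the control \(K_M\) for unpublished
levels, a neutral choice because \(V_{max}\) fold changes are insensitive
to it.

## Dose–response classification

`biphasic_test()` compares each dose level with the control by a Welch
test and classifies the profile:

* **biphasic** — at least one level significantly above the control *and*
  at least one strictly higher level significantly below it (hormesis);
* **monotonic_up / monotonic_down** — all significant effects share a
  sign;
* **flat** — nothing significant.  Mixed significant signs without the
  low-up/high-down ordering (a U-shape) do not meet the hormesis
  definition and also report `flat`; the per-level table is returned so
  such profiles remain visible.

The classification defaults to per-comparison decisions at α = 0.05, the
convention of the assay figures this analysis mirrors.  Holm-adjusted
p-values across levels are always reported alongside, and
`adjust = "holm"` makes them drive the classification.  The default was
chosen because with triplicate assays the Welch degrees of freedom are
tiny (2–4) and the Holm correction costs enough power that generating
profiles with 6-noise-SD effects are misclassified in over 10% of seeded
runs, while per-comparison decisions recover them in ≈98% — with only four
dose levels the family is small and the per-level table makes the
multiplicity visible.

`welch_t()` adds one convention to the standard test: two groups with zero
variance and equal means return p = 1 (no evidence of difference) instead
of an error, which keeps noise-free synthetic profiles classifiable.

## Two-way ANOVA and compact letters

`anova2_tukey()` analyses variant × dose tables with a two-way interaction
model, type-II sums of squares (identical to the classical decomposition
for balanced data, well-behaved under mild imbalance), and Tukey-adjusted
pairwise comparisons of variants within each dose level using the pooled
model variance.  Empty cells are an error naming the cells; at least two
replicates per cell are required.

`compact_letters()` builds the letter display from the pairwise p-matrix
by the insert-and-absorb algorithm: start from one set holding all groups;
for each significant pair split every set containing both members; drop
sets absorbed by supersets; one letter per surviving set.  Consistency —
shared letter ⇔ not significantly different — holds by construction and is
re-checked exhaustively in the tests on hundreds of random p-matrices with
2–6 groups.

## Synthetic data: what it does and does not emulate

Raw measurements behind the study are not publicly deposited, so all
generators are first-class, seeded, and emit machine-readable ground
truth:

* `gen_titration()` — protein 2 nM, ligand 0, 1, 2, 4, 8, 12, 16 nM,
  3 replicates, additive Gaussian noise with sd 1% of the amplitude
  \(|\Delta F|\); default \(K_d\) is the reciprocal of the wild-type
  \(K_a\) 19.27 × 10⁸ L/mol.
* `gen_mm()` / `gen_mm_series()` — substrate 1–200 µM, 3 replicates,
  noise sd 2% of \(V_{max}\) (1% for the multi-level series), rates
  truncated at zero; series defaults are the control / 2 nM / 50 nM
  parameters above.
* `gen_dose_response()` — multiplicative effects on the control mean
  (+30% at 2 nM, +15% at 10 nM, −30% at 50 and 100 nM), 5% coefficient of
  variation, n = 3.
* `gen_proteome()` — i.i.d. uniform residue background (which makes the
  expected background occurrence rate analytically exact, a property the
  tests exploit) with motif instances planted at recorded positions.

Replicate noise magnitudes are unpublished; the 1–5% defaults are
calibration choices and are stated as such here.  Gaussian additive noise
is assumed throughout — real fluorescence and LC-MS/MS readouts have
heteroscedastic, occasionally skewed errors, real proteomes are far from
i.i.d. background, and real titrations face detection limits at
sub-nanomolar ligand.  Passing recovery tests on these generators
therefore demonstrates correctness of the estimators under the stated
error model, not robustness to every artefact of real data.

Determinism contract: identical spec + seed ⇒ identical bytes, and the
generators restore the caller's RNG state.

## Problem sizes and reproduction

`reproduce(seed)` runs the full pipeline — 50-sequence proteome scan with
recall check, three titration fits, a three-level kinetics series, and a
dose–response classification — in a few seconds.  The test suite uses 100
seeded repetitions for the recovery properties (median |log10 Kd error| ≤
0.15; median \(V_{max}\) error ≤ 5%, \(K_M\) ≤ 15%), 200 random sequences
for scanner/oracle equivalence, and 1000 random triples for the
mass-action oracle; these sizes keep the whole suite well under a minute
per module while leaving the Monte-Carlo margins wide.
`scripts/acceptance.R` recomputes the headline quantities from scratch at
any seed.

## Known limitations

* One-site binding only; no competitive or two-site models, no spectral
  preprocessing (inputs are extracted peak intensities).
* Michaelis–Menten without inhibition terms; the modulator enters only
  through per-level parameters, not a mechanistic dose term.
* The biphasic classifier is a significance-pattern rule, not a fitted
  hormesis curve; it reports what the per-level tests support.
* Compact letters are per dose level; letters are not comparable across
  levels.
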