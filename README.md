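# abamod

Quantitative analysis toolkit for studies of abscisic acid (ABA) binding
to plant phosphodiesterases (PDEs), such as the PDE domain embedded in the
*Arabidopsis* K⁺ transporter AtKUP5.  Written for protein biochemists and
plant signalling groups who need the numerical layer of such a study —
motif discovery, binding constants, enzyme kinetics, dose–response
statistics — as tested, reusable R functions.

## What it computes

**Gapped-motif scanning.**  The conserved ABA-binding signature is four
anchor residue classes with bounded spacers,

```
[DE].{7,9}[RH].{8,11}[FY].{6,7}[HRK]
```

`scan_sequence()` enumerates *every* anchor placement satisfying the gap
bounds (1-based coordinates), `scan_fasta()` summarises per-protein hits,
and `feature_overlap()` measures overlap with annotated intervals such as
PDE catalytic centers.

**Tight-binding titration fitting.**  With receptor at 2 nM and ligand at
0–16 nM, free ligand ≈ total ligand fails; the bound fraction follows the
quadratic ligand-depletion (Morrison) equation

$$\frac{[PL]}{[P]_t} = \frac{(P_t+L_a+K_d)-\sqrt{(P_t+L_a+K_d)^2-4P_tL_a}}{2P_t}$$

`fit_titration()` fits $F = F_0 + \Delta F \cdot f_b(P_t, L_a, K_d)$ by
multistart nonlinear least squares, covering fluorescence enhancement and
quenching with one signed amplitude, and reports $K_d$, $K_a = 1/K_d$,
standard errors and an optional seeded bootstrap.

**Michaelis–Menten kinetics across a modulator series.**
`fit_mm()` fits $v = V_{max}S/(K_M+S)$ per ABA level;
`modulator_series()` reports percent changes versus the 0-ABA control;
`biphasic_test()` classifies the dose–response (flat / monotonic /
biphasic) from per-level Welch tests; `anova2_tukey()` runs the two-way
ANOVA with Tukey comparisons and compact letter displays.

**Synthetic data.**  Seeded generators (`gen_titration`, `gen_mm`,
`gen_mm_series`, `gen_dose_response`, `gen_proteome`) produce datasets
with the statistical structure each stage assumes, with ground truth
recorded for recovery testing.

## Worked example

```r
library(abamod)

# a synthetic wild-type-like titration (protein 2 nM, ligand 0-16 nM,
# 1% noise, 3 replicates) and its tight-binding fit
fit_titration(gen_titration(seed = 42))
#> <binding_fit> ligand ABA, mode auto
#>   Kd = 0.528 nM (SE 0.032), Ka = 18.93 x 10^8 L/mol
#>   F0 = 101.1, dF = +179.2 (enhancement), RSS = 104.4, n = 21

# kinetics at three ABA levels, fitted per level
modulator_series(gen_mm_series(seed = 42, noise_frac = 0.01))
#> <modulator_series> 3 modulator levels
#>  modulator_nM   Vmax KM_uM vmax_change_pct km_change_pct
#>             0 1.1921 5.219            0.00        0.0000
#>             2 1.5895 5.375           33.33        2.9917
#>            50 0.7473 5.177          -37.32       -0.8148

# hormetic dose-response classification
biphasic_test(gen_dose_response(seed = 42))
#> <dose_response_profile> classification: biphasic (alpha = 0.05, none-adjusted)
#>  modulator_nM relative_activity     p_raw   p_holm significant
#>             2            1.3138 0.0156126 0.031225        TRUE
#>            10            1.0822 0.0939152 0.093915       FALSE
#>            50            0.6978 0.0007199 0.002880        TRUE
#>           100            0.6736 0.0033109 0.009933        TRUE
```

Reading the output: the titration generated at the wild-type association
constant ($K_a = 19.27 \times 10^8$ L/mol, i.e. $K_d \approx 0.52$ nM) is
recovered at $18.93 \times 10^8$; the kinetics series generated at
$V_{max}$ 1.19 / 1.58 / 0.75 pmol·min⁻¹·µg⁻¹ shows +33% at 2 nM ABA and
−37% at 50 nM; and the activity profile (+30% low-dose, −30% high-dose,
5% CV) is classified biphasic.  `reproduce(seed)` chains all stages —
proteome scan with planted-motif recall, wild-type and mutant titrations,
kinetics, classification — into one seeded report.

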