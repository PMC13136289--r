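Package: abamod
Title: Motif Scanning, Tight-Binding Titrations and Enzyme Kinetics for
    Hormone-Modulated Phosphodiesterases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis toolkit for studies of abscisic acid
    (ABA) binding to plant phosphodiesterases embedded in potassium
    transporters.  Provides a gapped-anchor protein motif scanner for the
    conserved ABA-binding signature, nonlinear least-squares fitting of the
    quadratic ligand-depletion (Morrison) model to fluorescence titrations
    in the tight-binding regime, Michaelis-Menten kinetics across modulator
    concentration series with biphasic dose-response classification, the
    associated statistical comparisons (Welch t-tests, two-way ANOVA with
    Tukey compact letter displays), and seeded synthetic-data generators
    with recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
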