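test_that("fraction_bound matches limits and the mass-action oracle", {
  expect_equal(fraction_bound(2e-9, 0, 1e-9), 0)
  # infinitely tight binding reaches the stoichiometric limit min(La,Pt)/Pt
  expect_equal(fraction_bound(2e-9, 8e-9, 1e-30), 1, tolerance = 1e-9)
  expect_equal(fraction_bound(2e-9, 1e-9, 1e-30), 0.5, tolerance = 1e-9)
  expect_equal(fraction_bound(2e-9, 2e-9, 5.19e-10),
               oracle_fraction_bound(2e-9, 2e-9, 5.19e-10),
               tolerance = 1e-10)
  expect_error(fraction_bound(-1e-9, 1e-9, 1e-9), "positive")
  expect_error(fraction_bound(1e-9, -1e-9, 1e-9), "non-negative")
  expect_error(fraction_bound(1e-9, 1e-9, 0), "positive")
})

test_that("fraction_bound agrees with the bisection oracle on random triples", {
  set.seed(11)
  for (i in 1:1000) {
    Pt <- 10^runif(1, -12, -6)
    La <- 10^runif(1, -12, -6)
    Kd <- 10^runif(1, -12, -6)
    f <- fraction_bound(Pt, La, Kd)
    o <- oracle_fraction_bound(Pt, La, Kd)
    expect_equal(f, o, tolerance = 1e-10)
  }
})

test_that("fraction_bound is monotone and converges to the dilute isotherm", {
  La <- seq(0, 2e-8, length.out = 50)
  f <- fraction_bound(2e-9, La, 1e-9)
  expect_true(all(diff(f) > 0))        # nondecreasing in La
  kds <- 10^seq(-11, -7, length.out = 30)
  fk <- vapply(kds, function(k) fraction_bound(2e-9, 4e-9, k), 0)
  expect_true(all(diff(fk) < 0))       # nonincreasing in Kd
  # dilute receptor: quadratic model collapses onto La/(La + Kd)
  Kd <- 1e-9
  La <- c(0.1, 0.5, 1, 2, 10) * 1e-9
  expect_equal(fraction_bound(1e-15 * Kd, La, Kd), La / (La + Kd),
               tolerance = 1e-6)
})

test_that("titration fitting recovers noise-free parameters exactly", {
  d <- gen_titration(seed = 1, Kd = 2.16e-9, noise_sd = 0)
  fit <- fit_titration(d)
  expect_true(fit$converged)
  expect_equal(fit$Kd, 2.16e-9, tolerance = 1e-6)
  expect_equal(fit$F0, 100, tolerance = 1e-6)
  expect_equal(fit$dF, 180, tolerance = 1e-6)
  expect_equal(fit$Ka * fit$Kd, 1, tolerance = 1e-12)
})

test_that("titration fitting handles quenching symmetrically", {
  up <- gen_titration(seed = 5, Kd = 1.5e-9, dF = 150, noise_sd = 0)
  down <- up
  down$data$fluorescence <- 2 * up$truth$F0 - up$data$fluorescence
  f_up <- fit_titration(up)
  f_down <- fit_titration(down)
  expect_lt(f_down$dF, 0)
  expect_equal(f_down$Kd, f_up$Kd, tolerance = 1e-6)
  # explicit quenching data from the generator
  q <- gen_titration(seed = 6, Kd = 1 / 4.63e8, dF = -120)
  fq <- fit_titration(q, signal_mode = "quenching")
  expect_lt(fq$dF, 0)
  expect_equal(fq$Kd, 1 / 4.63e8, tolerance = 0.25)
})

test_that("titration fitting validates its inputs and flags degeneracy", {
  few <- data.frame(ligand_conc = c(0, 1e-9, 2e-9),
                    fluorescence = c(100, 150, 180))
  expect_error(fit_titration(few, protein_conc = 2e-9), ">= 4 distinct")
  # stoichiometric regime: ligand far above protein, Kd far below both
  sat <- gen_titration(seed = 2, Kd = 1e-13, protein_conc = 1e-12,
                       ligand_conc = c(0, 4, 8, 12, 16) * 1e-9,
                       noise_sd = 0.1)
  w <- capture_warnings(fs <- fit_titration(sat))
  expect_true(any(grepl("saturated", w)))
  expect_true(fs$saturated)
})

test_that("Kd recovery is unbiased across seeded replicate titrations", {
  errs <- vapply(1:100, function(s) {
    d <- gen_titration(seed = 1000 + s)
    f <- suppressWarnings(fit_titration(d))
    abs(log10(f$Kd / d$truth$Kd))
  }, numeric(1))
  expect_lte(median(errs), 0.15)
})

test_that("affinity fold changes reproduce the printed mutant contrasts", {
  # noise-free fits at the three reference constants; the fold ratios must
  # match direct arithmetic on the constants (4.16 and 9.49)
  kas <- c(WT = 19.27e8, E657A = 4.63e8, Y678A = 2.03e8)
  fits <- lapply(kas, function(ka) {
    fit_titration(gen_titration(seed = 3, Kd = 1 / ka, noise_sd = 0))
  })
  expect_equal(compare_affinities(fits$WT, fits$E657A),
               19.27 / 4.63, tolerance = 1e-4)
  expect_equal(compare_affinities(fits$WT, fits$E657A), 4.16,
               tolerance = 0.01)
  expect_equal(compare_affinities(fits$WT, fits$Y678A), 9.49,
               tolerance = 0.01)
  expect_equal(compare_affinities(fits$WT, fits$WT), 1.0)
  bad <- structure(list(converged = FALSE), class = "binding_fit")
  expect_error(compare_affinities(fits$WT, bad), "converged")
})

test_that("specificity classification separates cognate from residual", {
  rep1 <- specificity_report(list(ABA = 19.27e8, JA = 2e6, IAA = 3e6))
  expect_equal(rep1$class[rep1$ligand == "ABA"], "specific")
  expect_equal(rep1$class[rep1$ligand == "JA"], "residual")
  expect_equal(rep1$class[rep1$ligand == "IAA"], "residual")
  k <- 1e9
  expect_equal(
    specificity_report(list(ABA = k, X = k))$class, c("specific", "specific")
  )
  # boundary is inclusive on the residual side
  expect_equal(
    specificity_report(list(ABA = k, X = k / 100))$class[2], "residual"
  )
  expect_error(specificity_report(list(JA = 2e6)), "reference")
})

test_that("residual bootstrap is seeded and reproducible", {
  d <- gen_titration(seed = 4)
  f1 <- fit_titration(d, n_boot = 30, seed = 99)
  f2 <- fit_titration(d, n_boot = 30, seed = 99)
  expect_equal(f1$boot, f2$boot)
  expect_gt(f1$boot$Kd_sd, 0)
  expect_lt(f1$boot$Kd_ci[1], f1$boot$Kd_ci[2])
  expect_gt(f1$boot$n, 20)
  expect_error(fit_titration(d, n_boot = 5), "seed")
})
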