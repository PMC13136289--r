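test_that("rate conversion is product / (time x mass)", {
  expect_equal(to_rate(119, 20, 5), 1.19)
  expect_equal(to_rate(0, 20, 5), 0)
  expect_equal(to_rate(50, 10, 10), 0.5)
  expect_error(to_rate(10, 0, 5), "time")
  expect_error(to_rate(10, 20, -1), "protein")
  expect_error(to_rate(-1, 20, 5), "non-negative")
})

test_that("Michaelis-Menten fitting is exact on noise-free data", {
  d <- gen_mm(seed = 1, Vmax = 1.19, KM = 5.21e-6, noise_sd = 0)
  f <- fit_mm(d$data)
  expect_true(f$converged)
  expect_equal(f$Vmax, 1.19, tolerance = 1e-6)
  expect_equal(f$KM, 5.21e-6, tolerance = 1e-6)
  # raw product columns are converted on the fly
  raw <- data.frame(substrate_conc = d$data$substrate_conc,
                    product_pmol = d$data$rate * 20 * 5,
                    time_min = 20, protein_ug = 5)
  f_raw <- fit_mm(raw)
  expect_equal(f_raw$Vmax, f$Vmax, tolerance = 1e-8)
})

test_that("rate scaling halves Vmax and leaves KM unchanged", {
  d <- gen_mm(seed = 2, noise_sd = 0)$data
  f1 <- fit_mm(d)
  d$rate <- d$rate / 2
  f2 <- fit_mm(d)
  expect_equal(f2$Vmax, f1$Vmax / 2, tolerance = 1e-6)
  expect_equal(f2$KM, f1$KM, tolerance = 1e-6)
})

test_that("fit_mm validates input and flags saturated designs", {
  few <- data.frame(substrate_conc = c(1, 2, 5) * 1e-6, rate = c(.2, .3, .6))
  expect_error(fit_mm(few), ">= 4 distinct")
  # every substrate level >= 10x KM: no curvature information
  sat <- gen_mm(seed = 3, KM = 5.21e-6, noise_sd = 0,
                substrate_conc = c(60, 100, 150, 200, 300) * 1e-6)
  expect_warning(f <- fit_mm(sat$data), "poorly identified")
  expect_false(f$km_identifiable)
})

test_that("Vmax and KM recovery is accurate over seeded control simulations", {
  res <- t(vapply(1:100, function(s) {
    d <- gen_mm(seed = 5000 + s)   # control design, 2% noise
    f <- suppressWarnings(fit_mm(d$data))
    c(abs(f$Vmax - 1.19) / 1.19, abs(f$KM - 5.21e-6) / 5.21e-6)
  }, numeric(2)))
  expect_lte(median(res[, 1]), 0.05)
  expect_lte(median(res[, 2]), 0.15)
})

test_that("modulator series reports signed percent changes vs control", {
  d <- gen_mm_series(seed = 1, noise_sd = 0)
  ser <- modulator_series(d)
  expect_equal(ser$summary$vmax_change_pct[ser$summary$modulator_conc == 0], 0)
  expect_equal(
    ser$summary$vmax_change_pct[ser$summary$modulator_conc == 2e-9],
    100 * (1.58 - 1.19) / 1.19, tolerance = 1e-6
  )
  expect_equal(
    ser$summary$vmax_change_pct[ser$summary$modulator_conc == 5e-8],
    100 * (0.75 - 1.19) / 1.19, tolerance = 1e-6
  )
  expect_equal(
    round(ser$summary$vmax_change_pct[ser$summary$modulator_conc == 5e-8], 2),
    -36.97
  )
  no_ctrl <- d$data[d$data$modulator_conc > 0, ]
  expect_error(modulator_series(no_ctrl), "control")
})

test_that("biphasic classification follows the hormesis rule", {
  # the reference-like profile: up at low dose, down at high dose
  d <- gen_dose_response(seed = 21)
  prof <- biphasic_test(d)
  expect_equal(prof$classification, "biphasic")
  expect_equal(prof$levels$relative_activity[1], 1.3, tolerance = 0.1)

  # all levels equal to control -> flat (zero-variance convention p = 1)
  flat <- gen_dose_response(seed = 22, effects = data.frame(
    modulator_conc = c(2, 10, 50) * 1e-9, effect = c(0, 0, 0)), cv = 0)
  expect_equal(biphasic_test(flat)$classification, "flat")

  # strictly increasing significant effects -> monotonic_up
  up <- gen_dose_response(seed = 23, effects = data.frame(
    modulator_conc = c(2, 10, 50) * 1e-9, effect = c(0.2, 0.4, 0.6)),
    cv = 0.03)
  expect_equal(biphasic_test(up)$classification, "monotonic_up")

  down <- gen_dose_response(seed = 24, effects = data.frame(
    modulator_conc = c(2, 10, 50) * 1e-9, effect = c(-0.2, -0.4, -0.6)),
    cv = 0.03)
  expect_equal(biphasic_test(down)$classification, "monotonic_down")

  one_rep <- data.frame(modulator_conc = rep(c(0, 2e-9, 1e-8, 5e-8), 1),
                        activity = c(1, 1.3, 1.1, 0.7))
  expect_error(biphasic_test(one_rep), "2 replicates")
})

test_that("generated classifications are recovered at 5% CV", {
  hits <- vapply(1:40, function(s) {
    d <- gen_dose_response(seed = 3000 + s)   # +30/+15/-30/-30, cv 5%, n 3
    biphasic_test(d)$classification == d$truth$classification
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
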