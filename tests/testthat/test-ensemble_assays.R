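# Tight-binding model and fit, exponential fits, scalar conversions.

test_that("tight-binding model hits its analytic anchors", {
  expect_equal(tight_binding_model(1, 0.47, 10, 23.5, 0), 1)
  expect_equal(tight_binding_model(1, 0.47, 10, 0, 20), 1 - 0.47)
  # quadratic-root oracle for the bound complex concentration
  F0 <- 1; Bmax <- 0.47; E0 <- 10; KD <- 23.5; s <- 23.5
  roots <- polyroot(c(E0 * s, -(E0 + s + KD), 1))
  c_bound <- min(Re(roots))  # physical root: c <= min(E0, s)
  expect_equal(tight_binding_model(F0, Bmax, E0, KD, s),
               F0 - Bmax * c_bound / E0, tolerance = 1e-10)
})

test_that("tight-binding model is monotone and continuous at KD = 0", {
  s <- seq(0, 500, length.out = 200)
  f <- tight_binding_model(1, 0.47, 10, 23.5, s)
  expect_true(all(diff(f) <= 1e-12))
  f0 <- tight_binding_model(1, 0.47, 10, 0, s)
  feps <- tight_binding_model(1, 0.47, 10, 1e-9, s)
  expect_equal(f0, feps, tolerance = 1e-4)
})

test_that("noiseless titrations are recovered exactly", {
  s <- c(0, 2, 5, 10, 20, 40, 80, 160, 320, 640)
  ser <- generate_titration(titration_spec(1, 0.47, 10, 23.5, s))
  fit <- fit_tight_binding(ser)
  expect_lt(abs(fit$KD - 23.5) / 23.5, 1e-3)
  expect_lt(abs(fit$Bmax - 0.47) / 0.47, 1e-3)
  expect_lt(abs(fit$F0 - 1), 1e-3)
})

test_that("the depletion-free limit agrees with a simple hyperbola fit", {
  KD <- 100
  s <- c(0, 5, 12, 25, 50, 100, 200, 400, 800, 2000)
  # E0 << KD: depletion negligible, curve is F0 - Bmax*s/(KD+s)
  ser <- generate_titration(titration_spec(1, 0.5, 0.01, KD, s))
  fit <- fit_tight_binding(ser)
  hyp <- stats::nls(F ~ F0 - Bmax * s / (KD + s), data = ser,
                    start = list(F0 = 1, Bmax = 0.4, KD = 50))
  expect_lt(abs(fit$KD - coef(hyp)[["KD"]]) / coef(hyp)[["KD"]], 0.01)
})

test_that("flat titrations flag KD as unidentifiable", {
  ser <- data.frame(s = c(0, 10, 50, 200, 800), F = rep(1, 5))
  attr(ser, "E0") <- 10
  fit <- suppressWarnings(fit_tight_binding(ser))
  expect_lt(abs(fit$Bmax), 1e-6)
  expect_false(fit$kd_identifiable)
})

test_that("KD bias stays below 2% over 50 noisy seeded titrations", {
  s <- exp(seq(log(1), log(1000), length.out = 20))
  kds <- vapply(1:50, function(i) {
    ser <- generate_titration(titration_spec(1, 0.47, 10, 23.5, s,
                                             noise_sd = 0.01 * 0.47,
                                             seed = 2000 + i))
    suppressWarnings(fit_tight_binding(ser, seed = 1))$KD
  }, numeric(1))
  expect_lt(abs(mean(kds) - 23.5) / 23.5, 0.02)
})

test_that("single-exponential fits match the closed form and t_half", {
  tr <- generate_decay(decay_spec(rates = 0.1, amplitudes = 1, offset = 0.2,
                                  duration = 60, dt = 0.1))
  fit <- fit_exponentials(tr, n_components = 1)
  expect_equal(fit$rates, 0.1, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.1, tolerance = 1e-4)
  expect_equal(sum(fit$amplitudes_normalised), 1)
})

test_that("noiseless single-exponential equals log-linear regression", {
  tr <- generate_decay(decay_spec(rates = 0.3, amplitudes = 2, offset = 0,
                                  duration = 15, dt = 0.05))
  fit <- fit_exponentials(tr, n_components = 1)
  loglin <- stats::lm(log(F) ~ time, data = tr)
  expect_equal(fit$rates, -unname(coef(loglin)[2]), tolerance = 1e-6)
})

test_that("double exponentials are resolved, with or without fixed rates", {
  tr <- generate_decay(decay_spec(rates = c(0.5, 0.05),
                                  amplitudes = c(0.6, 0.4),
                                  offset = 0.1, duration = 120, dt = 0.05))
  fit <- fit_exponentials(tr, n_components = 2)
  expect_equal(fit$rates, c(0.5, 0.05), tolerance = 1e-3)
  # fix the slow rate at truth, float the fast one
  fit2 <- fit_exponentials(tr, n_components = 2, fixed_rates = c(NA, 0.05))
  expect_lt(abs(fit2$rates[1] - 0.5) / 0.5, 0.01)
  expect_equal(sum(fit2$amplitudes_normalised), 1)
})

test_that("proximity ratio and turnover conversions are exact arithmetic", {
  expect_equal(proximity_ratio(300, 700), 0.7)
  expect_equal(proximity_ratio(5, 5), 0.5)
  expect_equal(proximity_ratio(5, 0), 0)
  expect_error(proximity_ratio(0, 0), "positive")
  expect_equal(atpase_turnover(0.00622, 1e-6), 1)
  expect_equal(atpase_turnover(0.00622, 2e-6), 0.5)
  expect_equal(atpase_turnover(0, 1e-6), 0)
  expect_error(atpase_turnover(0.1, 0), "positive")
})

test_that("efficiency-to-distance conversion is calibrated and monotone", {
  expect_equal(efret_to_distance(0.5, R0 = 6), 6)
  expect_equal(efret_to_distance(0.76, R0 = 6),
               6 * (1 / 0.76 - 1)^(1 / 6), tolerance = 1e-12)
  e <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(efret_to_distance(e)) < 0))
  expect_error(efret_to_distance(1.2), "inside")
})
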