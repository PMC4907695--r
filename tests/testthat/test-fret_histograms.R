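# Histogram construction, replicate averaging, the staged global fit,
# orientation correction, ANOVA errors, anisotropy.

test_that("histogram binning is half-open with out-of-range logging", {
  h <- build_histogram(c(0.1, 0.1, 0.9), bin_edges = c(0, 0.5, 1))
  expect_equal(h$counts, c(2, 1))
  expect_equal(h$n_dropped, 0)
  h2 <- build_histogram(numeric(0), bin_edges = c(0, 0.5, 1))
  expect_equal(h2$counts, c(0, 0))
  # boundary values go in the right-hand bin; top edge is excluded
  h3 <- build_histogram(c(0, 0.5, 1, -0.1, 1.3), bin_edges = c(0, 0.5, 1))
  expect_equal(h3$counts, c(1, 1))
  expect_equal(h3$n_dropped, 3)
  expect_error(build_histogram(1, bin_edges = 0.5), "two bin edges")
  expect_error(build_histogram(1, bin_edges = c(0, 0)), "increasing")
})

test_that("histogram totals are conserved up to the dropped count", {
  x <- sample_mixture(lateral_gate_mixture(n_per_replicate = 200,
                                           n_replicates = 1, seed = 2))[[1]]
  h <- build_histogram(x)
  expect_equal(sum(h$counts) + h$n_dropped, 200)
})

test_that("replicate averaging produces per-bin mean and SEM", {
  mk <- function(counts) {
    h <- build_histogram(numeric(0), bin_edges = c(0, 0.5, 1))
    h$counts <- counts
    h
  }
  avg <- average_replicates(list(mk(c(0, 2)), mk(c(2, 0))))
  expect_equal(avg$mean, c(1, 1))
  expect_equal(avg$sem, c(1, 1))  # SD = sqrt(2), n = 2
  same <- average_replicates(list(mk(c(3, 4)), mk(c(3, 4))))
  expect_equal(same$sem, c(0, 0))
  h_other <- build_histogram(numeric(0), bin_edges = c(0, 1))
  expect_error(average_replicates(list(mk(c(1, 1)), h_other)),
               "mismatched")
})

test_that("staged fit requires an alone condition", {
  hs <- make_histogram_set(list(ATP = c(1, 1, 1) / 3), seed = 1)
  expect_error(fit_staged_mixture(hs), class = "lgfret_protocol")
})

test_that("single-component data leaves the other amplitudes near zero", {
  hs <- make_histogram_set(list(alone = c(1, 0, 0), high = c(1, 0, 0)),
                           seed = 3)
  fit <- fit_staged_mixture(hs, n_starts = 3, seed = 1)
  amp <- fit$condition_amplitudes["high", ]
  expect_lt(sum(amp[c("part_open", "open")]) / sum(amp), 0.05)
  expect_equal(unname(fit$components$mean[1]), 0.76, tolerance = 0.02)
})

test_that("a noiseless model curve is fitted with near-zero residual", {
  edges <- default_bin_edges()
  p <- diff(stats::pnorm(edges, 0.6, fwhm_to_sigma(0.2)))
  h <- build_histogram(numeric(0), edges, condition = "x", replicate = 1)
  h$counts <- 600 * p
  fit <- compare_k_fits(average_replicates(list(h)), k_values = 1,
                        n_starts = 3)
  expect_lt(fit$rss[1], 1e-4)
})

test_that("staged fit recovers the three-state parameters from a rich set", {
  hs <- make_histogram_set(lateral_gate_conditions(), seed = 8)
  fit <- fit_staged_mixture(hs, seed = 1)
  expect_equal(fit$components$state, c("closed", "part_open", "open"))
  expect_equal(unname(fit$components$mean), c(0.76, 0.59, 0.45),
               tolerance = 0.12)
  expect_true(all(diff(fit$components$mean) < 0))
  # replicate amplitudes exist for every condition x replicate x state
  expect_equal(nrow(fit$replicate_amplitudes),
               length(lateral_gate_conditions()) * 3 * 3)
  expect_true(all(fit$replicate_amplitudes$amplitude >= 0))
})

test_that("orientation correction is linear and fixes the alone identity", {
  alone <- c(0.9, 0.07, 0.03)
  expect_equal(orientation_correct(alone, alone), alone)
  cond <- c(0.6, 0.3, 0.1)
  corr <- orientation_correct(cond, c(1, 0, 0))
  expect_equal(corr, c(0.2, 0.6, 0.2))
  expect_equal(sum(corr), 1)  # preserved for unit-sum inputs
  expect_warning(out <- orientation_correct(c(0.1, 0.9, 0), c(1, 0, 0)),
                 "floored")
  expect_equal(out[1], 0)
  expect_error(orientation_correct(1:3, 1:2), "equal length")
})

test_that("amplitude ANOVA reproduces the one-group SD/sqrt(n) identity", {
  d <- data.frame(condition = "ATP", replicate = 1:3, state = "closed",
                  amplitude = c(0.2, 0.4, 0.6))
  res <- anova_amplitudes(d)
  expect_equal(res$mean, 0.4)
  expect_equal(res$sem, sqrt(0.04 / 3), tolerance = 1e-10)
  d0 <- transform(d, amplitude = 0.5)
  expect_equal(anova_amplitudes(d0)$sem, 0)
  expect_error(anova_amplitudes(d[1, ]), class = "lgfret_insufficient")
})

test_that("amplitude ANOVA pools residual variance across conditions", {
  d <- expand.grid(condition = c("a", "b"), replicate = 1:3)
  d$state <- "open"
  d$amplitude <- c(1, 5, 2, 6, 3, 7)  # per-condition values 1,2,3 / 5,6,7
  res <- anova_amplitudes(d)
  fit <- stats::aov(amplitude ~ condition, data = d)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  expect_equal(res$sem, rep(sqrt(mse / 3), 2))
  expect_equal(sort(res$mean), c(2, 6))
})

test_that("anisotropy follows the standard G-corrected expression", {
  expect_equal(compute_anisotropy(2, 1, G = 1), 0.25)
  expect_equal(compute_anisotropy(3, 1, G = 3), 0)
  expect_equal(compute_anisotropy(5, 0), 1)
  expect_error(compute_anisotropy(0, 0), "positive")
})
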