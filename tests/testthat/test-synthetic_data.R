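# Synthetic-data generators: analytic levels, determinism, statistics.

test_that("noiseless trace has exact piecewise-constant donor levels", {
  p <- trace_params(noise_sd = 0, fret_efficiency_true = 0.6,
                    donor_brightness = 1000, background_mean = 0,
                    acceptor_bleach_rate = 0.1, donor_bleach_rate = 0.05,
                    n_frames = 300, seed = 7)
  tr <- generate_intensity_trace(p)
  fa <- attr(tr, "acceptor_bleach_frame")
  fd <- attr(tr, "donor_bleach_frame")
  expect_true(fa < fd)
  expect_equal(unique(tr$donor_counts[tr$frame < fa]), 400)
  expect_equal(unique(tr$donor_counts[tr$frame >= fa & tr$frame < fd]), 1000)
  expect_equal(unique(tr$donor_counts[tr$frame >= fd]), 0)
  # acceptor mirrors: sensitised emission then background
  expect_equal(unique(tr$acceptor_counts[tr$frame < fa]), 600)
  expect_equal(unique(tr$acceptor_counts[tr$frame >= fa]), 0)
})

test_that("zero bleach rates give a single flat FRET phase", {
  tr <- generate_intensity_trace(trace_params(
    noise_sd = 0, acceptor_bleach_rate = 0, donor_bleach_rate = 0,
    background_mean = 50, donor_brightness = 800,
    fret_efficiency_true = 0.5, n_frames = 120, seed = 1))
  expect_true(is.na(attr(tr, "acceptor_bleach_frame")))
  expect_true(is.na(attr(tr, "donor_bleach_frame")))
  expect_equal(unique(tr$donor_counts), 50 + 800 * 0.5)
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- trace_params(seed = 42)
  expect_identical(generate_intensity_trace(p),
                   generate_intensity_trace(p))
  spec <- lateral_gate_mixture(seed = 42)
  expect_identical(sample_mixture(spec), sample_mixture(spec))
  dspec <- decay_spec(rates = 0.3, amplitudes = 1, noise_sd = 0.05,
                      seed = 42)
  expect_identical(generate_decay(dspec), generate_decay(dspec))
  tspec <- titration_spec(1, 0.5, 10, 20, c(0, 10, 50), noise_sd = 0.01,
                          seed = 42)
  expect_identical(generate_titration(tspec), generate_titration(tspec))
})

test_that("trace segment means match the analytic construction", {
  p <- trace_params(noise_sd = 30, fret_efficiency_true = 0.76,
                    donor_brightness = 1000, background_mean = 100,
                    n_frames = 500, seed = 3)
  tr <- generate_intensity_trace(p)
  fa <- attr(tr, "acceptor_bleach_frame")
  fd <- attr(tr, "donor_bleach_frame")
  segs <- list(
    list(idx = tr$frame < fa, level = 100 + 1000 * (1 - 0.76)),
    list(idx = tr$frame >= fa & tr$frame < fd, level = 100 + 1000),
    list(idx = tr$frame >= fd, level = 100)
  )
  for (s in segs) {
    n <- sum(s$idx)
    expect_lt(abs(mean(tr$donor_counts[s$idx]) - s$level),
              3 * 30 / sqrt(n))
  }
})

test_that("mixture sampling respects degenerate and empty specs", {
  one <- mixture_spec(data.frame(mean = 0.5, width = 1e-6, weight = 1),
                      n_per_replicate = 50, n_replicates = 2, seed = 1)
  reps <- sample_mixture(one)
  expect_equal(reps[[1]], rep(0.5, 50), tolerance = 1e-5)
  empty <- mixture_spec(data.frame(mean = 0.5, width = 0.1, weight = 1),
                        n_per_replicate = 0, n_replicates = 1, seed = 1)
  expect_identical(sample_mixture(empty)[[1]], numeric(0))
  expect_error(
    mixture_spec(data.frame(mean = c(0.3, 0.7), width = c(0.1, 0.1),
                            weight = c(0.6, 0.5))),
    "sum to 1")
})

test_that("mixture sample mean obeys the law of large numbers", {
  spec <- mixture_spec(data.frame(mean = 0.76, width = 0.24, weight = 1),
                       n_per_replicate = 1e5, n_replicates = 1, seed = 5)
  x <- sample_mixture(spec)[[1]]
  se <- fwhm_to_sigma(0.24) / sqrt(1e5)
  expect_lt(abs(mean(x) - 0.76), 3 * se)
  # draws are not truncated to the unit interval
  spec2 <- mixture_spec(data.frame(mean = 0.9, width = 0.4, weight = 1),
                        n_per_replicate = 1e4, n_replicates = 1, seed = 6)
  expect_gt(sum(sample_mixture(spec2)[[1]] > 1), 0)
})

test_that("titration generator hits the analytic limits", {
  s <- c(0, 23.5, 1e9 * 23.5)
  tser <- generate_titration(titration_spec(1, 0.47, 10, 23.5, s))
  expect_equal(tser$F[1], 1)
  expect_equal(tser$F[3], 1 - 0.47, tolerance = 1e-4)
  # stoichiometric full binding when KD = 0 and s = E0
  t0 <- generate_titration(titration_spec(1, 0.47, 10, 0, 10))
  expect_equal(t0$F, 1 - 0.47)
  expect_error(titration_spec(1, 0.47, 0, 23.5, 10), "E0")
})

test_that("decay generator satisfies the half-life identity", {
  k <- 0.2
  d <- generate_decay(decay_spec(rates = k, amplitudes = 2, offset = 1,
                                 duration = 40, dt = log(2) / k / 100))
  f_half <- stats::approx(d$time, d$F, xout = log(2) / k)$y
  expect_equal(f_half - 1, 1, tolerance = 1e-6)
  flat <- generate_decay(decay_spec(rates = 1, amplitudes = 0, offset = 3,
                                    duration = 5, dt = 0.5))
  expect_equal(unique(flat$F), 3)
  expect_error(decay_spec(rates = 1, amplitudes = c(1, 2)), "equal length")
})
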