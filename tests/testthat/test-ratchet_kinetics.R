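# Gillespie two-state simulation, TIRF emulation, dwell statistics.

test_that("overwhelming reverse rate pins occupancy in the high state", {
  m <- two_state_model(k_cat = 0.27, k_cleave = 1e6, total_time = 50)
  traj <- simulate_two_state(m, seed = 1)
  expect_gt(mean(traj$states == "high"), 1 - 1e-3)
})

test_that("occupancy matches the alternating-renewal stationary law", {
  m <- two_state_model(total_time = 2000)
  traj <- simulate_two_state(m, seed = 2)
  occ <- mean(traj$states == "high")
  p <- stationary_occupancy(m)
  expect_equal(p, 11.5 / (0.27 + 11.5))
  # binomial SE with the number of high-state visits as effective n
  n_cycles <- sum(traj$dwells$state == "high")
  se <- sqrt(p * (1 - p) / n_cycles)
  expect_lt(abs(occ - p), 3 * se)
})

test_that("mean high-state dwell equals the ADP release time", {
  m <- two_state_model(total_time = 2200)
  traj <- simulate_two_state(m, seed = 3)
  d <- traj$dwells
  high <- d$duration[d$state == "high" & d$complete]
  expect_gt(length(high), 500)
  expect_lt(abs(mean(high) - 1 / 0.27), 3 * sd(high) / sqrt(length(high)))
  # dwell durations tile the whole trajectory
  expect_equal(sum(d$duration), m$total_time)
  expect_true(all(d$state[-1] != d$state[-nrow(d)]))
})

test_that("dwell-rate MLE recovers both rates from a long trajectory", {
  m <- two_state_model(total_time = 2000)
  traj <- simulate_two_state(m, seed = 4)
  est <- estimate_dwell_rates(traj)
  for (row in seq_len(nrow(est))) {
    truth <- if (est$state[row] == "high") m$k_cat else m$k_cleave
    expect_lt(abs(est$rate[row] - truth), 3 * est$se[row] + 0.01 * truth)
  }
})

test_that("dwell-rate MLE has the closed-form value on constant dwells", {
  d <- data.frame(state = "high", duration = rep(2, 25), complete = TRUE)
  est <- estimate_dwell_rates(d)
  expect_equal(est$rate, 0.5)
  expect_equal(est$se, 0.5 / sqrt(25))
  single <- data.frame(state = "high", duration = 2, complete = TRUE)
  expect_error(estimate_dwell_rates(single), class = "lgfret_insufficient")
})

test_that("dwell samples pass a KS test against the generating exponential", {
  m <- two_state_model(total_time = 400)
  pass <- 0L
  for (i in 1:20) {
    traj <- simulate_two_state(m, seed = 100 + i)
    d <- traj$dwells
    low <- d$duration[d$state == "low" & d$complete]
    # grid discretisation: jitter within the 1 ms step before testing
    set.seed(i)
    low <- low - runif(length(low), 0, m$dt)
    p <- suppressWarnings(stats::ks.test(low, "pexp", m$k_cleave)$p.value)
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass / 20, 0.95)
})

test_that("TIRF emulation is exact in the noiseless static limit", {
  m <- two_state_model(k_cat = 1e-9, k_cleave = 1e6, noise_width = 1e-12,
                       total_time = 10)
  traj <- simulate_two_state(m, seed = 5)
  tr <- emulate_tirf(traj, seed = 6)
  expect_equal(unique(round(tr$E, 9)), m$E_high)
  expect_equal(nrow(tr), 10 / 0.2)
})

test_that("window equal to dt is the identity up to noise", {
  m <- two_state_model(noise_width = 1e-12, window = 0.001,
                       total_time = 2)
  traj <- simulate_two_state(m, seed = 7)
  tr <- emulate_tirf(traj, seed = 8)
  e_states <- ifelse(traj$states == "high", m$E_high, m$E_low)
  expect_equal(tr$E, e_states, tolerance = 1e-9)
})

test_that("window averaging conserves the trajectory mean", {
  m <- two_state_model(total_time = 600)
  traj <- simulate_two_state(m, seed = 9)
  tr <- emulate_tirf(traj, seed = 10)
  e_states <- ifelse(traj$states == "high", m$E_high, m$E_low)
  sigma <- fwhm_to_sigma(m$noise_width)
  se <- sigma / sqrt(length(e_states))
  expect_lt(abs(mean(tr$E) - mean(e_states)), 3 * se + 1e-6)
})

test_that("ADP-like kinetics give a single histogram peak at the closed E", {
  m <- two_state_model(k_cat = 0.27, k_cleave = 1e9, total_time = 600)
  traj <- simulate_two_state(m, seed = 11)
  h <- trajectory_histogram(emulate_tirf(traj, seed = 12))
  expect_equal(h$mids[which.max(h$counts)], 0.775, tolerance = 0.06)
})

test_that("ATP kinetics shift the peak only slightly, no third feature", {
  m <- two_state_model(total_time = 600)
  traj <- simulate_two_state(m, seed = 13)
  h <- trajectory_histogram(emulate_tirf(traj, seed = 14))
  modal <- h$mids[which.max(h$counts)]
  # modal bin adjacent to the high-FRET peak, not at the intermediate E
  expect_lt(abs(modal - 0.76), 0.08)
  mid_region <- h$counts[h$mids > 0.5 & h$mids < 0.62]
  expect_lt(max(mid_region), max(h$counts) / 2)
})

test_that("symmetric rates without noise give two equal peaks", {
  # zero noise: E_low = 0.45 sits exactly on a bin edge, so any jitter
  # would split that peak across two bins
  m <- two_state_model(k_cat = 1, k_cleave = 1, noise_width = 0,
                       window = 0.001, total_time = 1000)
  traj <- simulate_two_state(m, seed = 15)
  h <- trajectory_histogram(emulate_tirf(traj, seed = 16))
  peaks <- sort(h$counts, decreasing = TRUE)[1:2]
  expect_lt(abs(peaks[1] - peaks[2]) / sum(peaks), 0.05)
})

test_that("oversized trajectories trigger the memory cap", {
  m <- two_state_model(total_time = 600)
  expect_error(simulate_two_state(m, seed = 1, max_steps = 1e4),
               class = "lgfret_size")
})
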