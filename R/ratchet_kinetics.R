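# Gillespie simulation of the two-state (closed/open) channel, TIRF
# sampling emulation, and dwell-time analysis. The closed, ADP-bound state
# emits high FRET; nucleotide exchange opens the channel to a short-lived
# low-FRET state.

#' Two-state kinetic model of channel opening and closing
#'
#' Defaults are the measured ATPase-cycle constants: the high-FRET
#' (closed, ADP-bound) state is left at `k_cat` = 0.27 1/s, the rate of
#' ADP release; the low-FRET (open, ATP-bound) state is left at
#' `k_cleave` = 11.5 1/s, the rate of ATP hydrolysis and phosphate
#' release. Emission levels are the closed/open FRET efficiencies 0.76
#' and 0.45; `noise_width` (0.24, FWHM) matches the width of the high
#' FRET peak.
#'
#' @param k_cat Exit rate from the high-FRET state, 1/s.
#' @param k_cleave Exit rate from the low-FRET state, 1/s.
#' @param E_high,E_low Emission FRET efficiencies of the two states.
#' @param noise_width FWHM of the added Gaussian noise (FRET units).
#' @param dt Simulation time step, s (default 1 ms).
#' @param window TIRF averaging window, s (default 0.2 = 200 ms).
#' @param total_time Total simulated time, s (default 600).
#' @return Object of class `two_state_model`.
#' @export
two_state_model <- function(k_cat = 0.27, k_cleave = 11.5,
                            E_high = 0.76, E_low = 0.45,
                            noise_width = 0.24, dt = 0.001,
                            window = 0.2, total_time = 600) {
  check_scalar_num(k_cat, "k_cat", 0, strict_lower = TRUE)
  check_scalar_num(k_cleave, "k_cleave", 0, strict_lower = TRUE)
  check_scalar_num(dt, "dt", 0, strict_lower = TRUE)
  if (window < dt) stop_invalid("window must be >= dt")
  if (total_time < window) stop_invalid("total_time must be >= window")
  structure(
    list(k_cat = k_cat, k_cleave = k_cleave, E_high = E_high,
         E_low = E_low, noise_width = noise_width, dt = dt,
         window = window, total_time = total_time),
    class = "two_state_model"
  )
}

#' Gillespie simulation of the two-state trajectory
#'
#' Draws alternating exponential dwells (high with mean `1/k_cat`, low
#' with mean `1/k_cleave`), starting in the high (ADP-bound) state since
#' ADP release is rate limiting, and maps them onto the `dt` grid by
#' rounding up to at least one step.
#'
#' @param model A [two_state_model()].
#' @param seed Integer seed or `NULL`.
#' @param max_steps Memory cap on the number of grid steps (default 2e7).
#' @return Object of class `state_trajectory`: `times` (s), `states`
#'   (`"high"`/`"low"` per step), `dwells` (data frame: `state`,
#'   `duration` in s on the grid, `complete`), and the model.
#' @export
simulate_two_state <- function(model, seed = NULL, max_steps = 2e7) {
  stopifnot(inherits(model, "two_state_model"))
  n_steps <- round(model$total_time / model$dt)
  if (n_steps > max_steps) {
    stop(errorCondition(
      paste0("trajectory of ", n_steps, " steps exceeds cap ", max_steps),
      class = c("lgfret_size", "error")))
  }
  with_seed_(seed, {
    states <- integer(n_steps)  # 1 = high, 2 = low
    dwell_state <- character(0); dwell_len <- integer(0)
    filled <- 0L
    cur <- 1L
    rates <- c(model$k_cat, model$k_cleave)
    while (filled < n_steps) {
      tau <- stats::rexp(1, rates[cur])
      len <- max(1, ceiling(tau / model$dt))  # double: may exceed .Machine
      take <- as.integer(min(len, n_steps - filled))
      states[(filled + 1L):(filled + take)] <- cur
      dwell_state <- c(dwell_state, c("high", "low")[cur])
      dwell_len <- c(dwell_len, take)
      filled <- filled + take
      cur <- 3L - cur
    }
    dwells <- data.frame(
      state = dwell_state,
      duration = dwell_len * model$dt,
      complete = c(rep(TRUE, length(dwell_len) - 1L), FALSE)
    )
    # the first dwell is left-censored only if the process started mid-dwell;
    # here it starts at a transition, so only the last dwell is truncated
    structure(
      list(times = (seq_len(n_steps) - 1) * model$dt,
           states = c("high", "low")[states],
           dwells = dwells, model = model),
      class = "state_trajectory"
    )
  })
}

#' Emulate TIRF sampling of a simulated trajectory
#'
#' Assigns each `dt` step its state's FRET efficiency, adds per-step
#' Gaussian noise of FWHM `noise_width` (noise first, then averaging,
#' so the post-average noise SD is `sigma / sqrt(window/dt)`), and
#' boxcar-averages over non-overlapping windows of length `window`.
#'
#' @param traj A `state_trajectory` from [simulate_two_state()].
#' @param model Optional [two_state_model()]; defaults to the trajectory's.
#' @param seed Integer seed or `NULL`.
#' @return Data frame of class `sim_fret_trace` with columns `time`
#'   (window centre, s) and `E`.
#' @export
emulate_tirf <- function(traj, model = NULL, seed = NULL) {
  stopifnot(inherits(traj, "state_trajectory"))
  if (is.null(model)) model <- traj$model
  m <- model$window / model$dt
  if (abs(m - round(m)) > 1e-8) {
    warning("window is not a multiple of dt; rounding to ",
            round(m), " steps")
  }
  m <- max(1L, as.integer(round(m)))
  e <- ifelse(traj$states == "high", model$E_high, model$E_low)
  with_seed_(seed, {
    if (model$noise_width > 0) {
      e <- e + stats::rnorm(length(e), 0,
                            fwhm_to_sigma(model$noise_width))
    }
    n_win <- floor(length(e) / m)
    e <- e[seq_len(n_win * m)]
    avg <- colMeans(matrix(e, nrow = m))
    out <- data.frame(
      time = (seq_len(n_win) - 0.5) * m * model$dt,
      E = avg
    )
    class(out) <- c("sim_fret_trace", "data.frame")
    out
  })
}

#' Histogram of a simulated TIRF FRET trace
#'
#' Thin wrapper over [build_histogram()] for simulated traces.
#'
#' @param sim_trace A `sim_fret_trace` (or numeric vector of E values).
#' @param bin_edges Bin edges (default [default_bin_edges()]).
#' @param condition Condition label for the histogram.
#' @return A `fret_histogram`.
#' @export
trajectory_histogram <- function(sim_trace,
                                 bin_edges = default_bin_edges(),
                                 condition = "simulated") {
  e <- if (is.data.frame(sim_trace)) sim_trace$E else sim_trace
  build_histogram(e, bin_edges, condition = condition)
}

#' Maximum-likelihood dwell-rate estimates from a trajectory
#'
#' Exponential rate `1/mean(dwell)` per state with `SE = rate / sqrt(n)`,
#' using complete dwells only (the censored first/last dwells are
#' excluded).
#'
#' @param traj A `state_trajectory`, or a data frame of dwells with
#'   columns `state`, `duration`, `complete`.
#' @param min_dwells Minimum complete dwells required per state
#'   (default 10).
#' @return Data frame with `state`, `rate` (1/s), `se`, `n`.
#' @export
estimate_dwell_rates <- function(traj, min_dwells = 10) {
  dwells <- if (inherits(traj, "state_trajectory")) traj$dwells else traj
  stopifnot(all(c("state", "duration") %in% names(dwells)))
  if ("complete" %in% names(dwells)) {
    dwells <- dwells[dwells$complete, , drop = FALSE]
  }
  out <- lapply(split(dwells, dwells$state), function(d) {
    n <- nrow(d)
    if (n < min_dwells) {
      stop(errorCondition(
        paste0("only ", n, " complete dwells in state ", d$state[1],
               "; need >= ", min_dwells),
        class = c("lgfret_insufficient", "error")))
    }
    rate <- 1 / mean(d$duration)
    data.frame(state = d$state[1], rate = rate, se = rate / sqrt(n), n = n)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stationary high-state occupancy of the two-state model
#'
#' Long-run fraction of time in the high-FRET state for the alternating
#' renewal process: `k_cleave / (k_cat + k_cleave)`.
#'
#' @param model A [two_state_model()].
#' @return Occupancy in \[0, 1\].
#' @export
stationary_occupancy <- function(model) {
  stopifnot(inherits(model, "two_state_model"))
  model$k_cleave / (model$k_cat + model$k_cleave)
}
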