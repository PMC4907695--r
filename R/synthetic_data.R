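# Synthetic-data generators: every input the analysis pipeline consumes can
# be produced here with known ground truth, under an explicit seed.

#' Parameters for a synthetic single-molecule intensity trace
#'
#' Describes one immobilised donor/acceptor-labelled particle imaged by
#' TIRF: a FRET phase, an acceptor photobleaching step (anti-correlated
#' rise in the donor channel), a donor-only phase, a donor photobleaching
#' step, and background. Bleaching times are exponential with the given
#' rates and are quantised to frame boundaries.
#'
#' @param frame_period Seconds per frame (default 0.22, a typical TIRF
#'   repetition time).
#' @param exposure Exposure time in seconds (metadata only).
#' @param donor_brightness Mean donor signal above background, counts/frame.
#' @param fret_efficiency_true True transfer efficiency in \[0, 1\].
#' @param background_mean Mean background, counts/frame.
#' @param noise_sd Additive Gaussian noise SD, counts/frame.
#' @param acceptor_bleach_rate,donor_bleach_rate Photobleaching rates, 1/s.
#'   A rate of 0 means the dye never bleaches within the trace.
#' @param n_frames Number of frames.
#' @param accepted_fixture If `TRUE` (default) the acceptor is forced to
#'   bleach before the donor, both within the trace and with at least 10
#'   frames per phase, so the trace passes the selection rules by
#'   construction; set `FALSE` to exercise rejection logic with
#'   unconstrained bleach orders.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(frame_period = 0.22,
                         exposure = 0.2,
                         donor_brightness = 1000,
                         fret_efficiency_true = 0.76,
                         background_mean = 100,
                         noise_sd = 30,
                         acceptor_bleach_rate = 0.05,
                         donor_bleach_rate = 0.05,
                         n_frames = 400,
                         accepted_fixture = TRUE,
                         seed = NULL) {
  check_scalar_num(frame_period, "frame_period", 0, strict_lower = TRUE)
  check_scalar_num(fret_efficiency_true, "fret_efficiency_true", 0, 1)
  check_scalar_num(noise_sd, "noise_sd", 0)
  check_scalar_num(acceptor_bleach_rate, "acceptor_bleach_rate", 0)
  check_scalar_num(donor_bleach_rate, "donor_bleach_rate", 0)
  check_scalar_num(n_frames, "n_frames", 1)
  structure(
    list(frame_period = frame_period, exposure = exposure,
         donor_brightness = donor_brightness,
         fret_efficiency_true = fret_efficiency_true,
         background_mean = background_mean, noise_sd = noise_sd,
         acceptor_bleach_rate = acceptor_bleach_rate,
         donor_bleach_rate = donor_bleach_rate,
         n_frames = as.integer(n_frames),
         accepted_fixture = isTRUE(accepted_fixture), seed = seed),
    class = "trace_params"
  )
}

#' Generate a synthetic donor/acceptor intensity trace
#'
#' Constructs the piecewise-constant ideal signal implied by
#' [trace_params()] and adds per-frame Gaussian noise. Before the acceptor
#' bleaches, the donor runs at `background + brightness * (1 - E)` and the
#' acceptor (sensitised emission) at `background + brightness * E`; after
#' acceptor bleaching the donor rises anti-correlatedly to
#' `background + brightness`; after donor bleaching both channels sit at
#' background. True bleach frames are recorded as metadata.
#'
#' @param params A [trace_params()] object.
#' @return An `intensity_trace`: a data frame with columns `frame`,
#'   `time_s`, `donor_counts`, `acceptor_counts` and attributes
#'   `frame_period`, `acceptor_bleach_frame`, `donor_bleach_frame`
#'   (`NA` if the dye never bleaches), and `params`.
#' @export
#' @examples
#' tr <- generate_intensity_trace(trace_params(noise_sd = 0, seed = 1))
#' head(tr)
generate_intensity_trace <- function(params) {
  stopifnot(inherits(params, "trace_params"))
  p <- params
  if (p$n_frames <= 0 || p$frame_period <= 0) {
    stop_invalid("n_frames and frame_period must be positive")
  }
  with_seed_(p$seed, {
    t_end <- p$n_frames * p$frame_period
    draw_bleach <- function(rate) {
      if (rate <= 0) Inf else stats::rexp(1, rate)
    }
    t_acc <- draw_bleach(p$acceptor_bleach_rate)
    t_don <- draw_bleach(p$donor_bleach_rate)
    if (p$accepted_fixture &&
        p$acceptor_bleach_rate > 0 && p$donor_bleach_rate > 0) {
      # resample until both bleach within the trace, acceptor strictly
      # first, leaving at least 10 frames per phase so every segment is
      # long enough to be measured (and detected) at all
      gap <- 10 * p$frame_period
      tries <- 0L
      while ((t_acc < gap || t_don - t_acc < gap ||
              t_don > t_end - gap) && tries < 10000L) {
        t_acc <- draw_bleach(p$acceptor_bleach_rate)
        t_don <- draw_bleach(p$donor_bleach_rate)
        tries <- tries + 1L
      }
      if (tries >= 10000L) {
        stop_invalid("could not draw an accepted-fixture bleach order; ",
                     "bleach rates too extreme for n_frames")
      }
    }
    # first frame recorded at the bleached level
    frame_of <- function(tb) {
      f <- ceiling(tb / p$frame_period) + 1
      if (!is.finite(f) || f > p$n_frames) NA_integer_ else as.integer(f)
    }
    f_acc <- frame_of(t_acc)
    f_don <- frame_of(t_don)
    frames <- seq_len(p$n_frames)
    donor <- rep(p$background_mean +
                   p$donor_brightness * (1 - p$fret_efficiency_true),
                 p$n_frames)
    acceptor <- rep(p$background_mean +
                      p$donor_brightness * p$fret_efficiency_true,
                    p$n_frames)
    if (!is.na(f_acc)) {
      donor[frames >= f_acc] <- p$background_mean + p$donor_brightness
      acceptor[frames >= f_acc] <- p$background_mean
    }
    if (!is.na(f_don)) {
      donor[frames >= f_don] <- p$background_mean
      # acceptor sensitised emission also dies with the donor
      acceptor[frames >= f_don] <- p$background_mean
    }
    if (p$noise_sd > 0) {
      donor <- donor + stats::rnorm(p$n_frames, 0, p$noise_sd)
      acceptor <- acceptor + stats::rnorm(p$n_frames, 0, p$noise_sd)
    }
    out <- data.frame(
      frame = frames,
      time_s = (frames - 1) * p$frame_period,
      donor_counts = donor,
      acceptor_counts = acceptor
    )
    attr(out, "frame_period") <- p$frame_period
    attr(out, "acceptor_bleach_frame") <- f_acc
    attr(out, "donor_bleach_frame") <- f_don
    attr(out, "params") <- p
    class(out) <- c("intensity_trace", "data.frame")
    out
  })
}

#' Specification of a Gaussian FRET-efficiency mixture
#'
#' @param components Data frame with columns `mean`, `width` (FWHM) and
#'   `weight`; weights must be non-negative and sum to 1 (tolerance 1e-9).
#' @param n_per_replicate Events per replicate (default 200, a typical
#'   per-condition event count in single-molecule TIRF experiments).
#' @param n_replicates Number of independent replicates (default 3).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, n_per_replicate = 200,
                         n_replicates = 3, seed = NULL) {
  stopifnot(is.data.frame(components),
            all(c("mean", "width", "weight") %in% names(components)))
  if (any(components$weight < 0)) stop_invalid("weights must be >= 0")
  if (abs(sum(components$weight) - 1) > 1e-9) {
    stop_invalid("component weights must sum to 1 (tolerance 1e-9)")
  }
  if (any(components$width <= 0)) stop_invalid("widths must be > 0")
  check_scalar_num(n_per_replicate, "n_per_replicate", 0)
  check_scalar_num(n_replicates, "n_replicates", 1)
  structure(
    list(components = components,
         n_per_replicate = as.integer(n_per_replicate),
         n_replicates = as.integer(n_replicates), seed = seed),
    class = "mixture_spec"
  )
}

#' The three-state lateral-gate mixture reported for the channel
#'
#' Convenience constructor for the closed / part-open / open FRET mixture
#' (means 0.76, 0.59, 0.45 and FWHM widths 0.24, 0.16, 0.31).
#'
#' @param weights Component weights, default `c(0.4, 0.3, 0.3)`.
#' @inheritParams mixture_spec
#' @return A `mixture_spec`.
#' @export
lateral_gate_mixture <- function(weights = c(0.4, 0.3, 0.3),
                                 n_per_replicate = 200, n_replicates = 3,
                                 seed = NULL) {
  mixture_spec(
    data.frame(mean = c(0.76, 0.59, 0.45),
               width = c(0.24, 0.16, 0.31),
               weight = weights),
    n_per_replicate = n_per_replicate,
    n_replicates = n_replicates, seed = seed
  )
}

#' Default condition series emulating the single-molecule experiment
#'
#' Named list of three-state weight vectors (closed, part-open, open) for
#' the conditions imaged in the experiment: channel alone (closed only),
#' motor + non-hydrolysable analogue, motor + ADP, motor + ATP (the
#' comparable-weights mixed condition), ATP + substrate, and high motor +
#' substrate. The progression toward the open states with ATP and
#' substrate mirrors the reported amplitude trends.
#'
#' @return Named list of numeric weight vectors summing to 1.
#' @export
lateral_gate_conditions <- function() {
  list(
    alone    = c(1.00, 0.00, 0.00),
    AMPPNP   = c(0.45, 0.20, 0.35),
    ADP      = c(0.75, 0.15, 0.10),
    ATP      = c(1, 1, 1) / 3,
    ATP_pOA  = c(0.30, 0.30, 0.40),
    ATP_high = c(0.20, 0.30, 0.50)
  )
}

#' Sample per-molecule FRET efficiencies from a Gaussian mixture
#'
#' Each event picks a component by weight and draws
#' `Normal(mean, fwhm_to_sigma(width))`. Values are deliberately not
#' truncated to \[0, 1\]: measured efficiencies scatter outside the unit
#' interval through noise, and the histogram fit must see that.
#'
#' @param spec A [mixture_spec()].
#' @return List of numeric vectors, one per replicate.
#' @export
sample_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  comp <- spec$components
  sig <- fwhm_to_sigma(comp$width)
  with_seed_(spec$seed, {
    lapply(seq_len(spec$n_replicates), function(r) {
      if (spec$n_per_replicate == 0L) return(numeric(0))
      idx <- sample.int(nrow(comp), spec$n_per_replicate,
                        replace = TRUE, prob = comp$weight)
      stats::rnorm(spec$n_per_replicate, comp$mean[idx], sig[idx])
    })
  })
}

#' Specification of a tight-binding titration curve
#'
#' Forward model for a fluorescence titration in the ligand-depletion
#' (tight-binding) regime, where the fixed partner concentration `E0` is
#' comparable to `KD`.
#'
#' @param F0 Signal without ligand.
#' @param Bmax Total signal change at saturation.
#' @param E0 Concentration of the fixed binding partner (nM); must be > 0.
#' @param KD Dissociation constant (nM).
#' @param concentrations Titrated ligand concentrations (nM).
#' @param noise_sd Gaussian noise SD on the signal (0 = noiseless).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `titration_spec`.
#' @export
titration_spec <- function(F0, Bmax, E0, KD, concentrations,
                           noise_sd = 0, seed = NULL) {
  check_scalar_num(E0, "E0", 0, strict_lower = TRUE)
  check_scalar_num(KD, "KD", 0)
  if (any(concentrations < 0)) stop_invalid("concentrations must be >= 0")
  check_scalar_num(noise_sd, "noise_sd", 0)
  structure(
    list(F0 = F0, Bmax = Bmax, E0 = E0, KD = KD,
         concentrations = as.numeric(concentrations),
         noise_sd = noise_sd, seed = seed),
    class = "titration_spec"
  )
}

#' Generate a titration series from the tight-binding model
#'
#' @param spec A [titration_spec()].
#' @return A `titration_series` data frame with columns `s` (nM) and `F`,
#'   and attribute `E0`.
#' @export
generate_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  f <- tight_binding_model(spec$F0, spec$Bmax, spec$E0, spec$KD,
                           spec$concentrations)
  with_seed_(spec$seed, {
    if (spec$noise_sd > 0) {
      f <- f + stats::rnorm(length(f), 0, spec$noise_sd)
    }
    out <- data.frame(s = spec$concentrations, F = f)
    attr(out, "E0") <- spec$E0
    class(out) <- c("titration_series", "data.frame")
    out
  })
}

#' Specification of a multi-exponential fluorescence decay
#'
#' @param rates Decay rates, 1/s (all > 0).
#' @param amplitudes Amplitudes, one per rate.
#' @param offset Baseline fluorescence.
#' @param duration Trace length, s.
#' @param dt Sampling interval, s (> 0).
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed or `NULL`.
#' @return Object of class `decay_spec`.
#' @export
decay_spec <- function(rates, amplitudes, offset = 0, duration = 60,
                       dt = 0.01, noise_sd = 0, seed = NULL) {
  if (any(rates <= 0)) stop_invalid("rates must be > 0")
  if (length(rates) != length(amplitudes)) {
    stop_invalid("rates and amplitudes must have equal length")
  }
  check_scalar_num(dt, "dt", 0, strict_lower = TRUE)
  check_scalar_num(duration, "duration", 0, strict_lower = TRUE)
  check_scalar_num(noise_sd, "noise_sd", 0)
  structure(
    list(rates = as.numeric(rates), amplitudes = as.numeric(amplitudes),
         offset = offset, duration = duration, dt = dt,
         noise_sd = noise_sd, seed = seed),
    class = "decay_spec"
  )
}

#' Generate a (multi-)exponential kinetic trace
#'
#' `F(t) = offset + sum_i amplitude_i * exp(-rate_i * t)` plus optional
#' Gaussian noise, sampled on a regular grid.
#'
#' @param spec A [decay_spec()].
#' @return A `kinetic_trace` data frame with columns `time` (s) and `F`.
#' @export
generate_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_spec"))
  tt <- seq(0, spec$duration, by = spec$dt)
  f <- rep(spec$offset, length(tt))
  for (i in seq_along(spec$rates)) {
    f <- f + spec$amplitudes[i] * exp(-spec$rates[i] * tt)
  }
  with_seed_(spec$seed, {
    if (spec$noise_sd > 0) f <- f + stats::rnorm(length(f), 0, spec$noise_sd)
    out <- data.frame(time = tt, F = f)
    class(out) <- c("kinetic_trace", "data.frame")
    out
  })
}
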