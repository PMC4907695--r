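# Selection of valid single-donor/single-acceptor traces by sequential
# single-step photobleaching, and acceptor-photobleaching FRET efficiency.

#' Detect intensity steps in a single channel
#'
#' Change-point detection by iterative binary segmentation: each segment is
#' split at the point minimising the piecewise-constant residual sum of
#' squares, and the split is kept when the level change exceeds
#' `threshold` times the channel's robust noise SD. The noise SD is
#' estimated from first differences as `mad(diff(x)) / sqrt(2)` (the MAD
#' already carries the 1/0.6745 normal-consistency factor), which is
#' insensitive to the steps themselves.
#'
#' @param x Numeric vector of per-frame intensities for one channel.
#' @param min_separation Minimum segment length in frames (default 5).
#' @param threshold Step-size threshold in units of noise SD (default 4).
#' @return Data frame of class `step_calls` with columns `frame_index`
#'   (first frame at the new level), `level_before`, `level_after` and
#'   `direction` (+1 up, -1 down), ordered by frame. Zero rows when no
#'   step passes the threshold.
#' @export
detect_steps <- function(x, min_separation = 5, threshold = 4) {
  if (!is.numeric(x)) stop_invalid("x must be numeric")
  n <- length(x)
  if (n < 2 * min_separation) {
    stop_invalid("trace shorter than 2 * min_separation (", n, " < ",
                 2 * min_separation, ")")
  }
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (sigma == 0) sigma <- .Machine$double.eps  # noiseless traces
  breaks <- integer(0)

  split_segment <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_separation) return(invisible(NULL))
    seg <- x[lo:hi]
    cs <- cumsum(seg)
    tot <- cs[len]
    # candidate split after position i (i frames left, len - i right)
    i <- min_separation:(len - min_separation)
    if (length(i) == 0) return(invisible(NULL))
    mean_l <- cs[i] / i
    mean_r <- (tot - cs[i]) / (len - i)
    # two-mean RSS up to a constant: maximise between-group sum of squares
    bss <- i * (len - i) / len * (mean_l - mean_r)^2
    k <- i[which.max(bss)]
    if (abs(mean_l[match(k, i)] - mean_r[match(k, i)]) <= threshold * sigma) {
      return(invisible(NULL))
    }
    breaks <<- c(breaks, lo + k - 1L)  # last frame of the left level
    split_segment(lo, lo + k - 1L)
    split_segment(lo + k, hi)
    invisible(NULL)
  }
  split_segment(1L, n)

  breaks <- sort(unique(breaks))
  if (length(breaks) == 0) {
    out <- data.frame(frame_index = integer(0), level_before = numeric(0),
                      level_after = numeric(0), direction = integer(0))
  } else {
    edges <- c(0L, breaks, n)
    seg_means <- vapply(seq_len(length(edges) - 1), function(j) {
      mean(x[(edges[j] + 1):edges[j + 1]])
    }, numeric(1))
    out <- data.frame(
      frame_index = breaks + 1L,
      level_before = seg_means[-length(seg_means)],
      level_after = seg_means[-1],
      direction = ifelse(diff(seg_means) > 0, 1L, -1L)
    )
  }
  class(out) <- c("step_calls", "data.frame")
  out
}

#' Select a valid smFRET trace and extract its intensity segments
#'
#' A trace is accepted when it shows the photobleaching signature of
#' exactly one donor and one acceptor: (a) a single downward acceptor
#' step, (b) a single downward donor step strictly later, and (c) an
#' anti-correlated upward donor step coincident with the acceptor bleach
#' (within ±1 frame) whose magnitude is at least `anticorr_frac` of the
#' acceptor drop. Rejection is a result, not an error; the reason codes
#' are `"no-acceptor-step"`, `"multi-step"`, `"donor-first"`,
#' `"no-donor-step"`, `"no-anticorrelation"` and `"short-segment"` (a
#' phase too short to average).
#'
#' Accepted traces yield the donor segment means: `I_DA` (during FRET),
#' `I_D` (after acceptor bleach), `I_bck` (after donor bleach, excluding
#' `guard` frames around each step), and the efficiency from
#' [compute_fret_efficiency()].
#'
#' @param trace An `intensity_trace` (or data frame with `donor_counts`
#'   and `acceptor_counts`).
#' @param donor_steps,acceptor_steps Optional precomputed [detect_steps()]
#'   results; computed from the trace when omitted.
#' @param anticorr_frac Minimum donor rise as a fraction of the acceptor
#'   drop (default 0.3).
#' @param guard Frames excluded on each side of a step when averaging
#'   segments (default 2).
#' @param ... Passed to [detect_steps()] when steps are not supplied.
#' @return A list of class `fret_observation`: `accepted`, `reason`
#'   (`NA` when accepted), `I_DA`, `I_D`, `I_bck`, `E`,
#'   `acceptor_bleach_frame`, `donor_bleach_frame`.
#' @export
select_smfret_trace <- function(trace, donor_steps = NULL,
                                acceptor_steps = NULL,
                                anticorr_frac = 0.3, guard = 2, ...) {
  stopifnot(is.data.frame(trace),
            all(c("donor_counts", "acceptor_counts") %in% names(trace)))
  donor <- trace$donor_counts
  acceptor <- trace$acceptor_counts
  if (is.null(donor_steps)) donor_steps <- detect_steps(donor, ...)
  if (is.null(acceptor_steps)) acceptor_steps <- detect_steps(acceptor, ...)

  reject <- function(reason) {
    structure(list(accepted = FALSE, reason = reason,
                   I_DA = NA_real_, I_D = NA_real_, I_bck = NA_real_,
                   E = NA_real_, acceptor_bleach_frame = NA_integer_,
                   donor_bleach_frame = NA_integer_),
              class = "fret_observation")
  }

  acc_down <- acceptor_steps[acceptor_steps$direction < 0, , drop = FALSE]
  if (nrow(acc_down) == 0) return(reject("no-acceptor-step"))
  if (nrow(acc_down) > 1) return(reject("multi-step"))
  a_frame <- acc_down$frame_index[1]

  don_down <- donor_steps[donor_steps$direction < 0, , drop = FALSE]
  if (nrow(don_down) == 0) {
    return(reject("no-donor-step"))
  }
  if (nrow(don_down) > 1) return(reject("multi-step"))
  d_frame <- don_down$frame_index[1]
  if (d_frame <= a_frame) return(reject("donor-first"))

  don_up <- donor_steps[donor_steps$direction > 0, , drop = FALSE]
  coincident <- don_up[abs(don_up$frame_index - a_frame) <= 1, , drop = FALSE]
  if (nrow(coincident) == 0) return(reject("no-anticorrelation"))
  rise <- coincident$level_after[1] - coincident$level_before[1]
  drop_mag <- acc_down$level_before[1] - acc_down$level_after[1]
  if (rise < anticorr_frac * drop_mag) return(reject("no-anticorrelation"))

  seg_mean <- function(from, to) {
    from <- max(1L, from)
    to <- min(length(donor), to)
    # require at least 3 usable frames per segment for a meaningful mean
    if (to - from < 2L) return(NA_real_)
    mean(donor[from:to])
  }
  i_da <- seg_mean(1L, a_frame - 1L - guard)
  i_d <- seg_mean(a_frame + guard, d_frame - 1L - guard)
  i_bck <- seg_mean(d_frame + guard, length(donor))
  if (anyNA(c(i_da, i_d, i_bck))) return(reject("short-segment"))
  e <- tryCatch(compute_fret_efficiency(i_da, i_d, i_bck),
                error = function(e) NA_real_)
  if (is.na(e)) return(reject("no-anticorrelation"))

  structure(list(accepted = TRUE, reason = NA_character_,
                 I_DA = i_da, I_D = i_d, I_bck = i_bck, E = e,
                 acceptor_bleach_frame = a_frame,
                 donor_bleach_frame = d_frame),
            class = "fret_observation")
}

#' Acceptor-photobleaching FRET efficiency
#'
#' `E = 1 - (I_DA - I_bck) / (I_D - I_bck)`: the donor signal during FRET
#' relative to the donor signal with the acceptor bleached, both background
#' corrected. This estimator needs no corrections for quantum yield or
#' channel sensitivity. Values may fall slightly outside \[0, 1\] through
#' noise and are not clipped.
#'
#' @param I_DA Donor mean during FRET (counts).
#' @param I_D Donor mean after acceptor photobleaching (counts).
#' @param I_bck Background: donor mean after donor photobleaching (counts).
#' @return The efficiency `E` (vectorised over equal-length inputs).
#' @export
#' @examples
#' compute_fret_efficiency(400, 1000, 0)  # 0.6
compute_fret_efficiency <- function(I_DA, I_D, I_bck) {
  if (any(I_D <= I_bck)) {
    stop_invalid("undefined efficiency: I_D must exceed I_bck")
  }
  1 - (I_DA - I_bck) / (I_D - I_bck)
}

#' Analyse a batch of traces into accepted FRET efficiencies
#'
#' Runs [detect_steps()] on both channels and [select_smfret_trace()] on
#' each trace, returning the accepted efficiencies and a table of
#' rejection reasons.
#'
#' @param traces List of `intensity_trace` objects.
#' @param ... Passed to [select_smfret_trace()].
#' @return List with `efficiencies` (numeric), `observations` (list of
#'   `fret_observation`), and `rejections` (named table of reason counts).
#' @export
analyze_traces <- function(traces, ...) {
  obs <- lapply(traces, select_smfret_trace, ...)
  acc <- vapply(obs, function(o) isTRUE(o$accepted), logical(1))
  reasons <- vapply(obs[!acc], function(o) o$reason, character(1))
  list(
    efficiencies = vapply(obs[acc], function(o) o$E, numeric(1)),
    observations = obs,
    rejections = table(reasons)
  )
}
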