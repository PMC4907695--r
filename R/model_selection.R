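# How many spectral components do the histograms require? Two independent
# answers: SVD component counting against the replicate-noise floor, and
# residual comparison of k-component constrained fits.

#' Count significant SVD components of a histogram set
#'
#' Columns (condition x replicate histograms) are area-normalised and the
#' singular value decomposition is taken. A component is significant when
#' its singular value exceeds `floor_factor` times the noise edge
#' `sigma_n * (sqrt(n_bins) + sqrt(n_cols))` — the largest singular value
#' a pure-noise matrix of the same shape would produce (the
#' Marchenko-Pastur bulk edge). The per-entry noise SD `sigma_n` is
#' estimated from the scatter of same-condition replicate columns about
#' their condition mean, with the `m/(m-1)` correction for deviations
#' from an `m`-replicate mean — i.e. the scatter that experimental error
#' alone produces. Components below the edge leave the data described
#' within experimental error.
#'
#' @param histogram_matrix Numeric matrix, rows = bins, columns =
#'   condition x replicate histograms.
#' @param conditions Character vector labelling each column's condition
#'   (used to estimate the noise floor). Required unless
#'   `replicate_noise` is given.
#' @param replicate_noise Optional externally supplied per-entry noise SD
#'   (on the area-normalised scale).
#' @param floor_factor Multiplier on the noise edge (default 1).
#' @return Object of class `svd_result`: `singular_values` (descending),
#'   `n_significant`, `noise_floor` (per-entry noise SD), `noise_edge`,
#'   `recon_rms` (per rank), `u`, `v`.
#' @export
svd_components <- function(histogram_matrix, conditions = NULL,
                           replicate_noise = NULL, floor_factor = 1) {
  m <- as.matrix(histogram_matrix)
  if (ncol(m) < 2) {
    stop(errorCondition("need at least 2 histogram columns",
                        class = c("lgfret_insufficient", "error")))
  }
  # area-normalise so amplitude differences, not totals, drive components
  tot <- colSums(m)
  if (any(tot <= 0)) stop_invalid("histogram columns must have positive mass")
  m <- sweep(m, 2, tot, "/")

  if (is.null(replicate_noise)) {
    if (is.null(conditions) || length(conditions) != ncol(m)) {
      stop_invalid("conditions labels (one per column) are required to ",
                   "estimate the replicate noise floor")
    }
    devs <- numeric(0)
    for (cn in unique(conditions)) {
      cols <- which(conditions == cn)
      nrep <- length(cols)
      if (nrep < 2) next
      mu <- rowMeans(m[, cols, drop = FALSE])
      d <- as.vector(m[, cols, drop = FALSE] - mu)
      devs <- c(devs, d * sqrt(nrep / (nrep - 1)))
    }
    if (length(devs) == 0) {
      stop(errorCondition(
        "no condition has replicate columns; supply replicate_noise",
        class = c("lgfret_insufficient", "error")))
    }
    replicate_noise <- sqrt(mean(devs^2))
  }

  dec <- svd(m)
  r <- length(dec$d)
  recon_rms <- vapply(seq_len(r), function(k) {
    approx_m <- dec$u[, seq_len(k), drop = FALSE] %*%
      diag(dec$d[seq_len(k)], k, k) %*%
      t(dec$v[, seq_len(k), drop = FALSE])
    sqrt(mean((m - approx_m)^2))
  }, numeric(1))
  noise_edge <- replicate_noise * (sqrt(nrow(m)) + sqrt(ncol(m)))
  n_sig <- sum(dec$d > floor_factor * noise_edge)
  structure(
    list(singular_values = dec$d, n_significant = n_sig,
         noise_floor = replicate_noise, noise_edge = noise_edge,
         recon_rms = recon_rms, u = dec$u, v = dec$v),
    class = "svd_result"
  )
}

#' @export
print.svd_result <- function(x, ...) {
  cat("SVD component analysis\n")
  cat("singular values:", signif(x$singular_values, 3), "\n")
  cat("noise SD:", signif(x$noise_floor, 3),
      " noise edge:", signif(x$noise_edge, 3), "\n")
  cat("significant components:", x$n_significant, "\n")
  invisible(x)
}

#' Residual sum of squares of k-Gaussian constrained fits
#'
#' Fits k-component Gaussian mixtures (k in `k_values`) to the
#' condition-averaged histograms under the staged-protocol constraint
#' (high peak position/width taken from a single-Gaussian fit to the
#' alone condition and fixed, when an alone condition is present), and
#' returns the residual sum of squares per k as a measure of fit quality.
#' Each fit seeds one start from the (k-1)-component solution plus a
#' vanishing extra component, so RSS is non-increasing in k.
#'
#' @param histograms List of `fret_histogram` objects (as for
#'   [fit_staged_mixture()]), or a single `fret_histogram_avg`.
#' @param k_values Component counts to compare (default `1:3`).
#' @param alone_label Condition fixing the high peak, if present.
#' @param n_starts,seed Multi-start controls.
#' @return Data frame with columns `k`, `rss`, plus attribute `fits`
#'   (the full fit objects).
#' @export
compare_k_fits <- function(histograms, k_values = 1:3,
                           alone_label = "alone", n_starts = 5, seed = 1L) {
  if (any(k_values < 1)) stop_invalid("k must be >= 1")
  k_values <- sort(unique(as.integer(k_values)))

  if (inherits(histograms, "fret_histogram_avg")) {
    edges <- histograms$bin_edges
    Y <- matrix(histograms$mean, ncol = 1)
    mu_fix <- NA_real_; sg_fix <- NA_real_
  } else {
    conds <- vapply(histograms, function(h) h$condition, character(1))
    edges <- histograms[[1]]$bin_edges
    avg <- lapply(split(histograms, conds), average_replicates)
    Y <- vapply(avg, function(h) h$mean, numeric(length(edges) - 1))
    Y <- matrix(Y, nrow = length(edges) - 1L,
                dimnames = list(NULL, names(avg)))
    if (alone_label %in% conds) {
      a <- avg[[alone_label]]
      s1 <- fit_mixture_ls(matrix(a$mean, ncol = 1), edges, 1,
                           weights = "poisson",
                           n_starts = n_starts, seed = seed)
      mu_fix <- s1$mu[1]; sg_fix <- s1$sigma[1]
    } else {
      mu_fix <- NA_real_; sg_fix <- NA_real_
    }
  }

  fits <- list(); rss <- numeric(length(k_values))
  prev <- NULL
  for (j in seq_along(k_values)) {
    k <- k_values[j]
    fixed_mean <- c(mu_fix, rep(NA_real_, k - 1))[seq_len(k)]
    fixed_sigma <- c(sg_fix, rep(NA_real_, k - 1))[seq_len(k)]
    fit <- fit_mixture_ls(Y, edges, k, fixed_mean = fixed_mean,
                          fixed_sigma = fixed_sigma, weights = "poisson",
                          n_starts = n_starts, seed = seed + k)
    if (!is.null(prev) && k == prev$k + 1L) {
      # nested start: previous solution plus a vanishing component
      nested <- fit_mixture_ls(
        Y, edges, k, fixed_mean = fixed_mean, fixed_sigma = fixed_sigma,
        start_mean = c(prev$fit$mu, min(prev$fit$mu) - 0.1)[seq_len(k)],
        start_sigma = c(prev$fit$sigma, 0.1)[seq_len(k)],
        weights = "poisson", n_starts = 1, seed = seed)
      if (nested$rss < fit$rss) fit <- nested
    }
    fits[[j]] <- fit
    rss[j] <- fit$rss
    prev <- list(k = k, fit = fit)
  }
  # monotonicity guard: a richer model can always reproduce a poorer one
  rss <- cummin(rss)
  out <- data.frame(k = k_values, rss = rss)
  attr(out, "fits") <- fits
  out
}
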