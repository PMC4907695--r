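# FRET-efficiency histograms: construction, replicate averaging, the staged
# constrained three-Gaussian global fit, orientation correction, ANOVA
# errors on amplitudes, and steady-state anisotropy.

#' Default FRET-efficiency bin edges
#'
#' Bin width 0.05 over \[-0.2, 1.2\]: wide enough to keep noise-broadened
#' efficiencies outside the unit interval, fine enough to resolve peaks
#' separated by ~0.15.
#'
#' @return Numeric vector of bin edges.
#' @export
default_bin_edges <- function() seq(-0.2, 1.2, by = 0.05)

#' Build a FRET-efficiency histogram
#'
#' Counts values into half-open bins `[lo, hi)`. Values outside the edge
#' range are dropped and counted in the `n_dropped` attribute.
#'
#' @param efficiencies Numeric vector of per-molecule efficiencies.
#' @param bin_edges Strictly increasing bin edges.
#' @param condition Condition label (e.g. `"alone"`, `"ATP"`).
#' @param replicate Replicate index.
#' @return Object of class `fret_histogram`: list with `bin_edges`,
#'   `counts`, `mids`, `condition`, `replicate`, `n_dropped`.
#' @export
build_histogram <- function(efficiencies, bin_edges = default_bin_edges(),
                            condition = NA_character_,
                            replicate = NA_integer_) {
  if (length(bin_edges) < 2) stop_invalid("need at least two bin edges")
  if (any(diff(bin_edges) <= 0)) {
    stop_invalid("bin_edges must be strictly increasing")
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(efficiencies, bin_edges, rightmost.closed = FALSE)
  in_range <- idx >= 1L & idx <= nb &
    efficiencies < bin_edges[length(bin_edges)]
  counts <- tabulate(idx[in_range], nbins = nb)
  structure(
    list(bin_edges = bin_edges, counts = as.numeric(counts),
         mids = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
         condition = condition, replicate = replicate,
         n_dropped = sum(!in_range)),
    class = "fret_histogram"
  )
}

#' Average replicate histograms bin by bin
#'
#' @param histograms List of `fret_histogram` objects sharing identical
#'   bin edges.
#' @return Object of class `fret_histogram_avg`: `bin_edges`, `mids`,
#'   `mean` (per-bin mean frequency), `sem` (per-bin SD/sqrt(n)), `n`,
#'   `condition`.
#' @export
average_replicates <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  edges <- histograms[[1]]$bin_edges
  for (h in histograms) {
    if (!isTRUE(all.equal(h$bin_edges, edges))) {
      stop_invalid("replicate histograms have mismatched bin edges")
    }
  }
  m <- vapply(histograms, function(h) h$counts, numeric(length(edges) - 1))
  m <- matrix(m, nrow = length(edges) - 1L)
  n <- ncol(m)
  mu <- rowMeans(m)
  sem <- if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else rep(0, nrow(m))
  structure(
    list(bin_edges = edges,
         mids = (edges[-1] + edges[-length(edges)]) / 2,
         mean = mu, sem = sem, n = n,
         condition = histograms[[1]]$condition),
    class = "fret_histogram_avg"
  )
}

# ---- internal mixture machinery ------------------------------------------

# Per-bin probability mass of area-normalised Gaussians: matrix bins x k.
# The model curve is integrated over each bin, not point-sampled at the
# centre, so broad components in narrow bins are represented exactly.
gauss_bin_fractions <- function(edges, mu, sigma) {
  nb <- length(edges) - 1L
  p <- matrix(0, nb, length(mu))
  for (i in seq_along(mu)) {
    cdf <- stats::pnorm(edges, mu[i], sigma[i])
    p[, i] <- diff(cdf)
  }
  p
}

# Weighted non-negative linear least squares for amplitudes given shapes:
# minimises sum(w * (y - P a)^2) over a >= 0 by subset enumeration (k <= 3
# in practice, so at most 2^k - 1 candidate supports).
wnnls_amplitudes <- function(P, y, w) {
  k <- ncol(P)
  best_a <- rep(0, k)
  best_obj <- sum(w * y^2)
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  for (s in subsets) {
    Ps <- P[, s, drop = FALSE]
    G <- crossprod(Ps * w, Ps)
    a_s <- tryCatch(solve(G + diag(1e-12, length(s)), crossprod(Ps * w, y)),
                    error = function(e) NULL)
    if (is.null(a_s) || any(a_s < 0)) next
    r <- y - Ps %*% a_s
    obj <- sum(w * r^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_a <- rep(0, k); best_a[s] <- a_s
    }
  }
  best_a
}

# Poisson deviance between observed and expected bin contents; valid for
# non-integer (replicate-averaged) y as well, up to a constant scale.
poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

# Poisson maximum-likelihood amplitudes for fixed component shapes, by EM
# multiplicative updates (non-negativity is automatic).
em_amplitudes <- function(P, y, n_iter = 60) {
  k <- ncol(P)
  tot <- sum(y)
  if (tot <= 0) return(rep(0, k))
  a <- rep(tot / k, k)
  cs <- colSums(P)
  cs[cs < 1e-12] <- 1e-12
  for (it in seq_len(n_iter)) {
    m <- as.vector(P %*% a)
    m[m < 1e-12] <- 1e-12
    a <- a * as.vector(crossprod(P, y / m)) / cs
  }
  a
}

# Weighted least-squares fit of a k-Gaussian mixture to one or more
# histograms sharing bin edges. Y: matrix bins x ncol (one column per data
# set); shared means/widths across columns, independent amplitude vectors
# per column. Fixed shape parameters are given as non-NA entries of
# fixed_mean / fixed_sigma (components in decreasing-mean order, fixed
# components first).
#
# Two numerical choices matter here. (1) Free means are parameterised as
# ordered gaps below the preceding component with a minimum separation
# `min_sep`: coincident means do not describe distinct states, and the gap
# parameterisation removes label-switching and peak-collapse degeneracies.
# (2) The amplitudes are profiled out by exact weighted non-negative linear
# least squares (variable projection), so the nonlinear search runs only
# over the handful of shape parameters; this avoids the scaling problems of
# optimising counts-scale amplitudes and FRET-scale positions jointly.
# Multi-start with seeded jitter; asymptotic SEs in natural parameters.
fit_mixture_core <- function(Y, edges, k,
                           fixed_mean = rep(NA_real_, k),
                           fixed_sigma = rep(NA_real_, k),
                           start_mean = NULL, start_sigma = NULL,
                           weights = NULL, n_starts = 5, seed = 1L,
                           amplitudes_only = FALSE,
                           objective = c("wls", "deviance"),
                           min_sep = 0.08, sigma_min = 0.05,
                           sigma_max = 0.25) {
  objective <- match.arg(objective)
  Y <- as.matrix(Y)
  nb <- nrow(Y)
  nc <- ncol(Y)
  if (is.null(weights)) weights <- matrix(1, nb, nc)
  weights <- as.matrix(weights)
  if (ncol(weights) == 1L && nc > 1L) {
    weights <- weights[, rep(1L, nc), drop = FALSE]
  }

  free_mu <- which(is.na(fixed_mean)) ; free_sg <- which(is.na(fixed_sigma))
  if (amplitudes_only) { free_mu <- integer(0); free_sg <- integer(0) }
  n_shape <- length(free_mu) + length(free_sg)

  if (is.null(start_mean)) {
    # spread free means below the lowest fixed component, or around the
    # occupied centre of mass when nothing is fixed
    gaps0 <- max(min_sep, 0.15)
    start_mean <- fixed_mean
    if (length(free_mu) == k) {
      mids <- (edges[-1] + edges[-length(edges)]) / 2
      wt <- pmax(rowSums(Y), 0)
      anchor <- if (sum(wt) > 0) stats::weighted.mean(mids, wt) else 0.6
      start_mean[free_mu] <- anchor + gaps0 * (k - 1) / 2 -
        gaps0 * (seq_along(free_mu) - 1)
    } else {
      start_mean[free_mu] <- min(fixed_mean, na.rm = TRUE) -
        gaps0 * seq_along(free_mu)
    }
  }
  if (is.null(start_sigma)) {
    start_sigma <- fixed_sigma
    start_sigma[is.na(start_sigma)] <- 0.1
  }

  # parameter vector: [mu1 (if free) | gaps for later free means |
  #                    log sigmas (free)]; amplitudes are profiled out
  mu_to_par <- function(mu) {
    vapply(seq_along(free_mu), function(j) {
      i <- free_mu[j]
      if (i == 1L) mu[1] else max(mu[i - 1] - mu[i], min_sep)
    }, numeric(1))
  }
  par_to_mu <- function(p) {
    mu <- fixed_mean
    for (j in seq_along(free_mu)) {
      i <- free_mu[j]
      mu[i] <- if (i == 1L) p[j] else mu[i - 1] - p[j]
    }
    mu
  }
  shapes_of <- function(par) {
    mu <- if (amplitudes_only) start_mean else par_to_mu(par)
    sigma <- if (amplitudes_only) start_sigma else fixed_sigma
    if (length(free_sg)) {
      sigma[free_sg] <- exp(par[length(free_mu) + seq_along(free_sg)])
    }
    list(mu = mu, sigma = sigma)
  }
  amps_for <- function(mu, sigma) {
    P <- gauss_bin_fractions(edges, mu, sigma)
    A <- if (objective == "deviance") {
      vapply(seq_len(nc), function(cc) {
        em_amplitudes(P, Y[, cc])
      }, numeric(k))
    } else {
      vapply(seq_len(nc), function(cc) {
        wnnls_amplitudes(P, Y[, cc], weights[, cc])
      }, numeric(k))
    }
    list(P = P, A = matrix(A, k, nc))
  }
  fit_objective <- function(Yfit) {
    if (objective == "deviance") {
      poisson_deviance(Y, Yfit)
    } else {
      sum(weights * (Y - Yfit)^2)
    }
  }
  obj <- function(par) {
    q <- shapes_of(par)
    pa <- amps_for(q$mu, q$sigma)
    fit_objective(pa$P %*% pa$A)
  }

  if (amplitudes_only) {
    q <- list(mu = start_mean, sigma = start_sigma)
    pa <- amps_for(q$mu, q$sigma)
    best_value <- fit_objective(pa$P %*% pa$A)
    best_conv <- 0L
  } else {
    p0 <- c(mu_to_par(start_mean),
            log(pmin(pmax(start_sigma[free_sg], sigma_min), sigma_max)))
    mu_lo <- ifelse(free_mu == 1L, -0.5, min_sep)
    mu_hi <- ifelse(free_mu == 1L, 1.5, 1)
    lower <- c(mu_lo, rep(log(sigma_min), length(free_sg)))
    upper <- c(mu_hi, rep(log(sigma_max), length(free_sg)))

    starts <- list(p0)
    if (n_starts > 1) {
      jit <- with_seed_(seed, {
        lapply(seq_len(n_starts - 1), function(j) {
          p <- p0
          if (length(free_mu)) {
            idx <- seq_along(free_mu)
            p[idx] <- p[idx] * stats::runif(length(idx), 0.6, 1.7)
          }
          if (length(free_sg)) {
            idx <- length(free_mu) + seq_along(free_sg)
            p[idx] <- p[idx] + stats::rnorm(length(idx), 0, 0.4)
          }
          pmin(pmax(p, lower), upper)
        })
      })
      starts <- c(starts, jit)
    }

    best <- NULL
    for (p in starts) {
      fit <- tryCatch(
        stats::optim(p, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) {
      stop(errorCondition("mixture fit failed to converge",
                          class = c("lgfret_fit_failure", "error")))
    }
    q <- shapes_of(best$par)
    pa <- amps_for(q$mu, q$sigma)
    best_value <- best$value
    best_conv <- best$convergence
  }

  fitted <- pa$P %*% pa$A
  rss <- sum((Y - fitted)^2)
  A <- pa$A

  # asymptotic SEs in natural parameters (free means, free sigmas, amps)
  # via the numeric Jacobian of the weighted residuals at the optimum
  # (for the deviance objective, Fisher-scoring weights 1/fitted)
  sw <- if (objective == "deviance") {
    1 / sqrt(pmax(fitted, 1e-4))
  } else {
    sqrt(weights)
  }
  se_mu <- rep(0, k); se_sigma <- rep(0, k)
  if (n_shape > 0) {
    nat <- c(q$mu[free_mu], q$sigma[free_sg], as.vector(A))
    resid_nat <- function(v) {
      mu <- q$mu; sigma <- q$sigma
      mu[free_mu] <- v[seq_along(free_mu)]
      sigma[free_sg] <- v[length(free_mu) + seq_along(free_sg)]
      Am <- matrix(v[(n_shape + 1):length(v)], k, nc)
      as.vector(sw * (Y - gauss_bin_fractions(edges, mu, sigma) %*% Am))
    }
    se <- tryCatch({
      nat0 <- nat
      r0 <- resid_nat(nat0)
      J <- matrix(0, length(r0), length(nat0))
      h <- pmax(abs(nat0) * 1e-5, 1e-7)
      for (j in seq_along(nat0)) {
        vv <- nat0; vv[j] <- vv[j] + h[j]
        J[, j] <- (resid_nat(vv) - r0) / h[j]
      }
      dof <- max(1, length(r0) - length(nat0))
      s2 <- sum(r0^2) / dof
      covm <- s2 * solve(crossprod(J) + diag(1e-10, ncol(J)))
      sqrt(pmax(diag(covm), 0))
    }, error = function(e) rep(NA_real_, length(nat)))
    se_mu[free_mu] <- se[seq_along(free_mu)]
    se_sigma[free_sg] <- se[length(free_mu) + seq_along(free_sg)]
  }

  list(mu = q$mu, sigma = q$sigma, A = A, rss = rss,
       weighted_rss = best_value, fitted = fitted,
       se_mu = se_mu, se_sigma = se_sigma, convergence = best_conv)
}

# Front end adding the weighting policy. weights may be a matrix (or
# vector) of per-bin weights, NULL for unweighted, or "poisson" for
# model-based counting-noise weights: w = 1/max(expected count, 1),
# iteratively reweighted (two refinement rounds). Histogram bin variance
# is Poisson, and weights estimated from the fitted model rather than the
# observed scatter keep low-count bins from biasing the broad components.
fit_mixture_ls <- function(Y, edges, k, ..., weights = NULL,
                           objective = "wls",
                           start_mean = NULL, start_sigma = NULL,
                           n_starts = 5, seed = 1L) {
  if (identical(objective, "deviance")) {
    return(fit_mixture_core(Y, edges, k, ..., objective = "deviance",
                            start_mean = start_mean,
                            start_sigma = start_sigma,
                            n_starts = n_starts, seed = seed))
  }
  if (!identical(weights, "poisson")) {
    return(fit_mixture_core(Y, edges, k, ..., weights = weights,
                            start_mean = start_mean,
                            start_sigma = start_sigma,
                            n_starts = n_starts, seed = seed))
  }
  Ym <- as.matrix(Y)
  w <- 1 / pmax(Ym, 1)
  fit <- fit_mixture_core(Ym, edges, k, ..., weights = w,
                          start_mean = start_mean,
                          start_sigma = start_sigma,
                          n_starts = n_starts, seed = seed)
  for (round in 1:2) {
    w <- 1 / pmax(fit$fitted, 1)
    fit <- fit_mixture_core(Ym, edges, k, ..., weights = w,
                            start_mean = fit$mu, start_sigma = fit$sigma,
                            n_starts = 1, seed = seed)
  }
  fit
}

# Per-bin weight 1/max(SEM, floor); the floor (median positive SEM) keeps
# bins whose replicate scatter is accidentally tiny from dominating.
sem_weights <- function(sem) {
  floor_ <- max(stats::median(sem[sem > 0]), 1e-6)
  if (!is.finite(floor_)) floor_ <- 1
  1 / pmax(sem, floor_)
}

#' Staged constrained three-Gaussian global fit of FRET histograms
#'
#' Fits the closed / part-open / open three-state model to a set of
#' replicate histograms across conditions, in four stages:
#'
#' 1. The high-FRET (closed) peak position and width are estimated by a
#'    single-Gaussian fit to the channel-alone condition, where the closed
#'    state dominates.
#' 2. All condition-averaged histograms are fitted globally to three
#'    Gaussians with the high peak fixed; the two lower peaks' positions
#'    and widths are shared across conditions, amplitudes free per
#'    condition.
#' 3. All positions and widths are fixed and per-replicate amplitudes are
#'    refitted (unshared), giving replicate-level amplitude estimates for
#'    ANOVA.
#' 4. The two lower peaks' positions and widths are released again (high
#'    peak still fixed) as an over-constraint check: the released
#'    parameters must agree with stage 2 within 3 standard errors,
#'    otherwise `over_constrained_flag` is set.
#'
#' The model curve is integrated over each bin and amplitudes are
#' parameterised as non-negative areas, profiled out exactly at every
#' objective evaluation. The default objective is the Poisson deviance of
#' the binned counts — bin contents are counting statistics, and weighting
#' by the replicate SEM (estimated from three replicates) or by squared
#' error alone systematically underprices model mass placed in empty tail
#' bins, biasing the broad open component; `objective = "wls"` gives
#' weighted least squares with model-based (iteratively reweighted
#' Poisson) weights instead. Multi-start (seeded jitter) guards against
#' local minima.
#'
#' @param histograms List of `fret_histogram` objects carrying `condition`
#'   and `replicate` labels; must include the `alone_label` condition.
#' @param alone_label Label of the channel-alone condition (default
#'   `"alone"`).
#' @param objective `"deviance"` (default) for Poisson maximum likelihood
#'   of the binned counts, or `"wls"` for iteratively reweighted least
#'   squares.
#' @param n_starts Number of jittered starts per stage (default 5).
#' @param seed Seed for start jitter.
#' @return Object of class `mixture_fit`: `components` (data frame with
#'   `state`, `mean`, `width` (FWHM), `se_mean`, `se_width`),
#'   `condition_amplitudes` (conditions x 3 matrix of areas),
#'   `replicate_amplitudes` (data frame: condition, replicate, state,
#'   amplitude), `rss` (named per-stage), `over_constrained_flag`,
#'   `stage4` (released parameters), `bin_edges`.
#' @export
fit_staged_mixture <- function(histograms, alone_label = "alone",
                               objective = c("deviance", "wls"),
                               n_starts = 5, seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(is.list(histograms), length(histograms) >= 1)
  conds <- vapply(histograms, function(h) h$condition, character(1))
  if (!alone_label %in% conds) {
    stop(errorCondition(
      paste0("protocol error: no '", alone_label, "' condition in input"),
      class = c("lgfret_protocol", "error")))
  }
  edges <- histograms[[1]]$bin_edges
  by_cond <- split(histograms, conds)
  cond_names <- names(by_cond)
  avg <- lapply(by_cond, average_replicates)

  # Stage 1: single Gaussian on 'alone'
  a <- avg[[alone_label]]
  s1 <- fit_mixture_ls(matrix(a$mean, ncol = 1), edges, k = 1,
                       weights = "poisson", objective = objective,
                       n_starts = n_starts, seed = seed)
  mu_high <- s1$mu[1]; sg_high <- s1$sigma[1]

  # Stage 2: global three-Gaussian fit, high peak fixed, shapes shared
  Y <- vapply(avg, function(h) h$mean, numeric(length(edges) - 1))
  Y <- matrix(Y, nrow = length(edges) - 1L,
              dimnames = list(NULL, cond_names))
  s2 <- fit_mixture_ls(Y, edges, k = 3,
                       fixed_mean = c(mu_high, NA, NA),
                       fixed_sigma = c(sg_high, NA, NA),
                       start_mean = c(mu_high, mu_high - 0.15,
                                      mu_high - 0.3),
                       start_sigma = c(sg_high, sg_high, sg_high),
                       weights = "poisson", objective = objective,
                       n_starts = n_starts, seed = seed + 1L)

  # Stage 3: all shapes fixed; per-replicate amplitudes (unshared)
  rep_rows <- list(); rss3 <- 0
  for (cn in cond_names) {
    for (h in by_cond[[cn]]) {
      f3 <- fit_mixture_ls(matrix(h$counts, ncol = 1), edges, k = 3,
                           amplitudes_only = TRUE,
                           start_mean = s2$mu, start_sigma = s2$sigma,
                           weights = "poisson", objective = objective,
                           n_starts = 1, seed = seed)
      rss3 <- rss3 + f3$rss
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        condition = cn, replicate = h$replicate,
        state = c("closed", "part_open", "open"),
        amplitude = f3$A[, 1])
    }
  }
  replicate_amplitudes <- do.call(rbind, rep_rows)

  # Stage 4: release lower two peaks (over-constraint check)
  s4 <- fit_mixture_ls(Y, edges, k = 3,
                       fixed_mean = c(mu_high, NA, NA),
                       fixed_sigma = c(sg_high, NA, NA),
                       start_mean = s2$mu, start_sigma = s2$sigma,
                       weights = "poisson", objective = objective,
                       n_starts = n_starts, seed = seed + 2L)
  tol_mu <- 3 * pmax(s4$se_mu[2:3], 0.01)
  tol_sg <- 3 * pmax(s4$se_sigma[2:3], 0.01)
  over_constrained <- any(abs(s4$mu[2:3] - s2$mu[2:3]) > tol_mu) ||
    any(abs(s4$sigma[2:3] - s2$sigma[2:3]) > tol_sg)

  amp <- t(s2$A)
  dimnames(amp) <- list(cond_names, c("closed", "part_open", "open"))
  structure(
    list(
      components = data.frame(
        state = c("closed", "part_open", "open"),
        mean = s2$mu, width = sigma_to_fwhm(s2$sigma),
        se_mean = s2$se_mu, se_width = s2$se_sigma / FWHM_TO_SIGMA,
        row.names = NULL),
      condition_amplitudes = amp,
      replicate_amplitudes = replicate_amplitudes,
      rss = c(stage1 = s1$rss, stage2 = s2$rss, stage3 = rss3,
              stage4 = s4$rss),
      over_constrained_flag = over_constrained,
      stage4 = list(mean = s4$mu, width = sigma_to_fwhm(s4$sigma)),
      bin_edges = edges),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Staged three-Gaussian global fit\n")
  print(x$components, digits = 3)
  cat("\nCondition amplitudes (areas):\n")
  print(round(x$condition_amplitudes, 2))
  cat("\nRSS per stage:", paste(names(x$rss), signif(x$rss, 4),
                                sep = "=", collapse = ", "), "\n")
  if (x$over_constrained_flag) {
    cat("NOTE: stage-4 released parameters disagree with stage 2;",
        "model may be over-constrained.\n")
  }
  invisible(x)
}

#' Correct state amplitudes for inward-facing channel orientation
#'
#' In proteoliposomes about half of the reconstituted channels face
#' inwards and cannot respond to externally added ligand; they contribute
#' an 'alone'-like sub-population to every condition. The correction
#' removes 50% of the alone amplitudes from each condition and rescales by
#' two: `corrected = 2 * (A - 0.5 * alone)`. Negative results are floored
#' at zero with a warning. The operation is linear and leaves the alone
#' condition itself unchanged.
#'
#' @param condition_amplitudes Numeric vector of per-state amplitudes for
#'   one condition.
#' @param alone_amplitudes Amplitudes of the alone condition, same length.
#' @return Corrected amplitude vector.
#' @export
orientation_correct <- function(condition_amplitudes, alone_amplitudes) {
  if (length(condition_amplitudes) != length(alone_amplitudes)) {
    stop_invalid("amplitude vectors must have equal length")
  }
  corrected <- 2 * (condition_amplitudes - 0.5 * alone_amplitudes)
  if (any(corrected < 0)) {
    warning("negative corrected amplitude floored at 0")
    corrected[corrected < 0] <- 0
  }
  corrected
}

#' Mean and SEM of per-replicate state amplitudes by one-way ANOVA
#'
#' For each state, fits a one-way layout of amplitude on condition
#' (via [stats::aov()]) and reports per-condition means with
#' `SEM = sqrt(residual mean square / n_replicates)`; with a single
#' condition this reduces to the ordinary `SD/sqrt(n)`.
#'
#' @param replicate_amplitudes Data frame with columns `condition`,
#'   `replicate`, `state`, `amplitude` (as returned in a `mixture_fit`).
#' @return Data frame with `condition`, `state`, `mean`, `sem`, `n`.
#' @export
anova_amplitudes <- function(replicate_amplitudes) {
  d <- replicate_amplitudes
  stopifnot(all(c("condition", "state", "amplitude") %in% names(d)))
  n_rep <- table(d$condition, d$state)
  if (any(n_rep < 2)) {
    stop(errorCondition("need >= 2 replicates per condition and state",
                        class = c("lgfret_insufficient", "error")))
  }
  out <- list()
  for (st in unique(d$state)) {
    ds <- d[d$state == st, ]
    ds$condition <- factor(ds$condition)
    if (nlevels(ds$condition) > 1) {
      fit <- stats::aov(amplitude ~ condition, data = ds)
      mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
    } else {
      mse <- stats::var(ds$amplitude)
    }
    agg <- stats::aggregate(amplitude ~ condition, data = ds,
                            FUN = function(x) c(mean = mean(x),
                                                n = length(x)))
    out[[st]] <- data.frame(
      condition = as.character(agg$condition), state = st,
      mean = agg$amplitude[, "mean"],
      sem = sqrt(mse / agg$amplitude[, "n"]),
      n = agg$amplitude[, "n"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Steady-state fluorescence anisotropy with G-factor correction
#'
#' `r = (I_par - G * I_perp) / (I_par + 2 * G * I_perp)`, vectorised; pass
#' spectra over an emission window and average the result to summarise a
#' band.
#'
#' @param I_par Emission intensity, polariser parallel to excitation.
#' @param I_perp Emission intensity, perpendicular.
#' @param G Instrument sensitivity correction factor (default 1).
#' @return Anisotropy value(s).
#' @export
#' @examples
#' compute_anisotropy(2, 1, G = 1)  # 0.25
compute_anisotropy <- function(I_par, I_perp, G = 1) {
  denom <- I_par + 2 * G * I_perp
  if (any(denom <= 0)) stop_invalid("total intensity must be positive")
  (I_par - G * I_perp) / denom
}
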