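# Shared fixtures and independent oracles, all built in code.

# Exhaustive single-change-point least-squares scan: the oracle against
# which the binary-segmentation step detector is checked. Returns the
# 1-based index of the first frame at the new level.
oracle_single_step <- function(x) {
  n <- length(x)
  best_k <- NA_integer_
  best_rss <- Inf
  for (k in seq_len(n - 1)) {
    left <- x[seq_len(k)]
    right <- x[(k + 1):n]
    rss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_k <- k
    }
  }
  best_k + 1L
}

# Replicate histogram set for a named list of three-state weight vectors,
# at the standard mixture parameters (200 events x 3 replicates each).
make_histogram_set <- function(weights_by_condition, seed,
                               n_per_replicate = 200, n_replicates = 3) {
  hs <- list()
  for (i in seq_along(weights_by_condition)) {
    cn <- names(weights_by_condition)[i]
    reps <- sample_mixture(lateral_gate_mixture(
      weights = weights_by_condition[[i]],
      n_per_replicate = n_per_replicate,
      n_replicates = n_replicates,
      seed = seed * 1009L + i))
    for (r in seq_along(reps)) {
      hs[[length(hs) + 1L]] <- build_histogram(reps[[r]],
                                               condition = cn,
                                               replicate = r)
    }
  }
  hs
}

# Minimal synthetic protein structure: residues along the x axis, each
# with backbone N/CA/C/O and a CB side-chain atom. Glycine at resno
# `gly_at` (if given) lacks CB.
make_synthetic_structure <- function(n_res = 10, spacing = 3.8,
                                     chain = "A", gly_at = integer(0)) {
  rows <- list()
  for (i in seq_len(n_res)) {
    x0 <- (i - 1) * spacing
    atoms <- c("N", "CA", "C", "O", "CB")
    resid <- if (i %in% gly_at) "GLY" else "ALA"
    if (i %in% gly_at) atoms <- setdiff(atoms, "CB")
    for (j in seq_along(atoms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = i, resid = resid, elety = atoms[j],
        x = x0 + 0.1 * j, y = 0.2 * j, z = 0)
    }
  }
  d <- do.call(rbind, rows)
  structure_model(d$chain, d$resno, d$resid, d$elety, d$x, d$y, d$z,
                  source = "synthetic")
}

# Apply a random rigid motion (rotation + translation) to a structure.
rigid_transform <- function(struct, seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::rnorm(3, 0, 50)
  xyz <- as.matrix(struct[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  structure_model(struct$chain, struct$resno, struct$resid, struct$elety,
                  xyz[, 1], xyz[, 2], xyz[, 3], source = "transformed")
}

# Write a minimal but valid PDB file for a structure model.
write_synthetic_pdb <- function(struct, path) {
  lines <- character(nrow(struct))
  for (i in seq_len(nrow(struct))) {
    lines[i] <- sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      i, struct$elety[i], struct$resid[i], struct$chain[i],
      struct$resno[i], struct$x[i], struct$y[i], struct$z[i],
      substr(struct$elety[i], 1, 1))
  }
  writeLines(c(lines, "END"), path)
  path
}
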