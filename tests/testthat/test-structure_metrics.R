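# Geometric metrics on synthetic coordinate models and PDB round-trips.

test_that("residue pair distances are Euclidean and symmetric", {
  s <- structure_model(chain = c("A", "A"), resno = c(1, 2),
                       resid = c("ALA", "ALA"), elety = c("CB", "CB"),
                       x = c(0, 3), y = c(0, 4), z = c(0, 0))
  expect_equal(residue_pair_distance(s, c("A", 1), c("A", 2)), 5)
  expect_equal(residue_pair_distance(s, c("A", 2), c("A", 1)), 5)
  expect_equal(residue_pair_distance(s, c("A", 1), c("A", 1)), 0)
  expect_error(residue_pair_distance(s, c("A", 1), c("A", 9)),
               "not found")
})

test_that("glycine falls back from CB to CA with a message", {
  s <- make_synthetic_structure(n_res = 4, gly_at = 2)
  expect_message(d <- residue_pair_distance(s, c("A", 1), c("A", 2)),
                 "using CA")
  expect_gt(d, 0)
})

test_that("distances satisfy the triangle inequality", {
  s <- make_synthetic_structure(n_res = 8)
  d12 <- residue_pair_distance(s, c("A", 1), c("A", 4))
  d23 <- residue_pair_distance(s, c("A", 4), c("A", 7))
  d13 <- residue_pair_distance(s, c("A", 1), c("A", 7))
  expect_lte(d13, d12 + d23 + 1e-9)
})

test_that("lateral-gate widths are reported in nm with their mean", {
  s <- make_synthetic_structure(n_res = 300)
  # CA atoms are spaced 3.8 A apart along x; choose pairs 15 A apart
  lg <- lateral_gate_width(s, pairs = list(c(10, 14), c(20, 24),
                                           c(30, 34)))
  expect_equal(unname(lg$per_pair), rep(4 * 3.8 / 10, 3),
               tolerance = 1e-9)
  expect_equal(lg$mean_nm, 1.52)
})

test_that("all metrics are invariant under rigid motions", {
  s <- make_synthetic_structure(n_res = 20)
  for (seed in 1:5) {
    t <- rigid_transform(s, seed)
    expect_equal(residue_pair_distance(t, c("A", 2), c("A", 11)),
                 residue_pair_distance(s, c("A", 2), c("A", 11)),
                 tolerance = 1e-9)
    expect_equal(lateral_gate_width(t, pairs = list(c(1, 6), c(3, 9)))$mean_nm,
                 lateral_gate_width(s, pairs = list(c(1, 6), c(3, 9)))$mean_nm,
                 tolerance = 1e-9)
    expect_equal(min_sidechain_distance(t, c("A", 1), c("A", 5)),
                 min_sidechain_distance(s, c("A", 1), c("A", 5)),
                 tolerance = 1e-9)
  }
})

test_that("minimum side-chain distance matches a brute-force pair scan", {
  set.seed(3)
  for (rep in 1:5) {
    na <- sample(5:20, 1); nb <- sample(5:20, 1)
    mk <- function(resno, n, centre) {
      data.frame(chain = "A", resno = resno, resid = "ARG",
                 elety = paste0("C", seq_len(n)),  # side-chain names
                 x = centre[1] + rnorm(n), y = centre[2] + rnorm(n),
                 z = centre[3] + rnorm(n))
    }
    d <- rbind(mk(1, na, c(0, 0, 0)), mk(2, nb, c(8, 0, 0)))
    s <- structure_model(d$chain, d$resno, d$resid, d$elety, d$x, d$y, d$z)
    a <- as.matrix(d[d$resno == 1, c("x", "y", "z")])
    b <- as.matrix(d[d$resno == 2, c("x", "y", "z")])
    brute <- Inf
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        brute <- min(brute, sqrt(sum((a[i, ] - b[j, ])^2)))
      }
    }
    expect_equal(min_sidechain_distance(s, c("A", 1), c("A", 2)), brute,
                 tolerance = 1e-9)
    expect_equal(min_sidechain_distance(s, c("A", 2), c("A", 1)),
                 min_sidechain_distance(s, c("A", 1), c("A", 2)))
  }
})

test_that("two single-atom side chains measure their separation", {
  d <- data.frame(chain = "A", resno = c(1, 2), resid = "CYS",
                  elety = "SG", x = c(0, 4), y = 0, z = 0)
  s <- structure_model(d$chain, d$resno, d$resid, d$elety, d$x, d$y, d$z)
  expect_equal(min_sidechain_distance(s, c("A", 1), c("A", 2)), 4)
  # backbone-only residue raises a lookup error
  bb <- data.frame(chain = "A", resno = 3, resid = "GLY",
                   elety = c("N", "CA", "C", "O"), x = 1:4, y = 0, z = 0)
  s2 <- structure_model(c(d$chain, bb$chain), c(d$resno, bb$resno),
                        c(d$resid, bb$resid), c(d$elety, bb$elety),
                        c(d$x, bb$x), c(d$y, bb$y), c(d$z, bb$z))
  expect_error(min_sidechain_distance(s2, c("A", 1), c("A", 3)),
               "side-chain")
})

test_that("synthetic PDB files round-trip through the reader", {
  s <- make_synthetic_structure(n_res = 6, gly_at = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(s, path)
  r <- read_structure(path)
  expect_equal(nrow(r), nrow(s))
  expect_equal(residue_pair_distance(r, c("A", 1), c("A", 5)),
               residue_pair_distance(s, c("A", 1), c("A", 5)),
               tolerance = 1e-3)
  # missing CB on glycine: the structure loads, the lookup is what fails
  expect_error(get_atom <- residue_pair_distance(r, c("A", 3), c("A", 4),
                                                 atom_name = "OG"),
               "not found")
})
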