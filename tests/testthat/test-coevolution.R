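# Mutual information, joint-entropy normalization, Z-scores and the
# tree-based shuffling null.

test_that("joint entropy matches brute-force enumeration on toy columns", {
  # identical two-symbol columns: joint collapses to ln 2
  m <- toy_msa("AA", "AA", "VV", "VV")
  expect_equal(joint_entropy(m, 1, 2), log(2), tolerance = 1e-12)

  # independent uniform 2-symbol columns: product distribution, ln 4
  m2 <- toy_msa("AA", "AV", "VA", "VV")
  expect_equal(joint_entropy(m2, 1, 2), log(4), tolerance = 1e-12)

  # worked 3-sequence toy vs direct frequency count with Henikoff weights
  m3 <- toy_msa("AD", "AE", "VD")
  w <- m3$weights
  joint <- paste(m3$seq[, 1], m3$seq[, 2])
  expect_equal(joint_entropy(m3, 1, 2), brute_entropy(joint, w),
               tolerance = 1e-12)
  expect_equal(normalized_mi(m3, 1, 2)[["mi"]],
               brute_entropy(m3$seq[, 1], w) + brute_entropy(m3$seq[, 2], w) -
                 brute_entropy(joint, w), tolerance = 1e-12)
})

test_that("normalized MI hits its exact fixed points", {
  # duplicated non-constant column -> mi_norm = 1
  dup <- toy_msa("AA", "VV", "AA", "LL")
  expect_equal(normalized_mi(dup, 1, 2)[["mi_norm"]], 1, tolerance = 1e-12)

  # exact product frequencies -> mi = 0
  ind <- toy_msa("AA", "AV", "VA", "VV")
  expect_equal(normalized_mi(ind, 1, 2)[["mi"]], 0, tolerance = 1e-12)

  # constant column -> mi = 0, mi_norm = 0 by the zero-entropy rule
  cst <- toy_msa("AA", "AV", "AA", "AV")
  expect_equal(unname(normalized_mi(cst, 1, 2)), c(0, 0), tolerance = 1e-12)
})

test_that("MI identities hold across random alignments", {
  set.seed(404)
  for (rep in 1:60) {
    n <- sample(5:30, 1)
    L <- 4
    seqs <- replicate(n, paste(sample(c("A", "V", "L", "D", "-"), L,
                                      replace = TRUE, prob = c(.3, .3, .2, .15, .05)),
                               collapse = ""))
    names(seqs) <- sprintf("s%03d", seq_len(n))
    m <- set_henikoff_weights(new_msa(seqs))
    for (pair in list(c(1, 2), c(2, 3), c(1, 4))) {
      i <- pair[1]; j <- pair[2]
      ci <- m$seq[, i]; cj <- m$seq[, j]
      keep <- ci != "-" & cj != "-"
      if (sum(keep) < 2) next
      v_ij <- normalized_mi(m, i, j)
      v_ji <- normalized_mi(m, j, i)
      expect_equal(v_ij[["mi"]], v_ji[["mi"]], tolerance = 1e-12)
      expect_equal(v_ij[["mi_norm"]], v_ji[["mi_norm"]], tolerance = 1e-12)
      expect_gte(v_ij[["mi"]], -1e-12)
      w <- m$weights[keep] / sum(m$weights[keep])
      hi <- brute_entropy(ci[keep], w); hj <- brute_entropy(cj[keep], w)
      expect_lte(v_ij[["mi"]], min(hi, hj) + 1e-9)
      expect_gte(v_ij[["mi_norm"]], 0)
      expect_lte(v_ij[["mi_norm"]], 1 + 1e-12)
    }
  }
})

test_that("Z-scores are standardized and rank a planted pair first", {
  sim <- gen_msa(synthetic_spec(seed = 12, n_positions = 18, n_sequences = 64))
  m <- set_henikoff_weights(sim$msa)
  z <- zscores_all_pairs(m)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(sd(z$z), 1, tolerance = 1e-9)
  expect_true(!is.unsorted(-z$z))

  planted <- data.frame(i = 5, j = 11, epsilon = 0.9)
  sim2 <- gen_msa(synthetic_spec(seed = 13, n_positions = 18,
                                 n_sequences = 150, planted_pairs = planted))
  m2 <- set_henikoff_weights(sim2$msa)
  z2 <- zscores_all_pairs(m2)
  expect_equal(c(z2$i[1], z2$j[1]), c(5, 11))

  tiny <- toy_msa("ACDE", "ACDF", "GCDE")
  expect_warning(try(zscores_all_pairs(tiny), silent = TRUE), "fewer than 10")
})

test_that("tree shuffling preserves column composition and orders p-values sanely", {
  planted <- data.frame(i = 2, j = 6, epsilon = 0.85)
  sim <- gen_msa(synthetic_spec(seed = 31, n_positions = 30, n_sequences = 48,
                                planted_pairs = planted))
  m <- set_henikoff_weights(sim$msa)
  d <- kimura_distance_matrix(m)

  # composition invariance: every replicate's shuffled column is a
  # permutation of the original (symbol multiset preserved)
  res <- tree_shuffle_null(m, d, 2, 6, shuffle_null_spec(seed = 3),
                           return_columns = TRUE)
  orig <- sort(match(m$seq[, 6], c(stabcons:::AA20, "-")))
  for (it in seq_len(ncol(res$columns))) {
    expect_identical(sort(res$columns[, it]), orig)
  }
  expect_true(all(res$null >= 0 & res$null <= 1))
  expect_lte(res$p_shuffle, 0.05) # coupled pair beats its tree null
  expect_equal(res$decay_lambda, 1 / mean(d[upper.tri(d)]), tolerance = 1e-12)

  # p is the null exceedance fraction (floored at its resolution), and an
  # observed score below the null median must give p > 0.5
  for (pr in list(c(1, 4), c(3, 9), c(10, 20), c(5, 25))) {
    rr <- tree_shuffle_null(m, d, pr[1], pr[2], shuffle_null_spec(seed = 4))
    frac <- mean(rr$null >= rr$observed)
    expect_equal(rr$p_shuffle, if (frac == 0) 1 / 101 else frac)
    if (rr$observed < median(rr$null)) expect_gt(rr$p_shuffle, 0.5)
  }

  expect_error(shuffle_null_spec(n_iterations = 5), "n_iterations")
  expect_error(shuffle_null_spec(decay_lambda = -1), "decay_lambda")
  expect_error(tree_shuffle_null(m, NULL, 1, 2,
                                 shuffle_null_spec(decay_lambda = 1)),
               "distances")
})

test_that("shuffling is seeded and reproducible", {
  sim <- gen_msa(synthetic_spec(seed = 44, n_positions = 30, n_sequences = 32))
  m <- set_henikoff_weights(sim$msa)
  d <- kimura_distance_matrix(m)
  a <- tree_shuffle_null(m, d, 1, 2, shuffle_null_spec(seed = 7))
  b <- tree_shuffle_null(m, d, 1, 2, shuffle_null_spec(seed = 7))
  expect_identical(a$null, b$null)
})

test_that("significant_pairs applies both thresholds and spatial annotation", {
  pairs <- data.frame(i = c(50, 51, 113, 113), j = c(51, 55, 123, 118),
                      z = c(4.2, 3.9, 5.0, 4.5),
                      p_shuffle = c(0.029, 0.01, 0.2, 0.022))
  got <- significant_pairs(pairs)
  # z = 4.2, p = 0.029 retained; z = 3.9 excluded; z = 5, p = 0.2 excluded
  expect_equal(got$i, c(50, 113))
  expect_equal(got$spatial_class, c("unknown", "unknown"))

  atoms <- read_structure(paste(
    pdb_atom_line(1, "CB", "ALA", "A", 50, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 51, 3, 0, 0),
    pdb_atom_line(3, "CB", "ALA", "A", 113, 0, 0, 0),
    pdb_atom_line(4, "CB", "ALA", "A", 118, 30, 0, 0), sep = "\n"))
  got2 <- significant_pairs(pairs, atoms = atoms)
  expect_equal(got2$spatial_class, c("proximal", "distant"))
})
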