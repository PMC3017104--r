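# Boltzmann propensities, positional entropies, lethality classification
# and the lethal-vs-viable t-test.

make_scan <- function(ddg_by_pos, wt = "A") {
  muts <- setdiff(c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                    "Q", "R", "S", "T", "V", "W", "Y"), wt)
  rows <- lapply(seq_along(ddg_by_pos), function(k) {
    data.frame(chain = "A", position = k, wt_aa = wt,
               mut_aa = c(wt, muts), ddg = c(0, ddg_by_pos[[k]]))
  })
  df <- do.call(rbind, rows)
  read_ddg_table(paste(c("chain,position,wt_aa,mut_aa,ddg",
                         sprintf("%s,%d,%s,%s,%.17g", df$chain, df$position,
                                 df$wt_aa, df$mut_aa, df$ddg)),
                       collapse = "\n"))
}

test_that("ddG table reader validates alphabet, duplicates and numerics", {
  sc <- make_scan(list(rep(1, 17)))
  expect_s3_class(sc, "ddg_scan")
  expect_equal(length(unique(sc$mut_aa)), 18L) # native + 17 mutants

  expect_error(read_ddg_table(
    "chain,position,wt_aa,mut_aa,ddg\nA,1,A,C,2.0"), "cysteine")
  expect_error(read_ddg_table(
    "chain,position,wt_aa,mut_aa,ddg\nA,1,A,V,2.0\nA,1,A,V,2.1"), "duplicate")
  expect_error(read_ddg_table(
    "chain,position,wt_aa,mut_aa,ddg\nA,1,A,V,oops"), "non-numeric")
  expect_warning(read_ddg_table(
    "chain,position,wt_aa,mut_aa,ddg\nA,1,A,A,0\nA,1,A,V,1"), "fewer than 17")

  gen <- gen_ddg_scan(synthetic_spec(seed = 3, n_positions = 30))
  expect_equal(length(unique(gen$scan$position)), 30L)
})

test_that("Boltzmann propensities reproduce hand-computed oracles", {
  # all ddG equal -> uniform over the 18-letter alphabet
  sc <- make_scan(list(rep(0, 17)))
  p <- boltzmann_propensities(sc, 1)
  expect_equal(unname(p$probs), rep(1 / 18, 18), tolerance = 1e-12)
  expect_equal(p$entropy_nats, log(18), tolerance = 1e-12)
  expect_equal(p$entropy_normalized, log(18) / log(20), tolerance = 1e-12)

  # 3-letter toy at 300 K: 0.59616 kcal/mol = exp(-1) weight
  sc3 <- suppressWarnings(read_ddg_table(
    "chain,position,wt_aa,mut_aa,ddg\nA,1,A,A,0\nA,1,A,V,0.59616\nA,1,A,L,0.59616"))
  p3 <- boltzmann_propensities(sc3, 1)
  expect_equal(unname(p3$probs), c(1, exp(-1), exp(-1)) / (1 + 2 * exp(-1)),
               tolerance = 1e-9)
  expect_equal(round(unname(p3$probs), 3), c(0.576, 0.212, 0.212))
  expect_equal(p3$entropy_nats, 0.975, tolerance = 1e-3)

  # one hugely destabilizing mutant: native dominates, entropy ~ 0
  scd <- suppressWarnings(read_ddg_table(
    "chain,position,wt_aa,mut_aa,ddg\nA,1,A,A,0\nA,1,A,V,50"))
  pd <- boltzmann_propensities(scd, 1)
  expect_equal(unname(pd$probs["A"]), 1, tolerance = 1e-10)
  expect_lt(pd$entropy_nats, 1e-8)

  expect_error(boltzmann_propensities(sc, 99), "not present")
  no_native <- suppressWarnings(read_ddg_table(
    "chain,position,wt_aa,mut_aa,ddg\nA,1,A,V,1.0"))
  expect_error(boltzmann_propensities(no_native, 1), "native")
})

test_that("positional entropy matches direct summation and its bounds", {
  expect_equal(positional_entropy(c(A = 1))[["nats"]], 0)
  p <- c(0.576, 0.212, 0.212)
  expect_equal(positional_entropy(p / sum(p))[["nats"]],
               -sum(p / sum(p) * log(p / sum(p))), tolerance = 1e-12)
  u <- rep(1 / 18, 18)
  expect_equal(positional_entropy(u)[["normalized"]], log(18) / log(20),
               tolerance = 1e-12)
})

test_that("propensities obey shift invariance and temperature monotonicity", {
  set.seed(101)
  for (rep in 1:25) {
    ddg <- runif(17, -2, 6)
    sc <- make_scan(list(ddg))
    base <- boltzmann_propensities(sc, 1)
    # shift invariance: adding a constant to every ddG (native included)
    # must leave the propensities unchanged
    w <- exp(-(ddg + 3.7) / (0.0019872 * 300))
    p_shift <- c(exp(-3.7 / (0.0019872 * 300)), w)
    p_shift <- p_shift / sum(p_shift)
    expect_equal(unname(base$probs), unname(p_shift), tolerance = 1e-9)

    h_cold <- boltzmann_propensities(sc, 1, temperature_K = 250)$entropy_nats
    h_warm <- boltzmann_propensities(sc, 1, temperature_K = 350)$entropy_nats
    expect_gte(h_warm, h_cold - 1e-12)
  }
})

test_that("native recapitulation counts minima and ties correctly", {
  all_native <- make_scan(list(rep(1, 17), rep(0.5, 17)))
  expect_equal(native_recapitulation(all_native), 1.0)

  mixed <- make_scan(list(rep(1, 17), rep(1, 17), rep(1, 17),
                          c(-0.5, rep(1, 16))))
  expect_equal(native_recapitulation(mixed), 0.75)

  tie <- make_scan(list(c(0, rep(1, 16)))) # native ties the best mutant
  expect_equal(native_recapitulation(tie), 1.0)
})

test_that("the +3 kcal/mol classifier reproduces the published calls", {
  phen <- data.frame(
    mutation = c("H113A", "L126A", "A114Y", "L130A", "neutral"),
    ddg = c(8.1, 4.8, 3.0, 10.1, 0.0),
    phenotype = c("lethal", "lethal", "lethal", "lethal", "viable"))
  cls <- classify_mutations(phen, cutoff = 3.0)
  expect_equal(cls$lethal_sensitivity, 1.0) # 3.0 >= 3.0 counts lethal
  expect_equal(cls$viable_specificity, 1.0)
  expect_equal(unname(cls$counts["lethal", "lethal"]), 4L)

  # monotone in cutoff: sensitivity non-increasing, specificity non-decreasing
  spec <- synthetic_spec(seed = 8)
  tab <- gen_phenotype_table(spec)
  cuts <- seq(-2, 8, by = 0.5)
  sens <- sapply(cuts, function(cc) classify_mutations(tab, cc)$lethal_sensitivity)
  specif <- sapply(cuts, function(cc) classify_mutations(tab, cc)$viable_specificity)
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(specif) >= -1e-12))
})

test_that("pooled one-tailed t-test matches stats::t.test and a permutation oracle", {
  a <- c(4.1, 5.0, 3.2, 6.3, 4.4, 5.8)
  b <- c(2.0, 3.1, 2.5, 1.9, 3.3, 2.2, 2.8)
  got <- lethal_viable_ttest(a, b)
  ref <- t.test(a, b, alternative = "greater", var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  pperm <- perm_ttest_p(a, b)
  expect_lt(abs(got$p - pperm), 3 * sqrt(max(pperm, 1e-4) / 1e5) + 2e-3)

  # identical samples: centered at the null
  same <- c(1, 1, 1)
  expect_equal(lethal_viable_ttest(same, same)$p, 0.5)
  expect_error(lethal_viable_ttest(1, c(1, 2)), "size")

  # large planted effect at the published sample sizes is overwhelming
  set.seed(5)
  strong <- lethal_viable_ttest(rnorm(27, 5, 1), rnorm(35, 0, 1))
  expect_lt(strong$p, 1e-6)

  w <- lethal_viable_ttest(a, b, welch = TRUE)
  refw <- t.test(a, b, alternative = "greater")
  expect_equal(w$p, refw$p.value, tolerance = 1e-12)
})
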