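# Shared in-code fixtures: tiny PDB records, toy alignments, brute-force
# oracles.

pdb_atom_line <- function(serial, atom, res, chain, resnum, x, y, z,
                          occ = 1.0, elem = "C", altloc = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          serial, paste0(" ", atom), altloc, res, chain, resnum, x, y, z,
          occ, elem)
}

# MSA from unnamed sequences, auto-ids, Henikoff weights attached
toy_msa <- function(..., weights = TRUE) {
  seqs <- c(...)
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  m <- new_msa(seqs)
  if (weights) m <- set_henikoff_weights(m)
  m
}

# Brute-force weighted entropy of a symbol vector (independent oracle for
# the rowsum-based implementation)
brute_entropy <- function(symbols, w = rep(1 / length(symbols), length(symbols))) {
  w <- w / sum(w)
  f <- tapply(w, symbols, sum)
  f <- f[f > 0]
  -sum(f * log(f))
}

# Exposed area of each of two equal spheres of expanded radius R whose
# centers are d apart: full sphere minus the buried spherical cap.
two_sphere_cap_area <- function(R, d) {
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# Permutation p-value oracle for the one-tailed two-sample mean test
perm_ttest_p <- function(a, b, n_perm = 1e5, seed = 42) {
  set.seed(seed)
  pooled <- c(a, b)
  obs <- mean(a) - mean(b)
  stat <- replicate(n_perm, {
    idx <- sample(length(pooled), length(a))
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  mean(stat >= obs)
}
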