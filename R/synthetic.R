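## Seeded generators for every pipeline input class, with known ground
## truth: toy structures, ddG scans, tree-simulated alignments and
## phenotype tables.

#' Specification for the synthetic-data generators
#'
#' Bundles the knobs of all generators. Defaults mirror the study
#' conditions the pipeline targets: 223 sequences (the size of a typical
#' curated histone family alignment), ddG spread of 3 kcal/mol (the scale
#' of the lethality threshold), phenotype samples of 27 lethal and 35
#' viable mutations.
#'
#' @param seed RNG seed; every generator is deterministic given the spec.
#' @param n_positions Alignment length / scan size.
#' @param n_sequences Number of sequences (>= 4).
#' @param tree_shape `"balanced"` (default: a perfect binary ultrametric
#'   tree, pruned deterministically when `n_sequences` is not a power of
#'   2), `"coalescent"` (random ultrametric; ancestry concentrates in a
#'   few deep lineages, as in real species samples) or `"iid"` (no tree:
#'   every cell drawn independently).
#' @param tree_depth Root-to-tip height in expected substitutions per
#'   site (default 2: leaves close to site stationarity).
#' @param q Per-site conservation: probability mass of the dominant
#'   letter, scalar or length-`n_positions` vector in (0, 1\]; `NULL`
#'   draws each site's q uniformly from \[0.5, 1\]. `q = 0.05` gives the
#'   uniform 20-letter distribution.
#' @param planted_pairs Data frame `i`, `j`, `epsilon` of coevolving
#'   column pairs (positions pairwise disjoint); `epsilon` in \[0, 1) is
#'   the probability a sequence emits the latent-state letter pair rather
#'   than independent letters.
#' @param ddg_spread Scale (kcal/mol) of the mutant ddG gaps in
#'   [gen_ddg_scan()]; 0 gives flat scans (maximal entropy), large values
#'   freeze each position.
#' @param effect_size Mean ddG shift (kcal/mol) of lethal over viable
#'   mutations in [gen_phenotype_table()].
#' @param n_lethal,n_viable Phenotype sample sizes (defaults 27 / 35).
#' @param sigma Within-class ddG standard deviation, kcal/mol.
#' @param mu_viable Mean viable ddG, kcal/mol.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_positions = 30L, n_sequences = 223L,
                           tree_shape = c("balanced", "coalescent", "iid"),
                           tree_depth = 2, q = NULL, planted_pairs = NULL,
                           ddg_spread = 3, effect_size = 3,
                           n_lethal = 27L, n_viable = 35L, sigma = 2,
                           mu_viable = 1) {
  tree_shape <- match.arg(tree_shape)
  if (!is.null(planted_pairs)) {
    pp <- unlist(planted_pairs[, c("i", "j")])
    if (anyDuplicated(pp)) stop("planted pair positions must be disjoint")
    if (any(pp < 1 | pp > n_positions)) stop("planted pair position out of range")
  }
  if (!is.null(q) && (any(q <= 0) || any(q > 1))) stop("q must be in (0, 1]")
  structure(list(seed = as.integer(seed), n_positions = as.integer(n_positions),
                 n_sequences = as.integer(n_sequences),
                 tree_shape = tree_shape, tree_depth = tree_depth, q = q,
                 planted_pairs = planted_pairs, ddg_spread = ddg_spread,
                 effect_size = effect_size, n_lethal = as.integer(n_lethal),
                 n_viable = as.integer(n_viable), sigma = sigma,
                 mu_viable = mu_viable),
            class = "synthetic_spec")
}

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Toy structure with a known buried core
#'
#' Builds a cubic cluster of single-carbon pseudo-residues on a 2.8 A
#' grid: interior grid points are fully enclosed by their 26 neighbours
#' (SASA exactly 0 at any dot density), shell residues stay well above
#' the 1 A^2 burial threshold. Deterministic; no randomness involved.
#'
#' @param n_side Residues per cube edge (default 3; `n_side = 1` has no
#'   interior, so nothing is buried).
#' @param spacing Grid spacing in Angstrom.
#' @return List: `pdb_text` (legal ATOM records, chain A, residues
#'   numbered from 1), `buried_truth` (data frame `chain`, `resnum` of
#'   interior residues), `n_residues`.
#' @export
gen_toy_structure <- function(n_side = 3L, spacing = 2.8) {
  stopifnot(n_side >= 1)
  g <- seq_len(n_side)
  grid <- expand.grid(ix = g, iy = g, iz = g)
  n <- nrow(grid)
  interior <- grid$ix > 1 & grid$ix < n_side &
    grid$iy > 1 & grid$iy < n_side & grid$iz > 1 & grid$iz < n_side
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n),
    grid$ix * spacing, grid$iy * spacing, grid$iz * spacing)
  list(pdb_text = paste(c(lines, "END"), collapse = "\n"),
       buried_truth = data.frame(chain = rep("A", sum(interior)),
                                 resnum = which(interior)),
       n_residues = n)
}

## Entropy of the Boltzmann distribution with native gap 0 and mutant
## gaps `gaps` (kcal/mol) at temperature T.
#' @noRd
boltz_entropy_from_gaps <- function(gaps, temperature_K = 300) {
  w <- exp(-c(0, gaps) / (KB_KCAL * temperature_K))
  shannon(w / sum(w))
}

#' Synthetic ddG mutational scan with planted positional entropies
#'
#' For each position a preferred (native) amino acid is drawn and the 17
#' mutant ddG values are designed by inverse solving: heterogeneous gap
#' directions are scaled (1-d root finding) until the Boltzmann entropy
#' of the position matches a target drawn from a `ddg_spread`-scaled
#' family. The returned targets are the achieved entropies of the
#' planted values, so they round-trip exactly through the CSV format and
#' [boltzmann_propensities()].
#'
#' @param spec A [synthetic_spec()]; uses `seed`, `n_positions`,
#'   `ddg_spread`.
#' @param temperature_K Temperature of the designed scan (default 300).
#' @return List: `scan` (a `ddg_scan`), `csv_text` (full-precision CSV),
#'   `targets` (data frame `position`, `entropy_nats`,
#'   `entropy_normalized`).
#' @export
gen_ddg_scan <- function(spec = synthetic_spec(), temperature_K = 300) {
  with_seed(spec$seed, {
    alphabet <- setdiff(AA20, c("C", "P"))
    rows <- list(); targets <- list()
    for (pos in seq_len(spec$n_positions)) {
      wt <- sample(alphabet, 1)
      muts <- setdiff(alphabet, wt)
      dirs <- stats::runif(17, 0.5, 1.5)
      t0 <- spec$ddg_spread * stats::runif(1, 0.5, 1.5)
      h_target <- boltz_entropy_from_gaps(rep(t0, 17), temperature_K)
      if (t0 == 0) {
        scale <- 0
      } else {
        f <- function(s) boltz_entropy_from_gaps(s * dirs, temperature_K) - h_target
        upper <- 4 * t0 + 10
        while (f(upper) > 0) upper <- upper * 2
        scale <- stats::uniroot(f, c(0, upper), tol = 1e-13)$root
      }
      gaps <- scale * dirs
      h <- boltz_entropy_from_gaps(gaps, temperature_K)
      rows[[pos]] <- data.frame(
        chain = "A", position = pos, wt_aa = wt,
        mut_aa = c(wt, muts), ddg = c(0, gaps),
        sem = c(0, stats::runif(17, 0.05, 0.5)), ddg_type = "stability")
      targets[[pos]] <- data.frame(position = pos, entropy_nats = h,
                                   entropy_normalized = h / log(20))
    }
    df <- do.call(rbind, rows)
    csv <- paste(c(paste(names(df), collapse = ","),
                   sprintf("%s,%d,%s,%s,%.17g,%.17g,%s", df$chain, df$position,
                           df$wt_aa, df$mut_aa, df$ddg, df$sem, df$ddg_type)),
                 collapse = "\n")
    list(scan = read_ddg_table(csv, temperature_K = temperature_K),
         csv_text = csv,
         targets = do.call(rbind, targets))
  })
}

#' @noRd
stationary_dist <- function(dominant_code, q) {
  p <- rep((1 - q) / 19, 20)
  p[dominant_code] <- q
  p
}

#' Tree-simulated alignment with planted coevolving pairs
#'
#' Simulates amino-acid columns down an ultrametric tree: along each
#' branch of length t, each site is redrawn from its stationary
#' distribution with probability \eqn{1 - e^{-t}} (substitution rate 1
#' per site). Site k's stationary distribution puts mass `q_k` on a
#' random dominant letter and spreads the rest uniformly. For each
#' planted pair a latent binary state evolves down the same tree
#' (switch probability \eqn{1 - e^{-t}}) and each leaf emits the state's
#' compatible letter pair with probability `epsilon`, otherwise its
#' independently simulated letters: coevolution is phylogeny-aware, so
#' the tree-based null is meaningfully exercised.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `msa` (a `weighted_msa`, weights unset), `tree` (a
#'   `phylo`, or `NULL` for `tree_shape = "iid"`), `expected_entropy`
#'   (per-column stationary normalized entropy, mixture-adjusted for
#'   planted columns), `planted_pairs` (echo of the spec, with the
#'   latent-state letter pairs), `spec`.
#' @export
gen_msa <- function(spec = synthetic_spec()) {
  if (spec$n_sequences < 4) stop("n_sequences must be >= 4")
  with_seed(spec$seed, {
    L <- spec$n_positions
    n <- spec$n_sequences
    q <- spec$q
    if (is.null(q)) q <- stats::runif(L, 0.5, 1)
    if (length(q) == 1L) q <- rep(q, L)
    dominant <- sample.int(20L, L, replace = TRUE)
    stat <- lapply(seq_len(L), function(k) stationary_dist(dominant[k], q[k]))

    draw_site <- function(k, m) sample.int(20L, m, replace = TRUE, prob = stat[[k]])

    if (spec$tree_shape == "iid") {
      tree <- NULL
      leaf_states <- vapply(seq_len(L), function(k) draw_site(k, n), integer(n))
      latent <- matrix(sample(1:2, n * max(1, NROW(spec$planted_pairs)),
                              replace = TRUE), nrow = n)
    } else {
      tree <- if (spec$tree_shape == "balanced") {
        k <- ceiling(log2(n))
        t <- ape::stree(2^k, type = "balanced")
        t$edge.length <- rep(spec$tree_depth / k, nrow(t$edge))
        if (2^k > n) {
          ## deterministic, evenly spaced pruning down to n leaves
          drop <- round(seq(1, 2^k, length.out = 2^k - n))
          t <- ape::drop.tip(t, t$tip.label[drop])
        }
        t
      } else {
        t <- ape::rcoal(n)
        t$edge.length <- t$edge.length * spec$tree_depth /
          max(ape::node.depth.edgelength(t))
        t
      }
      tree$tip.label <- sprintf("seq%03d", seq_len(n))
      ntip <- n
      nnode <- tree$Nnode
      states <- matrix(NA_integer_, ntip + nnode, L)
      lat <- matrix(NA_integer_, ntip + nnode,
                    max(1, NROW(spec$planted_pairs)))
      root <- ntip + 1L
      states[root, ] <- vapply(seq_len(L), function(k) draw_site(k, 1L), integer(1))
      lat[root, ] <- sample(1:2, ncol(lat), replace = TRUE)
      ## preorder: parents before children
      for (e in rev(ape::postorder(tree))) {
        par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
        t_len <- tree$edge.length[e]
        s <- states[par, ]
        flip <- stats::runif(L) < 1 - exp(-t_len)
        if (any(flip)) {
          s[flip] <- vapply(which(flip), function(k) draw_site(k, 1L), integer(1))
        }
        states[child, ] <- s
        lv <- lat[par, ]
        sw <- stats::runif(length(lv)) < 1 - exp(-t_len)
        lv[sw] <- 3L - lv[sw]
        lat[child, ] <- lv
      }
      leaf_states <- states[seq_len(ntip), , drop = FALSE]
      latent <- lat[seq_len(ntip), , drop = FALSE]
    }

    planted <- spec$planted_pairs
    if (!is.null(planted) && nrow(planted)) {
      planted$aa_i1 <- planted$aa_i2 <- planted$aa_j1 <- planted$aa_j2 <- NA_character_
      for (k in seq_len(nrow(planted))) {
        li <- sample.int(20L, 2)   # state letters at column i
        lj <- sample.int(20L, 2)   # state letters at column j
        use <- stats::runif(n) < planted$epsilon[k]
        st <- latent[, k]
        leaf_states[use, planted$i[k]] <- li[st[use]]
        leaf_states[use, planted$j[k]] <- lj[st[use]]
        planted$aa_i1[k] <- AA20[li[1]]; planted$aa_i2[k] <- AA20[li[2]]
        planted$aa_j1[k] <- AA20[lj[1]]; planted$aa_j2[k] <- AA20[lj[2]]
      }
    }

    expected <- vapply(seq_len(L), function(k) shannon(stat[[k]]) / log(20),
                       numeric(1))
    if (!is.null(planted) && nrow(planted)) {
      for (k in seq_len(nrow(planted))) {
        eps <- planted$epsilon[k]
        for (col in c("i", "j")) {
          pos <- planted[[col]][k]
          ll <- if (col == "i") c(planted$aa_i1[k], planted$aa_i2[k])
                else c(planted$aa_j1[k], planted$aa_j2[k])
          mix <- (1 - eps) * stat[[pos]]
          mix[match(ll, AA20)] <- mix[match(ll, AA20)] + eps / 2
          expected[pos] <- shannon(mix) / log(20)
        }
      }
    }

    seqs <- apply(leaf_states, 1, function(r) paste(AA20[r], collapse = ""))
    ids <- if (is.null(tree)) sprintf("seq%03d", seq_len(n)) else tree$tip.label
    names(seqs) <- ids
    list(msa = new_msa(seqs), tree = tree, expected_entropy = expected,
         planted_pairs = planted, spec = spec)
  })
}

#' Synthetic lethal/viable mutant phenotype table
#'
#' Lethal ddG values are drawn from Normal(`mu_viable` + `effect_size`,
#' `sigma`), viable ones from Normal(`mu_viable`, `sigma`).
#'
#' @param spec A [synthetic_spec()]; uses `seed`, `n_lethal`, `n_viable`,
#'   `effect_size`, `sigma`, `mu_viable`.
#' @return Data frame `mutation`, `ddg`, `phenotype`.
#' @export
gen_phenotype_table <- function(spec = synthetic_spec()) {
  with_seed(spec$seed, {
    lethal <- stats::rnorm(spec$n_lethal, spec$mu_viable + spec$effect_size,
                           spec$sigma)
    viable <- stats::rnorm(spec$n_viable, spec$mu_viable, spec$sigma)
    data.frame(
      mutation = sprintf("M%03d", seq_len(spec$n_lethal + spec$n_viable)),
      ddg = c(lethal, viable),
      phenotype = rep(c("lethal", "viable"), c(spec$n_lethal, spec$n_viable)))
  })
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits PDB, ddG CSV, FASTA alignment, Newick tree and phenotype CSV
#' fixtures plus a YAML manifest recording the spec and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths and ground truths.
#' @export
write_synthetic_bundle <- function(spec = synthetic_spec(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  toy <- gen_toy_structure()
  writeLines(toy$pdb_text, p("structure.pdb"))
  ddg <- gen_ddg_scan(spec)
  writeLines(ddg$csv_text, p("ddg_scan.csv"))
  sim <- gen_msa(spec)
  write_msa_fasta(sim$msa, p("alignment.fasta"))
  if (!is.null(sim$tree)) ape::write.tree(sim$tree, p("tree.nwk"))
  phen <- gen_phenotype_table(spec)
  utils::write.csv(phen, p("phenotypes.csv"), row.names = FALSE, quote = FALSE)
  manifest <- spec
  class(manifest) <- NULL
  manifest$planted_pairs <- if (is.null(spec$planted_pairs)) NULL else
    as.list(spec$planted_pairs)
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(list(structure = p("structure.pdb"), ddg_table = p("ddg_scan.csv"),
                 alignment = p("alignment.fasta"),
                 tree = if (is.null(sim$tree)) NULL else p("tree.nwk"),
                 phenotype_table = p("phenotypes.csv"),
                 manifest = p("manifest.yaml"),
                 buried_truth = toy$buried_truth, ddg_targets = ddg$targets,
                 expected_entropy = sim$expected_entropy,
                 planted_pairs = sim$planted_pairs))
}
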