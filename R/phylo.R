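## Kimura-corrected protein distances, neighbor-joining trees, and
## per-node conservation profiles.

#' Kimura-corrected protein distance matrix
#'
#' For each sequence pair, the observed mismatch fraction `p` is computed
#' over columns where neither sequence is gapped, then corrected for
#' multiple substitutions: \eqn{d = -\ln(1 - p - p^2/5)} (substitutions
#' per site).
#'
#' @param msa A `weighted_msa`.
#' @return Square symmetric numeric matrix with the sequence ids as
#'   dimnames; errors (naming the pair) when a pair is saturated, i.e.
#'   \eqn{1 - p - p^2/5 \le 0}.
#' @export
kimura_distance_matrix <- function(msa) {
  codes <- msa_codes(msa)
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (a in seq_len(n - 1)) {
    ca <- codes[a, ]
    for (b in (a + 1):n) {
      cb <- codes[b, ]
      keep <- ca != GAP_CODE & cb != GAP_CODE
      if (!any(keep)) stop(sprintf("pair (%s, %s): no ungapped columns",
                                   msa$ids[a], msa$ids[b]))
      p <- mean(ca[keep] != cb[keep])
      arg <- 1 - p - p^2 / 5
      if (arg <= 0) {
        stop(sprintf("pair (%s, %s): distance saturated (p = %.3f)",
                     msa$ids[a], msa$ids[b], p))
      }
      d[a, b] <- d[b, a] <- -log(arg)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch lengths,
#' which NJ can produce on non-additive input, are clamped to zero and
#' counted in the `clamped_branches` attribute.
#'
#' @param dist Square symmetric distance matrix with dimnames.
#' @return An unrooted `phylo` tree over the sequence ids.
#' @export
neighbor_joining <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3) stop("neighbor joining needs at least 3 sequences")
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix is not symmetric")
  tree <- ape::nj(dist)
  neg <- tree$edge.length < 0
  if (any(neg)) tree$edge.length[neg] <- 0
  attr(tree, "clamped_branches") <- sum(neg)
  tree
}

#' Path-length (patristic) distances of a tree
#' @param tree A `phylo`.
#' @return Matrix of leaf-to-leaf path distances.
#' @export
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Per-node conservation profile at one alignment position
#'
#' For every internal node of the tree, computes the amino-acid frequency
#' vector of the alignment column restricted to the node's leaf
#' descendants (gaps excluded) and the preferred (most frequent) amino
#' acid, ties broken alphabetically. Disjoint clades preferring different
#' letters mark a position whose conservation is tree-determinant.
#'
#' @param tree A `phylo` whose tip labels are (a subset of) the MSA ids.
#' @param msa A `weighted_msa`.
#' @param position Column index.
#' @return Data frame: `node` (ape node number), `position`,
#'   `preferred_aa`, `frequency` (of the preferred letter), `n_leaves`;
#'   attribute `profiles` holds the full named frequency vector per node.
#' @export
node_conservation_profile <- function(tree, msa, position) {
  if (position < 1 || position > ncol(msa$seq)) stop("position out of range")
  if (!all(tree$tip.label %in% msa$ids)) {
    stop("tree has tips absent from the alignment")
  }
  col <- msa$seq[match(tree$tip.label, msa$ids), position]
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  tips <- phangorn::Descendants(tree, nodes, type = "tips")
  profiles <- list()
  rows <- lapply(seq_along(nodes), function(k) {
    letters <- col[tips[[k]]]
    letters <- letters[letters %in% AA20]
    if (!length(letters)) {
      profiles[[as.character(nodes[k])]] <<- numeric(0)
      return(data.frame(node = nodes[k], position = position,
                        preferred_aa = NA_character_, frequency = NA_real_,
                        n_leaves = length(tips[[k]])))
    }
    f <- table(letters) / length(letters)
    f <- f[order(names(f))]
    profiles[[as.character(nodes[k])]] <<- as.numeric(f) |>
      stats::setNames(names(f))
    pref <- names(f)[which.max(f)] # ties: alphabetical (first of sorted)
    data.frame(node = nodes[k], position = position, preferred_aa = pref,
               frequency = max(as.numeric(f)), n_leaves = length(tips[[k]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  out
}

#' Is a position's conservation tree-determinant?
#'
#' A position is tree-determinant when at least two disjoint internal
#' clades, each covering at least `min_leaf_frac` of the leaves, prefer
#' different amino acids with within-clade frequency at least
#' `min_within_freq` (e.g. a serine/alanine split between kingdoms).
#'
#' @inheritParams node_conservation_profile
#' @param min_leaf_frac Minimum clade size as a fraction of leaves
#'   (default 0.1).
#' @param min_within_freq Minimum within-clade frequency of the preferred
#'   letter (default 0.8).
#' @return List: `tree_determinant` (logical), `clades` (data frame of
#'   the supporting nodes, possibly empty).
#' @export
tree_determinant <- function(tree, msa, position, min_leaf_frac = 0.1,
                             min_within_freq = 0.8) {
  prof <- node_conservation_profile(tree, msa, position)
  ntip <- length(tree$tip.label)
  cand <- prof[!is.na(prof$frequency) &
                 prof$frequency >= min_within_freq &
                 prof$n_leaves >= min_leaf_frac * ntip, , drop = FALSE]
  tips <- phangorn::Descendants(tree, cand$node, type = "tips")
  if (nrow(cand) >= 2) {
    for (a in seq_len(nrow(cand) - 1)) {
      for (b in (a + 1):nrow(cand)) {
        if (cand$preferred_aa[a] != cand$preferred_aa[b] &&
            !length(intersect(tips[[a]], tips[[b]]))) {
          return(list(tree_determinant = TRUE,
                      clades = cand[c(a, b), , drop = FALSE]))
        }
      }
    }
  }
  list(tree_determinant = FALSE, clades = cand[0, , drop = FALSE])
}

#' Write a distance matrix in PHYLIP square format
#' @param dist Square matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_phylip_dist <- function(dist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dist)), con)
  for (k in seq_len(nrow(dist))) {
    writeLines(paste(formatC(rownames(dist)[k], width = -10),
                     paste(sprintf("%.6f", dist[k, ]), collapse = " ")), con)
  }
  invisible(path)
}
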