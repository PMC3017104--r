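## Normalized mutual information between alignment columns, Z-scores,
## and the tree-based shuffling null model.

#' @noRd
msa_codes <- function(msa) {
  m <- matrix(aa_to_code(msa$seq), nrow(msa$seq), ncol(msa$seq))
  rownames(m) <- msa$ids
  m
}

## Weighted marginal / joint entropies of two integer-coded columns.
## Sequences gapped at either column are dropped and weights renormalized
## (set gap_as_symbol = TRUE to keep them as a 21st symbol).
#' @noRd
pair_entropies <- function(ci, cj, w, gap_as_symbol = FALSE) {
  if (!gap_as_symbol) {
    keep <- ci != GAP_CODE & cj != GAP_CODE
    if (!any(keep)) {
      return(list(h_i = NA_real_, h_j = NA_real_, h_joint = NA_real_))
    }
    ci <- ci[keep]; cj <- cj[keep]; w <- w[keep]
  }
  w <- w / sum(w)
  fi <- rowsum(w, ci)[, 1]
  fj <- rowsum(w, cj)[, 1]
  fij <- rowsum(w, (ci - 1L) * 21L + cj)[, 1]
  list(h_i = shannon(fi), h_j = shannon(fj), h_joint = shannon(fij))
}

#' Weighted joint entropy of two alignment columns
#'
#' \eqn{H(i,j) = -\sum_{a,b} f(a,b) \ln f(a,b)} over Henikoff-weighted
#' joint symbol frequencies. Sequences gapped at either column are
#' dropped (weights renormalized).
#'
#' @param msa A `weighted_msa` with weights set.
#' @param i,j Column indices.
#' @param gap_as_symbol Treat the gap as a 21st symbol instead of
#'   dropping gapped sequences?
#' @return Joint entropy in nats; `NA` (flagged with a warning) when all
#'   sequences are gapped at the pair.
#' @export
joint_entropy <- function(msa, i, j, gap_as_symbol = FALSE) {
  w <- require_weights(msa)
  codes <- msa_codes(msa)
  h <- pair_entropies(codes[, i], codes[, j], w, gap_as_symbol)
  if (is.na(h$h_joint)) warning(sprintf("pair (%d, %d): all sequences gapped", i, j))
  h$h_joint
}

#' Mutual information and joint-entropy-normalized MI of a column pair
#'
#' \eqn{MI(i,j) = H(i) + H(j) - H(i,j)}, normalized by the joint entropy:
#' \eqn{MI_N(i,j) = MI(i,j)/H(i,j)} (0 when \eqn{H(i,j) = 0}), which
#' bounds the score to \[0, 1\] and decouples it from the columns'
#' individual variability.
#'
#' @inheritParams joint_entropy
#' @return Named numeric vector `c(mi = , mi_norm = )`.
#' @export
normalized_mi <- function(msa, i, j, gap_as_symbol = FALSE) {
  w <- require_weights(msa)
  codes <- msa_codes(msa)
  mi_from_entropies(pair_entropies(codes[, i], codes[, j], w, gap_as_symbol))
}

#' @noRd
mi_from_entropies <- function(h) {
  mi <- h$h_i + h$h_j - h$h_joint
  if (is.finite(mi) && mi < 0) mi <- max(mi, 0) # clip float negatives
  mi_norm <- if (!is.finite(h$h_joint) || h$h_joint <= 0) 0 else mi / h$h_joint
  c(mi = mi, mi_norm = mi_norm)
}

#' Normalized-MI Z-scores over all column pairs
#'
#' Computes MI and joint-entropy-normalized MI for every pair of the
#' requested columns, then standardizes: \eqn{z(i,j) = (MI_N(i,j) -
#' \bar{MI_N}) / sd(MI_N)} with mean and standard deviation taken over
#' all analyzed pairs. A Z-score of 4 or more flags significant
#' coevolution.
#'
#' @param msa A `weighted_msa` with weights set.
#' @param positions Columns to analyze (default all).
#' @param gap_as_symbol See [joint_entropy()].
#' @return Data frame sorted by `z` descending: `i`, `j`, `mi`,
#'   `joint_entropy`, `mi_norm`, `z`.
#' @export
zscores_all_pairs <- function(msa, positions = seq_len(ncol(msa$seq)),
                              gap_as_symbol = FALSE) {
  w <- require_weights(msa)
  codes <- msa_codes(msa)
  pr <- utils::combn(positions, 2)
  n <- ncol(pr)
  if (n < 10) warning("fewer than 10 eligible pairs; Z-scores are unstable")
  mi <- numeric(n); hij <- numeric(n); mn <- numeric(n)
  for (k in seq_len(n)) {
    h <- pair_entropies(codes[, pr[1, k]], codes[, pr[2, k]], w, gap_as_symbol)
    v <- mi_from_entropies(h)
    mi[k] <- v["mi"]; hij[k] <- h$h_joint; mn[k] <- v["mi_norm"]
  }
  s <- stats::sd(mn)
  if (!is.finite(s) || s == 0) {
    stop("degenerate alignment: normalized MI has zero variance across pairs")
  }
  out <- data.frame(i = pr[1, ], j = pr[2, ], mi = mi, joint_entropy = hij,
                    mi_norm = mn, z = (mn - mean(mn)) / s)
  out <- out[order(-out$z), ]
  rownames(out) <- NULL
  out
}

#' Specification of the tree-based shuffling null
#'
#' @param n_iterations Null replicates (default 100; at least 20 for a
#'   usable p-value).
#' @param n_shuffles Symbol swaps per replicate (default 2000).
#' @param decay_lambda Distance-decay rate of the swap probability
#'   \eqn{\exp(-\lambda d(a,b))}; `NULL` = 1 / mean pairwise distance;
#'   0 = uniform swapping.
#' @param seed RNG seed recorded with every result.
#' @return List of class `shuffle_null_spec`.
#' @export
shuffle_null_spec <- function(n_iterations = 100, n_shuffles = 2000,
                              decay_lambda = NULL, seed = 1L) {
  if (n_iterations < 20) stop("n_iterations must be >= 20 for p-value reporting")
  if (!is.null(decay_lambda) && decay_lambda < 0) stop("decay_lambda must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_shuffles = as.integer(n_shuffles),
                 decay_lambda = decay_lambda, seed = as.integer(seed)),
            class = "shuffle_null_spec")
}

#' Tree-based shuffling null p-value for one column pair
#'
#' Builds a null distribution of the normalized MI by repeatedly swapping
#' the symbols of column `j` between sequence pairs drawn with
#' probability proportional to \eqn{\exp(-\lambda d(a,b))}, where
#' \eqn{d(a,b)} is the genetic distance between sequences a and b: close
#' relatives trade symbols preferentially, so tree-wide conservation
#' structure survives while the specific i-j coupling is destroyed.
#' Column `i` is held fixed. The p-value is the fraction of null
#' replicates whose MI_N is at least the observed value; p below 0.05 is
#' considered significant. An exact zero is floored to
#' `1/(n_iterations + 1)` (the resolution of the null).
#'
#' @param msa A `weighted_msa` with weights set.
#' @param distances Square symmetric genetic-distance matrix over the
#'   MSA's sequence ids (e.g. [kimura_distance_matrix()]); may be `NULL`
#'   when `decay_lambda = 0` (uniform swapping).
#' @param i,j Column indices; column `j` is shuffled.
#' @param spec A [shuffle_null_spec()].
#' @param gap_as_symbol See [joint_entropy()].
#' @param return_columns Also return the shuffled column-j code vectors
#'   (one per replicate, for diagnostics)?
#' @return List: `p_shuffle`, `observed` (MI_N), `null` (vector of null
#'   MI_N values), `decay_lambda`, `seed`, and with
#'   `return_columns = TRUE` a `columns` matrix (replicates in columns).
#' @export
tree_shuffle_null <- function(msa, distances, i, j,
                              spec = shuffle_null_spec(),
                              gap_as_symbol = FALSE,
                              return_columns = FALSE) {
  w <- require_weights(msa)
  codes <- msa_codes(msa)
  n_seq <- nrow(codes)
  lambda <- spec$decay_lambda
  if (is.null(distances)) {
    if (is.null(lambda) || lambda > 0) {
      stop("distances are required unless decay_lambda = 0")
    }
  } else {
    if (!all(msa$ids %in% rownames(distances))) {
      stop("distance matrix does not cover all sequences")
    }
    distances <- distances[msa$ids, msa$ids]
  }
  pairs <- utils::combn(n_seq, 2)
  if (is.null(lambda)) {
    lambda <- 1 / mean(distances[upper.tri(distances)])
  }
  prob <- if (lambda == 0 || is.null(distances)) {
    rep(1, ncol(pairs))
  } else {
    exp(-lambda * distances[cbind(pairs[1, ], pairs[2, ])])
  }
  prob <- prob / sum(prob)

  ci <- codes[, i]; cj <- codes[, j]
  observed <- mi_from_entropies(pair_entropies(ci, cj, w, gap_as_symbol))["mi_norm"]

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  null <- numeric(spec$n_iterations)
  cols <- if (return_columns) {
    matrix(NA_integer_, n_seq, spec$n_iterations)
  }
  for (it in seq_len(spec$n_iterations)) {
    sel <- sample.int(ncol(pairs), spec$n_shuffles, replace = TRUE, prob = prob)
    col <- cj
    for (s in sel) {
      a <- pairs[1, s]; b <- pairs[2, s]
      tmp <- col[a]; col[a] <- col[b]; col[b] <- tmp
    }
    if (return_columns) cols[, it] <- col
    null[it] <- mi_from_entropies(pair_entropies(ci, col, w, gap_as_symbol))["mi_norm"]
  }
  p <- mean(null >= observed)
  if (p == 0) p <- 1 / (spec$n_iterations + 1)
  out <- list(p_shuffle = p, observed = unname(observed), null = null,
              decay_lambda = lambda, seed = spec$seed)
  if (return_columns) out$columns <- cols
  out
}

#' Filter coevolving pairs by Z-score and shuffle p-value
#'
#' Retains pairs with `z >= z_min` and `p_shuffle < p_max` and, when a
#' structure is supplied, annotates each pair as spatially `proximal`
#' (C-beta to C-beta distance, C-alpha for glycine, at most
#' `proximal_cutoff` Angstrom) or `distant`; `unknown` without a
#' structure.
#'
#' @param pairs Data frame with at least `i`, `j`, `z`, `p_shuffle`.
#' @param z_min Minimum Z-score (default 4).
#' @param p_max Maximum shuffle p-value (default 0.05), strict.
#' @param atoms Optional atom table ([read_structure()]); positions are
#'   matched to residue numbers.
#' @param chain Chain used for the distance lookup (default first chain).
#' @param proximal_cutoff Distance cutoff in Angstrom (default 8).
#' @return Filtered data frame with a `spatial_class` column.
#' @export
significant_pairs <- function(pairs, z_min = 4, p_max = 0.05, atoms = NULL,
                              chain = NULL, proximal_cutoff = 8) {
  keep <- pairs$z >= z_min & !is.na(pairs$p_shuffle) & pairs$p_shuffle < p_max
  out <- pairs[keep, , drop = FALSE]
  out$spatial_class <- rep("unknown", nrow(out))
  if (!is.null(atoms) && nrow(out)) {
    if (is.null(chain)) chain <- atoms$chain[1]
    cb <- cbeta_coords(atoms, chain)
    for (k in seq_len(nrow(out))) {
      a <- cb[[as.character(out$i[k])]]
      b <- cb[[as.character(out$j[k])]]
      if (is.null(a) || is.null(b)) next
      d <- sqrt(sum((a - b)^2))
      out$spatial_class[k] <- if (d <= proximal_cutoff) "proximal" else "distant"
    }
  }
  rownames(out) <- NULL
  out
}

#' @noRd
cbeta_coords <- function(atoms, chain) {
  sub <- atoms[atoms$chain == chain, , drop = FALSE]
  out <- list()
  for (rn in unique(sub$resnum)) {
    r <- sub[sub$resnum == rn, , drop = FALSE]
    row <- r[r$atom == "CB", , drop = FALSE]
    if (nrow(row) == 0L) row <- r[r$atom == "CA", , drop = FALSE]
    if (nrow(row) == 0L) row <- r[1, , drop = FALSE]
    out[[as.character(rn)]] <- c(row$x[1], row$y[1], row$z[1])
  }
  out
}
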