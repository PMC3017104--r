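## Alignment handling, Henikoff weights, evolutionary entropy,
## entropy-entropy correlation and three-set partitioning.

#' Construct a weighted MSA from named sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (20 amino acids + `-` gap).
#' @param species Optional species labels (default: the names).
#' @return Object of class `weighted_msa`: `ids`, `species`, `seq`
#'   (character matrix, rows = sequences), `weights` (NULL until
#'   [henikoff_weights()] is applied via [set_henikoff_weights()]).
#' @export
new_msa <- function(seqs, species = NULL) {
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("sequences must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != lens[1]][1]
    stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                 off, nchar(seqs[[off]]), lens[1]))
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  mat[mat %in% c(".", "*", "X")] <- "-"
  rownames(mat) <- ids
  structure(list(ids = ids,
                 species = if (is.null(species)) ids else species,
                 seq = mat, weights = NULL),
            class = "weighted_msa")
}

#' Read a multiple sequence alignment
#'
#' @param text Alignment text or file path, FASTA or Clustal format.
#' @param format `"fasta"` or `"clustal"`.
#' @return A `weighted_msa` (weights unset).
#' @export
read_alignment <- function(text, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  txt <- as_text(text)
  if (format == "fasta") {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf))
    writeLines(txt, tf)
    aln <- seqinr::read.alignment(tf, format = "fasta", forceToLower = FALSE)
    seqs <- vapply(aln$seq, function(s) s[[1]], character(1))
    names(seqs) <- aln$nam
    return(new_msa(seqs))
  }
  ## Clustal block format: header line, then blocks of "<id> <segment>"
  ## rows; conservation rows (leading whitespace) and blank lines skipped.
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (!length(lines) || !grepl("^CLUSTAL", lines[1])) {
    stop("not a Clustal alignment: missing CLUSTAL header line")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !grepl("^\\s", body)]
  parts <- regmatches(body, regexec("^(\\S+)\\s+([A-Za-z.*-]+)\\s*\\d*$", body))
  bad <- which(vapply(parts, length, integer(1)) != 3)
  if (length(bad)) stop(sprintf("unparseable Clustal line: '%s'", body[bad[1]]))
  ids <- vapply(parts, `[`, character(1), 2)
  segs <- vapply(parts, `[`, character(1), 3)
  seqs <- vapply(split(segs, factor(ids, unique(ids))), paste,
                 character(1), collapse = "")
  new_msa(seqs)
}

#' Write a weighted MSA as FASTA text
#' @param msa A `weighted_msa`.
#' @param path Optional output path; if `NULL` the text is returned.
#' @return FASTA text, invisibly when written to `path`.
#' @export
write_msa_fasta <- function(msa, path = NULL) {
  txt <- paste0(">", msa$ids, "\n",
                apply(msa$seq, 1, paste, collapse = ""), collapse = "\n")
  txt <- paste0(txt, "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Henikoff position-based sequence weights
#'
#' Down-weights phylogenetically redundant sequences: in each column a
#' sequence receives \eqn{1/(r s)} where `r` is the number of distinct
#' symbols in the column and `s` the number of sequences carrying that
#' sequence's symbol; a sequence's weight is the sum over columns,
#' normalized so all weights sum to 1.
#'
#' @param msa A `weighted_msa`.
#' @return Numeric weight vector (one per sequence, sums to 1).
#' @export
henikoff_weights <- function(msa) {
  mat <- msa$seq
  w <- numeric(nrow(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    cnt <- table(col)
    r <- length(cnt)
    w <- w + 1 / (r * as.numeric(cnt[col]))
  }
  w / sum(w)
}

#' Attach Henikoff weights to an MSA
#' @param msa A `weighted_msa`.
#' @return The MSA with `$weights` set.
#' @export
set_henikoff_weights <- function(msa) {
  msa$weights <- henikoff_weights(msa)
  msa
}

#' @noRd
require_weights <- function(msa) {
  if (is.null(msa$weights)) {
    stop("MSA weights are unset; call set_henikoff_weights() first")
  }
  if (abs(sum(msa$weights) - 1) > 1e-8 || any(msa$weights <= 0)) {
    stop("invalid weights: must be positive and sum to 1")
  }
  msa$weights
}

#' Weighted evolutionary entropy of an alignment column
#'
#' Weighted amino-acid frequencies at the column (gaps excluded, the
#' remaining mass renormalized), then \eqn{H = -\sum f \ln f} divided by
#' \eqn{\ln 20}.
#'
#' @param msa A `weighted_msa` with weights set.
#' @param position Column index.
#' @return Normalized entropy in \[0, 1\]; `NA` (with a warning) for an
#'   all-gap column.
#' @export
evolutionary_entropy <- function(msa, position) {
  w <- require_weights(msa)
  if (position < 1 || position > ncol(msa$seq)) {
    stop("position out of range")
  }
  col <- msa$seq[, position]
  keep <- col %in% AA20
  if (!any(keep)) {
    warning(sprintf("column %d is all gaps; entropy undefined", position))
    return(NA_real_)
  }
  f <- rowsum(w[keep], col[keep])[, 1]
  f <- f / sum(f)
  shannon(f) / log(20)
}

#' Evolutionary entropy for every column
#' @inheritParams evolutionary_entropy
#' @param positions Columns to evaluate (default all).
#' @return Named numeric vector of normalized entropies.
#' @export
evolutionary_entropy_profile <- function(msa, positions = seq_len(ncol(msa$seq))) {
  out <- vapply(positions, function(j) evolutionary_entropy(msa, j), numeric(1))
  names(out) <- positions
  out
}

#' Weighted amino-acid frequency matrix of an alignment
#'
#' @inheritParams evolutionary_entropy_profile
#' @return Matrix positions x 20 amino acids of weighted frequencies
#'   (rows sum to 1; gaps excluded and renormalized).
#' @export
msa_pwm <- function(msa, positions = seq_len(ncol(msa$seq))) {
  w <- require_weights(msa)
  m <- matrix(0, length(positions), 20, dimnames = list(positions, AA20))
  for (k in seq_along(positions)) {
    col <- msa$seq[, positions[k]]
    keep <- col %in% AA20
    if (!any(keep)) next
    f <- rowsum(w[keep], col[keep])[, 1]
    m[k, names(f)] <- f / sum(f)
  }
  m
}

#' Map alignment columns to reference-sequence numbering
#'
#' @param msa A `weighted_msa`.
#' @param reference Id (or row index) of the reference sequence.
#' @return Integer vector, one entry per column: the reference residue
#'   number, or `NA` where the reference is gapped.
#' @export
reference_positions <- function(msa, reference = 1L) {
  if (is.character(reference)) reference <- match(reference, msa$ids)
  row <- msa$seq[reference, ]
  out <- rep(NA_integer_, length(row))
  out[row %in% AA20] <- seq_len(sum(row %in% AA20))
  out
}

#' Pearson correlation with a t-transform p-value
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return List: `r`, `p` (two-sided), `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined")
  }
  r <- stats::cor(x, y)
  list(r = r, p = cor_p_from_r(r, length(x)), n = length(x))
}

#' Two-sided p-value for a Pearson correlation coefficient
#'
#' Uses the exact-null t-transform \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}
#' with n-2 degrees of freedom.
#'
#' @param r Correlation coefficient.
#' @param n Number of observations.
#' @return Two-sided p-value.
#' @export
cor_p_from_r <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Read a per-position entropy table (HSSP-style extract)
#'
#' A minimal reader for externally supplied per-position evolutionary
#' entropies: whitespace/tab-separated columns `position`, `entropy`.
#'
#' @param text TSV text or path.
#' @return Data frame `position`, `entropy`.
#' @export
read_entropy_table <- function(text) {
  df <- utils::read.table(text = as_text(text), header = TRUE)
  if (!all(c("position", "entropy") %in% names(df))) {
    stop("entropy table must have columns 'position' and 'entropy'")
  }
  df[, c("position", "entropy")]
}

#' Partition positions by evolutionary vs calculated entropy
#'
#' Splits positions into three sets: `outlier` (evolutionary entropy at
#' least `outlier_evo_min`, i.e. far more variable than the rest),
#' `correlated` (within `band_tol_factor` x RMS residual of the line
#' fitted to the non-outlier points, evolutionary on calculated entropy),
#' and `over-conserved` (the remainder: conservation higher than
#' stability alone would require). The fitted slope is reported.
#'
#' @param table Data frame with columns `position`, `evo_entropy`,
#'   `calc_entropy` (both normalized to \[0, 1\]).
#' @param outlier_evo_min Outlier threshold on normalized evolutionary
#'   entropy (default 0.2).
#' @param band_tol_factor Half-width of the correlated band in multiples
#'   of the RMS residual (default 2).
#' @return The table with a `set_label` column added; attributes `slope`,
#'   `intercept`, `rms_residual`, and the thresholds used.
#' @export
partition_positions <- function(table, outlier_evo_min = 0.2,
                                band_tol_factor = 2) {
  stopifnot(all(c("position", "evo_entropy", "calc_entropy") %in% names(table)))
  lab <- rep("unassigned", nrow(table))
  out <- table$evo_entropy >= outlier_evo_min
  lab[out] <- "outlier"
  rest <- which(!out)
  slope <- intercept <- rms <- NA_real_
  if (length(rest) >= 3 && stats::sd(table$calc_entropy[rest]) > 0 &&
      stats::sd(table$evo_entropy[rest]) > 0) {
    fit <- stats::lm(evo_entropy ~ calc_entropy, data = table[rest, ])
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    res <- stats::residuals(fit)
    rms <- sqrt(mean(res^2))
    tol <- band_tol_factor * rms
    lab[rest][abs(res) <= tol] <- "correlated"
    lab[rest][abs(res) > tol] <- "over-conserved"
  } else if (length(rest)) {
    ## degenerate: nothing to fit; constant columns are over-conserved
    lab[rest] <- "over-conserved"
  }
  table$set_label <- lab
  attr(table, "slope") <- slope
  attr(table, "intercept") <- intercept
  attr(table, "rms_residual") <- rms
  attr(table, "outlier_evo_min") <- outlier_evo_min
  attr(table, "band_tol_factor") <- band_tol_factor
  table
}
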