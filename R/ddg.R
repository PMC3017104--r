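## ddG mutational scans -> Boltzmann propensities, positional entropies,
## lethality classification.

#' Read a ddG mutational-scan table
#'
#' Parses a CSV with one row per (position, mutant amino acid) holding the
#' stability change \eqn{\Delta\Delta G = \Delta G_{Mut} - \Delta G_{WT}}
#' in kcal/mol (positive = destabilizing). Each position is expected to
#' carry a native self-row (`mut_aa == wt_aa`, `ddg = 0`) plus 17 mutant
#' rows: all natural amino acids except cysteine and proline.
#'
#' @param csv_text CSV text or a file path. Required columns: `chain`,
#'   `position`, `wt_aa`, `mut_aa`, `ddg`; optional `sem` (replicate
#'   standard error, kcal/mol) and `ddg_type` (`"stability"` or
#'   `"binding"`).
#' @param temperature_K Temperature attached to the scan (default 300 K).
#' @return A data frame of class `ddg_scan` grouped by (chain, position),
#'   with attribute `temperature_K`.
#' @export
read_ddg_table <- function(csv_text, temperature_K = 300) {
  df <- utils::read.csv(text = as_text(csv_text), stringsAsFactors = FALSE)
  need <- c("chain", "position", "wt_aa", "mut_aa", "ddg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ddG table missing column(s): ", paste(miss, collapse = ", "))
  if (!("sem" %in% names(df))) df$sem <- 0
  if (!("ddg_type" %in% names(df))) df$ddg_type <- "stability"

  if (!is.numeric(df$ddg)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$ddg))))
    stop(sprintf("non-numeric ddg value at data row %d", bad[1]))
  }
  if (anyNA(df$ddg)) stop(sprintf("non-numeric ddg value at data row %d",
                                  which(is.na(df$ddg))[1]))
  if (any(df$sem < 0, na.rm = TRUE)) stop("sem must be >= 0")
  if (!all(df$ddg_type %in% c("stability", "binding"))) {
    stop("ddg_type must be 'stability' or 'binding'")
  }

  scan_row <- df$mut_aa != df$wt_aa
  bad_aa <- scan_row & df$mut_aa %in% c("C", "P")
  if (any(bad_aa)) {
    stop(sprintf("mutant amino acid '%s' at position %d: cysteine and proline are not scanned",
                 df$mut_aa[bad_aa][1], df$position[bad_aa][1]))
  }
  self_bad <- !scan_row & df$ddg != 0
  if (any(self_bad)) {
    stop(sprintf("native self-row at position %d has nonzero ddg",
                 df$position[self_bad][1]))
  }
  key <- paste(df$chain, df$position, df$mut_aa, sep = "|")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (position, mut_aa) entry: position %d mutant %s",
                 df$position[duplicated(key)][1], df$mut_aa[duplicated(key)][1]))
  }

  n_mut <- tapply(scan_row, paste(df$chain, df$position), sum)
  low <- n_mut < 17
  if (any(low)) {
    warning(sprintf("%d position(s) have fewer than 17 mutant entries",
                    sum(low)))
  }
  df <- df[order(df$chain, df$position, df$mut_aa), ]
  rownames(df) <- NULL
  attr(df, "temperature_K") <- temperature_K
  class(df) <- c("ddg_scan", "data.frame")
  df
}

#' Boltzmann amino-acid propensities at one position
#'
#' Assumes amino acids at a position follow a Boltzmann distribution over
#' mutant stabilities: \eqn{p_i \propto \exp(-\Delta\Delta G_{wt\to i} /
#' k_B T)} with the native included at \eqn{\Delta\Delta G = 0} and
#' \eqn{k_B = 0.0019872} kcal/(mol K). Probabilities are normalized to sum
#' to one over the observed alphabet (native + scanned mutants, normally
#' 18 letters since C and P are not scanned).
#'
#' @param scan A `ddg_scan`.
#' @param position Residue position (source numbering).
#' @param chain Optional chain id, required when positions repeat across
#'   chains.
#' @param temperature_K Temperature in Kelvin (default: the scan's,
#'   normally 300).
#' @return List of class `propensity`: `probs` (named probability
#'   vector), `entropy_nats`, `entropy_normalized` (divided by
#'   \eqn{\ln 20}), `temperature_K`, `position`, `wt`.
#' @export
boltzmann_propensities <- function(scan, position, chain = NULL,
                                   temperature_K = NULL) {
  if (is.null(temperature_K)) {
    temperature_K <- attr(scan, "temperature_K")
    if (is.null(temperature_K)) temperature_K <- 300
  }
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  sub <- scan[scan$position == position, , drop = FALSE]
  if (!is.null(chain)) sub <- sub[sub$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("position %s not present in scan", position))
  if (!any(sub$mut_aa == sub$wt_aa)) {
    stop(sprintf("position %s has no native (ddg = 0) row", position))
  }
  kT <- KB_KCAL * temperature_K
  w <- exp(-sub$ddg / kT)
  p <- w / sum(w)
  names(p) <- sub$mut_aa
  H <- shannon(p)
  structure(list(probs = p, entropy_nats = H,
                 entropy_normalized = H / log(20),
                 temperature_K = temperature_K,
                 position = position, wt = sub$wt_aa[1]),
            class = "propensity")
}

#' Positional sequence entropy of a propensity vector
#'
#' \eqn{H(k) = -\sum_i p_i \ln p_i} in nats, plus the value normalized by
#' \eqn{\ln 20}, the maximal entropy over the 20 amino acids (0 = fully
#' conserved, 1 = all twenty equally likely).
#'
#' @param probs A named probability vector or a `propensity` object.
#' @return Named numeric vector `c(nats = , normalized = )`.
#' @export
positional_entropy <- function(probs) {
  if (inherits(probs, "propensity")) probs <- probs$probs
  if (abs(sum(probs) - 1) > 1e-6) stop("probabilities must sum to 1")
  H <- shannon(probs)
  c(nats = H, normalized = H / log(20))
}

#' Per-position entropy profile of a ddG scan
#'
#' @param scan A `ddg_scan`.
#' @param temperature_K Temperature in Kelvin.
#' @return Data frame: `chain`, `position`, `wt`, `entropy_nats`,
#'   `entropy_norm`, `top3` (the three most probable amino acids with
#'   their probabilities).
#' @export
propensity_profile <- function(scan, temperature_K = NULL) {
  keys <- unique(scan[, c("chain", "position")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    pr <- boltzmann_propensities(scan, keys$position[k], keys$chain[k],
                                 temperature_K)
    top <- sort(pr$probs, decreasing = TRUE)[1:min(3, length(pr$probs))]
    data.frame(chain = keys$chain[k], position = keys$position[k],
               wt = pr$wt, entropy_nats = pr$entropy_nats,
               entropy_norm = pr$entropy_normalized,
               top3 = paste(sprintf("%s:%.3f", names(top), top),
                            collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Position weight matrix of Boltzmann propensities
#'
#' Rows are positions, columns the 20 amino acids; unscanned letters
#' (cysteine, proline unless native) get probability zero. Suitable for
#' sequence-logo rendering.
#'
#' @inheritParams propensity_profile
#' @return Numeric matrix, rownames = positions, colnames = amino acids;
#'   rows sum to 1.
#' @export
propensity_pwm <- function(scan, temperature_K = NULL) {
  keys <- unique(scan[, c("chain", "position")])
  m <- matrix(0, nrow(keys), 20, dimnames = list(keys$position, AA20))
  for (k in seq_len(nrow(keys))) {
    pr <- boltzmann_propensities(scan, keys$position[k], keys$chain[k],
                                 temperature_K)
    m[k, names(pr$probs)] <- pr$probs
  }
  m
}

#' Fraction of positions whose lowest-ddG amino acid is the native
#'
#' A position is recapitulated when no mutant has a lower
#' \eqn{\Delta\Delta G} than the native (which sits at 0 by definition);
#' a tie between the native and a mutant counts as recapitulated.
#'
#' @param scan A `ddg_scan`.
#' @return Fraction in \[0, 1\].
#' @export
native_recapitulation <- function(scan) {
  keys <- unique(paste(scan$chain, scan$position))
  if (!length(keys)) stop("empty scan")
  mut <- scan[scan$mut_aa != scan$wt_aa, , drop = FALSE]
  min_mut <- tapply(mut$ddg, paste(mut$chain, mut$position), min)
  recap <- vapply(keys, function(k) {
    if (!k %in% names(min_mut)) TRUE else min_mut[[k]] >= 0
  }, logical(1))
  mean(recap)
}

#' Classify mutant phenotypes from a stability threshold
#'
#' Predicts a mutation lethal when its \eqn{\Delta\Delta G} is at least
#' `cutoff` kcal/mol (default +3, a point where destabilization of the
#' complex is deemed sufficient for lethality). The comparison is `>=` so
#' a mutation sitting exactly at the cutoff is called lethal.
#'
#' @param phenotypes Data frame with columns `mutation`, `ddg`,
#'   `phenotype` (`"lethal"` or `"viable"`).
#' @param cutoff Threshold in kcal/mol.
#' @return List: `counts` (2x2 observed x predicted matrix),
#'   `lethal_sensitivity` (fraction of lethal mutants predicted lethal),
#'   `viable_specificity` (fraction of viable mutants predicted viable),
#'   `cutoff`.
#' @export
classify_mutations <- function(phenotypes, cutoff = 3.0) {
  if (nrow(phenotypes) == 0L) stop("empty phenotype table")
  if (!all(phenotypes$phenotype %in% c("lethal", "viable"))) {
    stop("phenotype must be 'lethal' or 'viable'")
  }
  pred <- ifelse(phenotypes$ddg >= cutoff, "lethal", "viable")
  counts <- table(observed = factor(phenotypes$phenotype,
                                    c("lethal", "viable")),
                  predicted = factor(pred, c("lethal", "viable")))
  n_lethal <- sum(counts["lethal", ])
  n_viable <- sum(counts["viable", ])
  list(counts = counts,
       lethal_sensitivity = if (n_lethal) counts["lethal", "lethal"] / n_lethal else NA_real_,
       viable_specificity = if (n_viable) counts["viable", "viable"] / n_viable else NA_real_,
       cutoff = cutoff)
}

#' One-tailed two-sample t-test of lethal vs viable ddG
#'
#' Tests whether lethal mutations are more destabilizing than viable ones
#' (alternative: mean lethal ddG > mean viable ddG). Default is the
#' classical pooled-variance Student's t; set `welch = TRUE` for the
#' unequal-variance form. When the pooled variance is zero and the means
#' are equal the p-value is defined as 0.5 (the null center).
#'
#' @param lethal_ddg,viable_ddg Numeric vectors (each length >= 2),
#'   kcal/mol.
#' @param welch Use the Welch (unequal variance) statistic?
#' @return List: `t`, `p` (one-tailed), `df`, `method`.
#' @export
lethal_viable_ttest <- function(lethal_ddg, viable_ddg, welch = FALSE) {
  n1 <- length(lethal_ddg); n2 <- length(viable_ddg)
  if (n1 < 2 || n2 < 2) stop("both samples must have size >= 2")
  m1 <- mean(lethal_ddg); m2 <- mean(viable_ddg)
  v1 <- stats::var(lethal_ddg); v2 <- stats::var(viable_ddg)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    method <- "welch"
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "pooled"
  }
  if (se == 0) {
    if (m1 == m2) return(list(t = 0, p = 0.5, df = df, method = method))
    return(list(t = sign(m1 - m2) * Inf, p = if (m1 > m2) 0 else 1,
                df = df, method = method))
  }
  t <- (m1 - m2) / se
  list(t = t, p = stats::pt(t, df, lower.tail = FALSE), df = df,
       method = method)
}
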