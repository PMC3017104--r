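## Structure parsing, dot-surface SASA, burial / interface classification.

## Bondi van der Waals radii (A). Heavy atoms only; hydrogens are skipped
## at parse time.
.DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

## Residue names treated as nucleic acid and skipped by default.
.NUCLEIC <- c("DA", "DC", "DG", "DT", "DI", "DU",
              "A", "C", "G", "T", "U", "I", "N")

#' Default per-element van der Waals radius table
#'
#' Bondi (1964) radii in Angstrom for the heavy elements commonly found in
#' protein structures. Pass a modified copy to [read_structure()] to use a
#' different radius set.
#'
#' @return Named numeric vector, element symbol -> radius in Angstrom.
#' @export
default_vdw_radii <- function() .DEFAULT_VDW

#' Parse ATOM records from PDB text
#'
#' Reads fixed-column `ATOM` records into an atom table. Hydrogens are
#' skipped, `HETATM` records and nucleic-acid chains are ignored by
#' default, and alternate locations are resolved to the highest-occupancy
#' copy of each atom.
#'
#' @param pdb_text PDB text (or a path to a PDB file).
#' @param vdw_table Named numeric vector of per-element van der Waals
#'   radii in Angstrom; see [default_vdw_radii()].
#' @param keep_nucleic Keep nucleic-acid residues? Default `FALSE`.
#' @return A data frame of class `atom_record` with columns `chain`,
#'   `resnum`, `resname`, `atom`, `x`, `y`, `z`, `element`, `occupancy`,
#'   `vdw_radius`. Source-file residue numbering is preserved verbatim.
#' @export
read_structure <- function(pdb_text, vdw_table = default_vdw_radii(),
                           keep_nucleic = FALSE) {
  lines <- strsplit(as_text(pdb_text), "\n", fixed = TRUE)[[1]]
  is_atom <- startsWith(lines, "ATOM")
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("no ATOM records found in PDB input")

  f <- function(ln, from, to) substr(ln, from, to)
  recs <- lines[idx]
  short <- nchar(recs) < 54
  if (any(short)) {
    stop(sprintf("unparseable ATOM line %d: record shorter than coordinate fields",
                 idx[which(short)[1]]))
  }
  atom_name <- trimws(f(recs, 13, 16))
  altloc    <- f(recs, 17, 17)
  resname   <- trimws(f(recs, 18, 20))
  chain     <- f(recs, 22, 22)
  resnum_s  <- trimws(f(recs, 23, 26))
  xs <- trimws(f(recs, 31, 38)); ys <- trimws(f(recs, 39, 46))
  zs <- trimws(f(recs, 47, 54))
  occ_s <- trimws(f(recs, 55, 60))
  elem  <- toupper(trimws(f(recs, 77, 78)))

  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  resnum <- suppressWarnings(as.integer(resnum_s))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resnum))
  if (length(bad)) {
    stop(sprintf("unparseable ATOM line %d: non-numeric coordinate or residue number",
                 idx[bad[1]]))
  }
  occupancy <- suppressWarnings(as.numeric(occ_s))
  occupancy[!is.finite(occupancy)] <- 1.0

  ## element column may be blank in minimal files; fall back to the first
  ## alphabetic character of the atom name.
  blank <- elem == ""
  elem[blank] <- substr(gsub("[^A-Za-z].*$", "",
                             gsub("^[0-9]*", "", atom_name[blank])), 1, 1)

  keep <- !(elem %in% c("H", "D"))
  if (!keep_nucleic) keep <- keep & !(resname %in% .NUCLEIC)
  atoms <- data.frame(chain = chain, resnum = resnum, resname = resname,
                      atom = atom_name, x = x, y = y, z = z,
                      element = elem, occupancy = occupancy, altloc = altloc,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no protein heavy atoms after filtering")

  ## altloc: keep the highest-occupancy copy of each (chain, resnum, atom)
  key <- paste(atoms$chain, atoms$resnum, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resnum), , drop = FALSE]
  atoms$altloc <- NULL

  unknown <- setdiff(unique(atoms$element), names(vdw_table))
  if (length(unknown)) {
    stop(sprintf("unknown element(s) with no van der Waals radius: %s",
                 paste(unknown, collapse = ", ")))
  }
  atoms$vdw_radius <- unname(vdw_table[atoms$element])
  rownames(atoms) <- NULL
  class(atoms) <- c("atom_record", "data.frame")
  atoms
}

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#' @noRd
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Dot-surface solvent-accessible surface area
#'
#' Computes per-atom and per-residue SASA with a deterministic dot-surface
#' algorithm: `n_dots` quasi-uniform points (Fibonacci lattice) are placed
#' on each atom's probe-expanded sphere of radius `vdw_radius +
#' probe_radius`; a dot is exposed when it lies outside every neighbour's
#' expanded sphere, and the per-atom area is
#' \eqn{4\pi(r+p)^2 \times} (exposed dots / `n_dots`). Per-residue SASA is
#' the sum over the residue's atoms.
#'
#' @param atoms Atom table from [read_structure()].
#' @param n_dots Dots per atom (default 1024; minimum 32).
#' @param probe_radius Probe sphere radius in Angstrom (default 1.4, a
#'   water molecule).
#' @return A list of class `sasa_result`: `per_atom` (numeric vector,
#'   one entry per atom row), `per_residue` (data frame `chain`, `resnum`,
#'   `resname`, `sasa`), `n_dots`, `probe_radius`.
#' @export
dot_sphere_sasa <- function(atoms, n_dots = 1024, probe_radius = 1.4) {
  if (n_dots < 32) stop("n_dots must be >= 32")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atoms$vdw_radius + probe_radius
  dots <- fibonacci_sphere(n_dots)

  d2 <- as.matrix(stats::dist(xyz))^2
  per_atom <- numeric(n)
  for (k in seq_len(n)) {
    nb <- which(d2[k, ] < (R[k] + R)^2 & seq_len(n) != k)
    pts <- dots * R[k]
    pts <- sweep(pts, 2, xyz[k, ], "+")
    exposed <- rep(TRUE, n_dots)
    for (j in nb) {
      if (!any(exposed)) break
      dx <- pts[, 1] - xyz[j, 1]
      dy <- pts[, 2] - xyz[j, 2]
      dz <- pts[, 3] - xyz[j, 3]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz >= R[j]^2 - 1e-9)
    }
    per_atom[k] <- 4 * pi * R[k]^2 * sum(exposed) / n_dots
  }

  key <- paste(atoms$chain, atoms$resnum, sep = "|")
  agg <- rowsum(per_atom, key)
  first <- !duplicated(key)
  per_residue <- data.frame(chain = atoms$chain[first],
                            resnum = atoms$resnum[first],
                            resname = atoms$resname[first],
                            sasa = agg[match(key[first], rownames(agg)), 1],
                            stringsAsFactors = FALSE)
  per_residue <- per_residue[order(per_residue$chain, per_residue$resnum), ]
  rownames(per_residue) <- NULL
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 n_dots = n_dots, probe_radius = probe_radius),
            class = "sasa_result")
}

#' Classify buried residues by a SASA threshold
#'
#' A residue is buried when its whole-residue SASA is strictly below
#' `threshold_area` (default 1 Angstrom^2).
#'
#' @param sasa A `sasa_result` from [dot_sphere_sasa()] computed on the
#'   full complex.
#' @param threshold_area Burial threshold in Angstrom^2.
#' @return Data frame with columns `chain`, `resnum` of buried residues.
#' @export
classify_burial <- function(sasa, threshold_area = 1.0) {
  pr <- sasa$per_residue
  out <- pr[pr$sasa < threshold_area, c("chain", "resnum")]
  rownames(out) <- NULL
  out
}

#' Interface residues by inter-chain heavy-atom contact
#'
#' A residue is an interface residue when any of its heavy atoms lies
#' within `contact_cutoff` of a heavy atom of the partner chain. An
#' explicit `override` table (chain, resnum) can be supplied and is
#' returned verbatim, for cases where interface membership is known from
#' an external source (e.g. contact persistence in simulations).
#'
#' @param atoms Atom table from [read_structure()].
#' @param chain_pairs List of length-2 character vectors of chain ids.
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom
#'   (default 4.5).
#' @param override Optional data frame `chain`, `resnum`; returned as-is.
#' @return Data frame with columns `chain`, `resnum`.
#' @export
detect_interface_residues <- function(atoms, chain_pairs,
                                      contact_cutoff = 4.5,
                                      override = NULL) {
  if (!is.null(override)) {
    out <- unique(override[, c("chain", "resnum")])
    rownames(out) <- NULL
    return(out)
  }
  res <- list()
  for (pair in chain_pairs) {
    a <- atoms[atoms$chain == pair[1], , drop = FALSE]
    b <- atoms[atoms$chain == pair[2], , drop = FALSE]
    if (nrow(a) == 0L) stop(sprintf("chain '%s' absent from structure", pair[1]))
    if (nrow(b) == 0L) stop(sprintf("chain '%s' absent from structure", pair[2]))
    am <- as.matrix(a[, c("x", "y", "z")])
    bm <- as.matrix(b[, c("x", "y", "z")])
    d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * am %*% t(bm)
    hit <- d2 <= contact_cutoff^2
    ia <- which(apply(hit, 1, any))
    ib <- which(apply(hit, 2, any))
    if (length(ia)) {
      res[[length(res) + 1L]] <- data.frame(chain = a$chain[ia],
                                            resnum = a$resnum[ia])
    }
    if (length(ib)) {
      res[[length(res) + 1L]] <- data.frame(chain = b$chain[ib],
                                            resnum = b$resnum[ib])
    }
  }
  if (!length(res)) {
    return(data.frame(chain = character(), resnum = integer()))
  }
  out <- unique(do.call(rbind, res))
  out <- out[order(out$chain, out$resnum), ]
  rownames(out) <- NULL
  out
}

#' Write a burial/interface classification table
#'
#' @param sasa A `sasa_result`.
#' @param buried,interface Data frames `chain`, `resnum` (e.g. from
#'   [classify_burial()] and [detect_interface_residues()]).
#' @param path Output TSV path.
#' @return Invisibly, the written data frame with columns `chain`,
#'   `resnum`, `resname`, `sasa_A2`, `buried`, `interface`.
#' @export
write_burial_tsv <- function(sasa, buried, interface, path) {
  pr <- sasa$per_residue
  key <- function(d) paste(d$chain, d$resnum, sep = "|")
  out <- data.frame(chain = pr$chain, resnum = pr$resnum,
                    resname = pr$resname, sasa_A2 = pr$sasa,
                    buried = as.integer(key(pr) %in% key(buried)),
                    interface = as.integer(key(pr) %in% key(interface)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
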