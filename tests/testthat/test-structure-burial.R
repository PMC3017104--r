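# PDB parsing, dot-surface SASA and burial/interface classification.

test_that("read_structure parses ATOM records and applies the dedup rules", {
  one <- pdb_atom_line(1, "CA", "GLY", "A", 1, 1.5, -2.25, 3.125)
  at <- read_structure(one)
  expect_equal(nrow(at), 1L)
  expect_equal(c(at$x, at$y, at$z), c(1.5, -2.25, 3.125))
  expect_equal(at$vdw_radius, unname(default_vdw_radii()["C"]))
  expect_equal(at$resnum, 1L)

  # altloc A/B of the same atom -> single record, highest occupancy wins
  alt <- paste(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, occ = 0.4,
                             altloc = "A"),
               pdb_atom_line(2, "CA", "GLY", "A", 1, 9, 9, 9, occ = 0.6,
                             altloc = "B"), sep = "\n")
  at2 <- read_structure(alt)
  expect_equal(nrow(at2), 1L)
  expect_equal(at2$x, 9)

  # hydrogens are skipped
  hyd <- paste(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
               pdb_atom_line(2, "HA", "GLY", "A", 1, 1, 0, 0, elem = "H"),
               sep = "\n")
  expect_equal(nrow(read_structure(hyd)), 1L)
})

test_that("read_structure rejects broken input with informative errors", {
  expect_error(read_structure("ATOM  broken"), "line 1")
  bad_num <- pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0)
  substr(bad_num, 31, 38) <- "   xx.xx"
  expect_error(read_structure(bad_num), "line 1")
  unk <- pdb_atom_line(1, "XX", "GLY", "A", 1, 0, 0, 0, elem = "ZZ")
  expect_error(read_structure(unk), "ZZ")
})

test_that("toy structure from the generator round-trips its bookkeeping", {
  toy <- gen_toy_structure(n_side = 3)
  at <- read_structure(toy$pdb_text)
  expect_equal(nrow(at), toy$n_residues)
  expect_equal(length(unique(at$resnum)), 27L)
})

test_that("isolated sphere SASA matches the analytic area at any dot count", {
  one <- read_structure(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0))
  for (nd in c(64, 256, 1024)) {
    s <- dot_sphere_sasa(one, n_dots = nd, probe_radius = 1.4)
    expect_equal(s$per_atom, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-12)
  }
  # r = 1.6, probe = 1.4 -> 4*pi*3^2
  vdw <- c(default_vdw_radii(), ZZ = 1.6)
  one2 <- read_structure(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0,
                                       elem = "ZZ"), vdw_table = vdw)
  s2 <- dot_sphere_sasa(one2, 512, 1.4)
  expect_equal(s2$per_atom, 4 * pi * 3.0^2, tolerance = 1e-12)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  d <- 3.5 # < 2 * (1.70 + 1.4)
  two <- read_structure(paste(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, d, 0, 0), sep = "\n"))
  s <- dot_sphere_sasa(two, 1024, 1.4)
  analytic <- two_sphere_cap_area(1.70 + 1.4, d)
  expect_lt(max(abs(s$per_atom - analytic) / analytic), 0.02)
  # doubling the dot count moves the estimate by < 2%
  s2 <- dot_sphere_sasa(two, 2048, 1.4)
  expect_lt(max(abs(s2$per_atom - s$per_atom) / s$per_atom), 0.02)
})

test_that("a fully enclosed atom has zero SASA and rigid motions change nothing", {
  toy <- gen_toy_structure(n_side = 3)
  at <- read_structure(toy$pdb_text)
  s <- dot_sphere_sasa(at, 1024)
  center <- s$per_residue$sasa[s$per_residue$resnum == 14]
  expect_equal(center, 0)
  expect_true(all(s$per_atom >= 0))
  expect_true(all(s$per_atom <= 4 * pi * (at$vdw_radius + 1.4)^2 + 1e-9))
  # per-residue equals the sum over atoms (single-atom residues here)
  expect_equal(sort(s$per_residue$sasa), sort(s$per_atom))

  # rotation + translation invariance
  th <- 0.73
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% R
  at2 <- at
  at2$x <- xyz[, 1] + 11.3; at2$y <- xyz[, 2] - 5.1; at2$z <- xyz[, 3] + 0.7
  s2 <- dot_sphere_sasa(at2, 1024)
  # relative to each atom's full expanded-sphere area: the lattice is
  # orientation-fixed, so a rigid motion can only shift a dot or two
  sphere <- 4 * pi * (at$vdw_radius + 1.4)^2
  expect_lt(max(abs(s2$per_atom - s$per_atom) / sphere), 0.005)
})

test_that("burial classification is strict and monotone in the threshold", {
  sasa <- structure(list(per_residue = data.frame(
    chain = "A", resnum = 1:3, resname = "GLY",
    sasa = c(0.5, 1.0, 40))), class = "sasa_result")
  expect_equal(classify_burial(sasa, 1.0)$resnum, 1L) # 0.5 buried, 1.0 not
  expect_equal(nrow(classify_burial(sasa, 0.2)), 0L)
  a <- classify_burial(sasa, 0.9)$resnum
  b <- classify_burial(sasa, 2.0)$resnum
  expect_true(all(a %in% b))
  expect_error(dot_sphere_sasa(NULL, n_dots = 16), "n_dots")
})

test_that("interface detection honours the contact cutoff and override lists", {
  two_chain <- read_structure(paste(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "B", 7, 4.0, 0, 0), sep = "\n"))
  got <- detect_interface_residues(two_chain, list(c("A", "B")), 4.5)
  expect_equal(got, data.frame(chain = c("A", "B"), resnum = c(1L, 7L)))
  expect_equal(nrow(detect_interface_residues(two_chain, list(c("A", "B")), 3.5)), 0L)
  expect_error(detect_interface_residues(two_chain, list(c("A", "C")), 4.5), "'C'")

  # explicit override: the classic histone H3 interface residue list
  ov <- data.frame(chain = "A",
                   resnum = c(110L, 113L, 114L, 123L, 126L, 127L, 130L, 131L))
  expect_equal(detect_interface_residues(two_chain, list(c("A", "B")),
                                         override = ov), ov)
})

test_that("the burial TSV carries SASA and both classifications", {
  toy <- gen_toy_structure()
  at <- read_structure(toy$pdb_text)
  s <- dot_sphere_sasa(at, 256)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  out <- write_burial_tsv(s, classify_burial(s), toy$buried_truth[0, ], tsv)
  back <- read.delim(tsv)
  expect_equal(back$buried, out$buried)
  expect_equal(sum(back$buried), nrow(toy$buried_truth))
})
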