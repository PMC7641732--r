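# Structure container, parsing, writing, ensembles.

test_that("a minimal one-atom PDB parses into one chain/residue/atom", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      1.000   2.000   3.000  1.00  0.00           C",
    "END"), tmp)
  s <- read_structure(tmp)
  expect_equal(nrow(s$atom), 1L)
  expect_equal(nrow(chain_summary(s)), 1L)
  expect_equal(unname(as.numeric(s$atom[1, c("x", "y", "z")])), c(1, 2, 3))
})

test_that("fixture structures round-trip through PDB and mmCIF", {
  d <- build_aform_duplex("GCAUGC", fluoro_pyrimidines = TRUE)
  s <- d$structure
  s$cell <- c(30, 30, 40, 90, 90, 90)
  s$space_group <- "P 21"
  s$sym_ops <- space_group_ops("P 21")
  for (fmt in c("pdb", "mmcif")) {
    tmp <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(s, tmp, format = fmt)
    s2 <- suppressWarnings(read_structure(tmp))
    expect_equal(nrow(s2$atom), nrow(s$atom))
    expect_lt(max(abs(coords3d(s2) - coords3d(s))), 1e-3)
    expect_identical(s2$atom$elety, s$atom$elety)
    expect_identical(s2$atom$parent_base, s$atom$parent_base)
    expect_equal(s2$cell, s$cell)
    unlink(tmp)
  }
})

test_that("write-parse-write is idempotent and byte-stable", {
  d <- build_aform_duplex("GCGC")
  t1 <- tempfile(fileext = ".pdb"); t2 <- tempfile(fileext = ".pdb")
  write_structure(d$structure, t1)
  s1 <- read_structure(t1)
  write_structure(s1, t2)
  expect_identical(readLines(t1), readLines(t2))
  # repeated writes are byte-identical
  t3 <- tempfile(fileext = ".pdb")
  write_structure(d$structure, t3)
  expect_identical(readLines(t1), readLines(t3))
  unlink(c(t1, t2, t3))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1      0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1      5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AGLY A   2      0.000   3.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2      5.000   3.000   0.000  0.50  0.00           C",
    "END"), tmp)
  s <- read_structure(tmp)
  expect_equal(nrow(s$atom), 2L)
  # residue 1: occupancy 0.6 wins; residue 2: tie -> altloc A
  expect_equal(s$atom$x[s$atom$resno == 1], 5)
  expect_equal(s$atom$x[s$atom$resno == 2], 0)
  expect_true(all(s$atom$o <= 1))
  unlink(tmp)
})

test_that("polymer classification and parent-base mapping are derived", {
  d <- build_aform_duplex("GCAU", fluoro_pyrimidines = TRUE)
  cs <- chain_summary(d$structure)
  expect_equal(cs$polymer, "rna")
  pb <- d$structure$atom$parent_base
  expect_false(any(is.na(pb)))
  # 2'-F pyrimidines keep their parent base and carry a ribose fluorine
  fl <- d$structure$atom[d$structure$atom$elesy == "F", ]
  expect_true(all(fl$resid %in% c("C", "U")))
  expect_true(all(grepl("2'", fl$elety)))

  wat <- atom_df("O", "HOH", "W", 1, 0, 0, 0, "O", type = "HETATM")
  sw <- make_structure("w", wat)
  expect_equal(chain_summary(sw)$polymer, "water")
})

test_that("unknown elements are inferred from atom names with a warning", {
  bad <- atom_df("CA", "GLY", "A", 1, 0, 0, 0, elesy = "")
  bad2 <- atom_df("CA", "GLY", "A", 2, 3, 0, 0, elesy = "")
  expect_warning(s <- make_structure("x", bad, bad2), "inferred")
  expect_equal(s$atom$elesy, c("C", "C"))
})

test_that("ensembles round-trip with energies and honour selections", {
  pe <- build_planted_ensemble(c(4, 3), sigma = 0.2, separation = 12,
                               seed = 5, n_atoms = 12)
  mp <- tempfile(fileext = ".pdb"); ep <- tempfile(fileext = ".tsv")
  write_ensemble(pe$ensemble, mp, ep)
  e2 <- read_ensemble(mp, ep, selection = "all")
  expect_equal(length(e2$coords), 7L)
  expect_equal(e2$energy, pe$ensemble$energy)
  for (i in seq_along(e2$coords)) {
    expect_lt(max(abs(e2$coords[[i]] - pe$ensemble$coords[[i]])), 1e-3)
  }
  # one CA pseudo-atom per residue
  e3 <- read_ensemble(mp, ep, selection = "name CA")
  expect_equal(nrow(e3$coords[[1]]), 12L)
  expect_error(read_ensemble(mp, ep, selection = "name XX"), "zero atoms")
  unlink(c(mp, ep))
})

test_that("ensemble energy table errors list missing model indices", {
  pe <- build_planted_ensemble(c(2, 2), sigma = 0.2, separation = 12,
                               seed = 5, n_atoms = 6)
  mp <- tempfile(fileext = ".pdb"); ep <- tempfile(fileext = ".tsv")
  write_ensemble(pe$ensemble, mp, ep)
  bad <- data.frame(m = c(1, 2, 99), e = c(0, 1, 2))
  write.table(bad, ep, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(read_ensemble(mp, ep), "99")
  unlink(c(mp, ep))
})

test_that("structure invariants are enforced", {
  a <- atom_df("CA", "GLY", "A", 1, 0, 0, 0)
  dup <- rbind(a, a)
  dup$eleno <- 1:2
  expect_error(structure3d("dup", dup), "duplicate")
  bad <- a; bad$x <- NaN; bad$eleno <- 1L
  expect_error(structure3d("nan", bad), "finite")
})
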