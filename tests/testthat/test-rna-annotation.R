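# Base-pair detection, Leontis-Westhof classes, secondary structure,
# flipped-out bases.

test_that("an ideal complementary duplex yields exactly its canonical pairs", {
  d <- build_aform_duplex("GCGCGCG")
  p <- detect_base_pairs(d$structure, "A")
  expect_equal(nrow(p), 7L)
  expect_true(all(p$canonical))
  expect_true(all(p$edge_i == "WC" & p$edge_j == "WC"))
  expect_true(all(p$orientation == "cis"))
  got <- paste(p$res_i, p$res_j)
  want <- paste(d$truth$pairs$res_i, d$truth$pairs$res_j)
  expect_setequal(got, want)
  # order-normalised: i-position < j-position, no duplicates
  expect_true(all(p$pos_i < p$pos_j))
  expect_false(anyDuplicated(paste(p$pos_i, p$pos_j)) > 0)
})

test_that("pair recovery is exact on noisy duplexes up to 0.3 A", {
  for (sigma in c(0.1, 0.2, 0.3)) {
    d <- build_aform_duplex("GCAUGCA", noise_sigma = sigma, seed = 7)
    p <- detect_base_pairs(d$structure, "A")
    got <- paste(p$res_i, p$res_j)
    want <- paste(d$truth$pairs$res_i, d$truth$pairs$res_j)
    expect_setequal(got, want)
    expect_true(all(p$canonical))
  }
})

test_that("G-U wobble counts as canonical only when configured", {
  # duplex with a planted G-U pair: strand1 G at a position whose partner
  # is U requires a non-complementary construction; instead pair G with U
  # by building the U-containing duplex and swapping the base identity
  d <- build_aform_duplex("GCGC")
  s <- d$structure
  # residue 8 pairs residue 1 (G); turn its C into a U-like pattern is
  # geometry-incompatible, so test the classification rule directly
  expect_true(aptaface:::is_complementary("G", "U", wobble = TRUE))
  expect_false(aptaface:::is_complementary("G", "U", wobble = FALSE))
  expect_true(aptaface:::is_complementary("A", "U", wobble = FALSE))
  expect_false(aptaface:::is_complementary("A", "G", wobble = TRUE))
})

test_that("a single nucleotide or non-RNA chain is handled", {
  d <- build_aform_duplex("GC")
  one <- d$structure
  one$atom <- one$atom[one$atom$resno == 1, ]
  expect_equal(nrow(detect_base_pairs(one, "A")), 0L)
  h <- build_protein_helix(4, chain = "Q")
  expect_error(detect_base_pairs(h, "Q"), "nucleic")
})

test_that("a fully paired duplex derives one stem and no loops", {
  d <- build_aform_duplex("GCGCGCG")
  p <- detect_base_pairs(d$structure, "A")
  ss <- derive_secondary_structure(p, d$structure, "A")
  expect_length(ss$stems, 1L)
  expect_equal(nrow(ss$stems[[1]]), 7L)
  expect_length(ss$loops, 0L)
  expect_length(ss$unassigned, 0L)
  expect_true(ss_partition_ok(ss))
  expect_equal(ss$dotbracket, "((((((()))))))")
  expect_false(ss$pseudoknot)
})

test_that("a hairpin derives its stem and designed loop members", {
  hp <- build_hairpin("GCGCGCGC", "AAUAA")
  p <- detect_base_pairs(hp$structure, "R")
  ss <- derive_secondary_structure(p, hp$structure, "R")
  expect_length(ss$stems, 1L)
  expect_equal(nrow(ss$stems[[1]]), 8L)
  hl <- Filter(function(l) l$kind == "hairpin", ss$loops)
  expect_length(hl, 1L)
  expect_equal(ss$residues[hl[[1]]$members], hp$truth$loop_res)
  expect_true(ss_partition_ok(ss))
})

test_that("flipped-out bases are detected exactly, with no false positives", {
  # unperturbed duplex: no flipped-out calls
  d <- build_aform_duplex("GCGCGCG")
  ann <- annotate_rna(d$structure, "A")
  expect_length(ann$ss$flipped_out, 0L)
  # planted extrusions in hairpin loops
  for (fl in list(3L, c(2L, 4L), c(1L, 3L, 5L))) {
    hp <- build_hairpin("GCGC", "AAUAA", flipped_out = fl)
    ann <- annotate_rna(hp$structure, "R")
    expect_setequal(ann$ss$flipped_out, hp$truth$flipped_out)
  }
})

test_that("a base rotated out of a duplex is the only flipped-out call", {
  d <- build_aform_duplex("GCGCGCG")
  s2 <- rotate_base_out(d$structure, "A", 4, 120)
  ann <- annotate_rna(s2, "A")
  expect_equal(ann$ss$flipped_out, "A:4")
  # its former partner is unpaired but stays near the axis
  expect_equal(nrow(ann$pairs), 6L)
})

test_that("chains without stems fall back to the global centroid rule", {
  # loop-only synthetic: take a hairpin and keep just the loop residues
  hp <- build_hairpin("GCGC", "AAUAA", flipped_out = 2)
  s <- hp$structure
  s$atom <- s$atom[s$atom$resno %in% 5:9, ]
  p <- detect_base_pairs(s, "R")
  ss <- derive_secondary_structure(p, s, "R")
  expect_length(ss$stems, 0L)
  expect_warning(detect_flipped_out(s, "R", ss), "no stems")
})

test_that("noise perturbation does not break the partition identity", {
  for (seed in 1:3) {
    d <- build_aform_duplex("GCAUGC", noise_sigma = 0.2, seed = seed)
    ann <- annotate_rna(d$structure, "A")
    expect_true(ss_partition_ok(ann$ss))
  }
})
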