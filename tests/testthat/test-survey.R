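# Per-complex records and survey aggregation.

test_that("a toy complex record matches the generator's ground truth", {
  tc <- build_toy_complex(
    hbonds = list(list(rna_res = 6, rna_atom = "N6", distance = 2.9),
                  list(rna_res = 8, rna_atom = "N3", distance = 3.1)),
    water_bridges = list(list(rna_res = 7, rna_atom = "O4",
                              distance = 2.8)),
    flipped_out = c(2, 3, 4))
  rec <- analyze_complex(tc$structure, "P", "R", n_points = 240)
  expect_equal(rec$n_hbonds_direct, 2L)
  expect_equal(rec$n_hbonds_water, 1L)
  expect_equal(rec$n_hbonds_total, 3L)
  expect_equal(rec$n_hbonds_nucleobase, 2L)
  expect_equal(rec$n_hbonds_backbone, 0L)
  expect_true(rec$has_helix)
  expect_true(rec$has_stem_loop)
  expect_true(rec$has_flipped_out)
  expect_true(rec$is_duplex)
  expect_gt(rec$bsa_combined, 0)
  # count identity for nucleic-side direct bonds
  expect_equal(rec$n_hbonds_nucleobase + rec$n_hbonds_backbone,
               rec$n_hbonds_direct)
  expect_lte(rec$n_hbonds_loop + rec$n_hbonds_helix, rec$n_hbonds_total)
})

test_that("a pairless single strand is neither duplex nor helix", {
  hp <- build_hairpin("GCGC", "AAUAA")
  s <- hp$structure
  s$atom <- s$atom[s$atom$resno %in% 5:9, ]   # loop only
  helix <- build_protein_helix(8, chain = "P")
  helix$atom[, "y"] <- helix$atom[, "y"] - 40
  s$atom <- rbind(s$atom, helix$atom)
  rec <- suppressWarnings(analyze_complex(s, "P", "R", n_points = 240))
  expect_false(rec$is_duplex)
  expect_false(rec$has_helix)
  expect_false(rec$has_stem_loop)
})

test_that("aggregation reproduces hand-computed means and prevalences", {
  rec <- function(total, base, bb, loop, helix, flags) {
    data.frame(complex_id = "x", n_hbonds_total = total,
               n_hbonds_nucleobase = base, n_hbonds_backbone = bb,
               n_hbonds_loop = loop, n_hbonds_helix = helix,
               n_hbonds_direct = base + bb, n_hbonds_water = 0L,
               has_helix = flags[1], has_stem_loop = flags[2],
               has_flipped_out = flags[3], is_duplex = flags[4],
               bsa_combined = 1000)
  }
  r1 <- rec(10, 6, 4, 8, 2, c(TRUE, TRUE, TRUE, TRUE))
  r2 <- rec(18, 10, 8, 12, 6, c(TRUE, FALSE, TRUE, TRUE))
  st <- aggregate_survey(rbind(r1, r2))
  expect_equal(st$mean_hbonds_total, 14)       # (10 + 18) / 2
  expect_equal(st$mean_hbonds_nucleobase, 8)
  expect_equal(st$mean_hbonds_backbone, 6)
  expect_equal(st$mean_hbonds_loop, 10)
  expect_equal(st$mean_hbonds_helix, 4)
  expect_equal(st$pct_helix, 100)
  expect_equal(st$pct_stem_loop, 50)
  # one record: means = counts, percentages in {0, 100}
  s1 <- aggregate_survey(r1)
  expect_equal(s1$mean_hbonds_total, 10)
  expect_true(all(c(s1$pct_helix, s1$pct_duplex) %in% c(0, 100)))
  expect_error(aggregate_survey(r1[0, ]), "no records")
})

test_that("concatenated aggregation equals the size-weighted average", {
  set.seed(51)
  mk <- function(n) do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(complex_id = paste0("c", i),
               n_hbonds_total = sample(5:20, 1),
               n_hbonds_nucleobase = sample(0:10, 1),
               n_hbonds_backbone = sample(0:10, 1),
               n_hbonds_loop = sample(0:12, 1),
               n_hbonds_helix = sample(0:6, 1),
               n_hbonds_direct = 0L, n_hbonds_water = 0L,
               has_helix = runif(1) < 0.8, has_stem_loop = runif(1) < 0.5,
               has_flipped_out = runif(1) < 0.7, is_duplex = TRUE,
               bsa_combined = runif(1, 500, 3000))))
  A <- mk(3); B <- mk(5)
  sa <- aggregate_survey(A); sb <- aggregate_survey(B)
  sab <- aggregate_survey(rbind(A, B))
  expect_equal(sab$mean_hbonds_total,
               (3 * sa$mean_hbonds_total + 5 * sb$mean_hbonds_total) / 8)
  expect_equal(sab$pct_helix, (3 * sa$pct_helix + 5 * sb$pct_helix) / 8)
  # an all-zero record lowers every mean and raises no percentage
  zero <- mk(1)
  zero[, grep("n_hbonds", names(zero))] <- 0L
  zero$has_helix <- zero$has_stem_loop <- FALSE
  zero$has_flipped_out <- zero$is_duplex <- FALSE
  zero$bsa_combined <- 0
  szero <- aggregate_survey(rbind(A, zero))
  expect_lte(szero$mean_hbonds_total, sa$mean_hbonds_total)
  expect_lte(szero$pct_helix, sa$pct_helix)
})

test_that("the batch runner logs and skips failing entries", {
  dir <- tempfile(); dir.create(dir)
  tc <- build_toy_complex(
    hbonds = list(list(rna_res = 6, rna_atom = "N6", distance = 2.9)))
  write_structure(tc$structure, file.path(dir, "ok.pdb"))
  manifest <- data.frame(
    id = c("ok", "missing"),
    file = c("ok.pdb", "nope.pdb"),
    protein_chains = c("P", "P"),
    rna_chains = c("R", "R"),
    stringsAsFactors = FALSE)
  out <- run_survey(manifest, structures_dir = dir, n_points = 240)
  expect_equal(nrow(out$records), 1L)
  expect_named(out$failures, "missing")
  expect_equal(out$stats$n_complexes, 1L)
  unlink(dir, recursive = TRUE)
})
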