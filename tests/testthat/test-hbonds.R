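# Hydrogen-bond, water-bridge, stacking and categorisation detectors.

planted_toy <- function() {
  build_toy_complex(
    hbonds = list(list(rna_res = 6, rna_atom = "N6", distance = 2.9),
                  list(rna_res = 8, rna_atom = "N3", distance = 3.1),
                  list(rna_res = 1, rna_atom = "O6", distance = 2.8)),
    stacks = list(list(rna_res = 7, distance = 3.4)),
    water_bridges = list(list(rna_res = 12, rna_atom = "O6",
                              distance = 2.8)),
    flipped_out = c(2, 4))
}

test_that("planted hydrogen bonds are recovered with precision = recall = 1", {
  tc <- planted_toy()
  hb <- find_hbonds(tc$structure, "P", "R")
  got <- apply(hb[, c("donor", "acceptor")], 1, function(r)
    paste(sort(r), collapse = " "))
  want <- apply(tc$truth$hbonds[, c("rna_atom", "protein_atom")], 1,
                function(r) paste(sort(r), collapse = " "))
  expect_setequal(got, want)          # precision = recall = 1
  expect_equal(sort(hb$distance), sort(tc$truth$hbonds$distance),
               tolerance = 0.02)
  # partitions with nothing in range give an empty frame
  empty <- find_hbonds(tc$structure, "P", "R", dmax = 2.41, dmin = 2.4)
  expect_equal(nrow(empty), 0L)
})

test_that("the direct-bond count is monotone in the distance cutoff", {
  tc <- planted_toy()
  counts <- vapply(c(2.8, 3.0, 3.2, 3.5, 4.0, 4.5),
                   function(d) nrow(find_hbonds(tc$structure, "P", "R",
                                                dmax = d)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("swapping partitions flips orientation but keeps the count", {
  tc <- planted_toy()
  ab <- find_hbonds(tc$structure, "P", "R")
  ba <- find_hbonds(tc$structure, "R", "P")
  expect_equal(nrow(ab), nrow(ba))
  key <- function(h) sort(apply(h[, c("donor", "acceptor")], 1,
                                function(r) paste(sort(r), collapse = " ")))
  expect_equal(key(ab), key(ba))
})

test_that("water bridges require the water and both legs", {
  tc <- planted_toy()
  wb <- find_water_bridges(tc$structure, "P", "R")
  expect_equal(nrow(wb), 1L)
  expect_equal(wb$mediated_by, tc$truth$water_bridges$water_res)
  expect_true(all(c(wb$distance_a, wb$distance_b) <= 3.5))
  dry <- subset_structure(tc$structure, drop_water = TRUE)
  expect_equal(nrow(find_water_bridges(dry, "P", "R")), 0L)
})

test_that("fluorine is accepted only as a ribose 2'-F acceptor", {
  d <- build_aform_duplex("GCGC", fluoro_pyrimidines = TRUE)
  s <- d$structure
  f_atom <- s$atom[s$atom$elesy == "F", ][1, ]
  # plant a serine donor 3.0 A from the fluorine
  og <- c(f_atom$x, f_atom$y + 3.0, f_atom$z)
  probe <- rbind(
    atom_df("OG", "SER", "P", 1, og[1], og[2], og[3], "O"),
    atom_df("CB", "SER", "P", 1, og[1], og[2] + 1.4, og[3], "C"))
  s$atom <- rbind(s$atom[, colnames(s$atom)],
                  cbind(probe, parent_base = NA, polymer = "protein"))
  s$atom$eleno <- seq_len(nrow(s$atom))
  hb <- find_hbonds(s, "P", "A")
  fb <- hb[hb$fluorine_acceptor, ]
  expect_gte(nrow(fb), 1L)
  expect_true(all(grepl("F2'", fb$acceptor)))
  expect_true(all(fb$nucleic_part == "ribose"))
})

test_that("parallel rings at stacking distance are found, perpendicular not", {
  base <- hexagon_residue(c(0, 0, 0), c(0, 0, 1), "A", 1)
  par <- hexagon_residue(c(0.5, 0, 3.4), c(0, 0, 1), "B", 1)
  perp <- hexagon_residue(c(0, 0, 4.5), c(1, 0, 0), "B", 2)
  s1 <- make_structure("stack", base, par)
  st <- find_stacking(s1, "A", "B")
  expect_equal(nrow(st), 1L)
  expect_equal(st$centroid_distance, sqrt(0.5^2 + 3.4^2), tolerance = 1e-6)
  expect_lt(st$plane_angle, 1e-6)
  expect_equal(st$lateral_offset, 0.5, tolerance = 1e-6)
  s2 <- make_structure("perp", base, perp)
  expect_equal(nrow(find_stacking(s2, "A", "B")), 0L)
})

test_that("a planted base/phenyl stack is recovered across the interface", {
  tc <- planted_toy()
  st <- find_stacking(tc$structure, "P", "R")
  expect_equal(nrow(st), 1L)
  expect_equal(st$ring_b, tc$truth$stacks$rna_res)
  expect_equal(st$centroid_distance, tc$truth$stacks$distance,
               tolerance = 0.01)
})

test_that("categorisation tallies a hand-built bond list correctly", {
  tc <- planted_toy()
  ann <- annotate_rna(tc$structure, "R")
  hb <- find_hbonds(tc$structure, "P", "R")
  wb <- find_water_bridges(tc$structure, "P", "R")
  bonds <- rbind(hb, wb[, names(hb)])
  br <- categorize_hbonds(bonds, ann$ss)
  # planted: res 6, 8 in the loop; res 1, 12 in the stem; all nucleobase
  expect_equal(br$total, 4L)
  expect_equal(br$direct, 3L)
  expect_equal(br$water_mediated, 1L)
  expect_equal(br$nucleobase, 3L)   # direct bonds only
  expect_equal(br$backbone, 0L)
  expect_equal(br$loop, 2L)
  expect_equal(br$helix, 2L)
  expect_equal(br$fluorine, 0L)
  # empty list gives an all-zero breakdown
  z <- categorize_hbonds(hb[0, ], ann$ss)
  expect_equal(z$total, 0L)
  expect_equal(z$loop + z$helix + z$nucleobase, 0L)
})

test_that("bonds on nucleotides absent from the annotation error", {
  tc <- planted_toy()
  hb <- find_hbonds(tc$structure, "P", "R")
  hb$nucleic_res[1] <- "R:999"
  ann <- annotate_rna(tc$structure, "R")
  expect_error(categorize_hbonds(hb, ann$ss), "missing")
})

test_that("nonpolar contacts catch apolar side-chain packing", {
  a <- atom_df("CB", "ALA", "A", 1, 0, 0, 0, "C")
  b <- atom_df("CB", "ALA", "B", 1, 4.0, 0, 0, "C")
  s <- make_structure("np", a, b)
  np <- find_nonpolar_contacts(s, "A", "B")
  expect_equal(nrow(np), 1L)
  expect_equal(np$distance, 4.0)
  expect_equal(nrow(find_nonpolar_contacts(s, "A", "B", cutoff = 3.9)), 0L)
})
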