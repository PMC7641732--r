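# Superposition, matched RMSD, base planes.

test_that("identical point sets superpose to zero with identity rotation", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  f <- superpose(x, x)
  expect_lt(f$rmsd, 1e-12)
  expect_lt(max(abs(f$rotation - diag(3))), 1e-9)
})

test_that("a planted rotation + translation is recovered exactly", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  for (seed in c(11, 12, 13)) {
    R <- random_rotation(seed)
    y <- sweep(x %*% t(R), 2, c(3, -7, 2), `+`)
    f <- superpose(y, x)
    expect_lt(f$rmsd, 1e-9)
    # recovered rotation undoes the planted one
    expect_lt(max(abs(f$rotation %*% R - diag(3))), 1e-6)
    expect_lt(max(abs(apply_transform(y, f) - x)), 1e-9)
  }
})

test_that("rmsd under isotropic noise approaches sigma * sqrt(3)", {
  set.seed(4)
  n <- 20000
  sigma <- 0.4
  x <- matrix(runif(3 * n, 0, 50), n, 3)
  y <- x + matrix(rnorm(3 * n, 0, sigma), n, 3)
  f <- superpose(y, x)
  expect_lt(abs(f$rmsd / (sigma * sqrt(3)) - 1), 0.05)
})

test_that("superposition needs 3+ points and flags degenerate sets", {
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  f <- superpose(line, line)
  expect_true(f$degenerate)
  expect_lt(f$rmsd, 1e-9)
})

test_that("superposed rmsd never exceeds the unsuperposed rmsd", {
  set.seed(5)
  for (i in 1:5) {
    a <- matrix(rnorm(45), 15, 3)
    b <- matrix(rnorm(45), 15, 3)
    expect_lte(superpose(a, b)$rmsd, rmsd_coords(a, b) + 1e-12)
  }
})

test_that("matched RMSD of a structure against itself is zero", {
  h <- build_protein_helix(12)
  r <- rmsd_matched(h, h, "calpha")
  expect_equal(r$rmsd, 0)
  expect_equal(r$n_matched, 12L)  # one CA per residue
  # rigid motion invariance with superposition enabled
  R <- random_rotation(21)
  h2 <- h
  h2$atom[, c("x", "y", "z")] <-
    sweep(coords3d(h) %*% t(R), 2, c(5, 5, -2), `+`)
  expect_lt(rmsd_matched(h, h2, "heavy")$rmsd, 1e-9)
})

test_that("unmatched atoms are dropped and counted", {
  h1 <- build_protein_helix(12)
  h2 <- build_protein_helix(9)
  r <- rmsd_matched(h1, h2, "calpha")
  expect_equal(r$n_matched, 9L)
  expect_equal(r$n_unmatched_a, 3L)
  expect_error(rmsd_matched(h1, build_protein_helix(3),
                            "custom", elety = "OXT"), "matched")
})

test_that("base planes fit planar rings exactly and track noise", {
  hexa <- hexagon_residue(c(1, 2, 3), c(0, 0, 1), "A", 1)
  s <- make_structure("hex", hexa)
  pl <- base_plane(s$atom)
  expect_lt(pl$residual, 1e-12)
  expect_gt(abs(pl$normal[3]), 1 - 1e-12)
  expect_equal(unname(pl$centroid), c(1, 2, 3), tolerance = 1e-9)

  # out-of-plane noise sigma = 0.05 shows up as the residual
  set.seed(8)
  res <- replicate(40, {
    hx <- hexagon_residue(c(0, 0, 0), c(0, 0, 1), "A", 1)
    hx$z <- hx$z + rnorm(6, 0, 0.05)
    base_plane(make_structure("h", hx)$atom)$residual
  })
  expect_lt(abs(mean(res) / 0.05 - 1), 0.35)
})

test_that("successive base normals along a duplex strand are near-parallel", {
  d <- build_aform_duplex("GCAUGCG")
  a <- d$structure$atom
  rk <- unique(paste0("A:", 1:6))
  normals <- lapply(1:6, function(i)
    base_plane(a[a$resno == i, ])$normal)
  for (i in 1:5) {
    ang <- acos(abs(sum(normals[[i]] * normals[[i + 1]]))) * 180 / pi
    expect_lt(ang, 20)
  }
})

test_that("atom distances match hand values", {
  a <- atom_df("CA", "GLY", "A", 1, 0, 0, 0)
  b <- atom_df("CA", "GLY", "A", 2, 1, 0, 0)
  expect_equal(atom_distance(a, a), 0)
  expect_equal(atom_distance(a, b), 1)
})
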