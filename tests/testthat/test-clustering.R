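# Energy filtering and neighbour-count centroid clustering.

test_that("the energy filter keeps the ceiling fraction, ties by index", {
  e <- ensemble3d(replicate(10, matrix(0, 4, 3), simplify = FALSE),
                  energy = c(5, 1, 3, 2, 4, 6, 7, 8, 9, 10))
  expect_equal(select_low_energy(e, 1.0), 1:10)
  expect_equal(select_low_energy(e, 0.3), c(2, 3, 4))
  # all-equal energies: lowest model indices win
  e2 <- ensemble3d(replicate(6, matrix(0, 4, 3), simplify = FALSE),
                   energy = rep(1, 6))
  expect_equal(select_low_energy(e2, 0.5), 1:3)
  expect_error(select_low_energy(ensemble3d(list(), numeric()), 0.5),
               "empty")
})

test_that("a single member forms one singleton cluster of itself", {
  e <- ensemble3d(list(matrix(rnorm(12), 4, 3)), energy = 1)
  cr <- cluster_ensemble(e, clustering_config(energy_fraction = 1))
  expect_length(cr$clusters, 1L)
  expect_equal(cr$clusters[[1]]$member_models, 1L)
  expect_equal(cr$clusters[[1]]$centroid_model, 1L)
})

test_that("planted clusters are recovered with exact ranked sizes", {
  pe <- build_planted_ensemble(c(69, 61, 38), sigma = 0.5,
                               separation = 20, seed = 11,
                               survive_fraction = 0.1)
  cr <- cluster_ensemble(pe$ensemble,
                         clustering_config(energy_fraction = 0.10,
                                           rmsd_threshold = 5.0))
  expect_equal(cluster_sizes(cr), c(69L, 61L, 38L))
  expect_length(cr$overflow_pos, 0L)
  # recovered memberships equal the planted labels
  for (cl in cr$clusters) {
    labs <- pe$truth$labels[cl$member_pos]
    expect_length(unique(labs), 1L)
    expect_gt(unique(labs), 0L)
  }
})

test_that("clustering matches an exhaustive neighbour-count oracle", {
  for (seed in c(3, 17, 29)) {
    set.seed(seed)
    coords <- replicate(20, matrix(runif(30, 0, 12), 10, 3),
                        simplify = FALSE)
    e <- ensemble3d(coords, energy = runif(20))
    cfg <- clustering_config(energy_fraction = 1.0, rmsd_threshold = 4.0,
                             max_clusters = NULL)
    cr <- cluster_ensemble(e, cfg)
    oracle <- oracle_clustering(cr$pairwise_rmsd, cr$selected_models, 4.0)
    got <- lapply(cr$clusters, function(cl)
      sort(match(cl$member_pos, cr$selected_pos)))
    expect_equal(got, oracle)
  }
})

test_that("the result is a deterministic partition with ranked sizes", {
  pe <- build_planted_ensemble(c(8, 5, 3), sigma = 0.4, separation = 15,
                               seed = 23)
  cfg <- clustering_config(energy_fraction = 1.0)
  c1 <- cluster_ensemble(pe$ensemble, cfg)
  c2 <- cluster_ensemble(pe$ensemble, cfg)
  expect_identical(c1$clusters, c2$clusters)
  sizes <- cluster_sizes(c1)
  expect_true(all(diff(sizes) <= 0))
  n_covered <- sum(sizes) + length(c1$overflow_pos)
  expect_equal(n_covered, length(c1$selected_pos))
  all_members <- unlist(lapply(c1$clusters, function(cl) cl$member_pos))
  expect_false(anyDuplicated(all_members) > 0)
  # every non-centroid member lies within the threshold of its centroid
  for (cl in c1$clusters) {
    ci <- match(cl$centroid_pos, c1$selected_pos)
    for (m in match(cl$member_pos, c1$selected_pos)) {
      if (m != ci) expect_lt(c1$pairwise_rmsd[ci, m], 5.0)
    }
  }
})

test_that("max_clusters truncation reports singleton overflow", {
  pe <- build_planted_ensemble(c(6, 4, 3), sigma = 0.3, separation = 15,
                               seed = 9)
  cr <- cluster_ensemble(pe$ensemble,
                         clustering_config(energy_fraction = 1,
                                           max_clusters = 2))
  expect_length(cr$clusters, 2L)
  expect_equal(length(cr$overflow_pos), 3L)
  expect_equal(sum(cluster_sizes(cr)) + length(cr$overflow_pos), 13L)
})

test_that("raising the threshold never needs more clusters", {
  pe <- build_planted_ensemble(c(7, 5), sigma = 0.5, separation = 12,
                               seed = 13)
  cfg_lo <- clustering_config(energy_fraction = 1, rmsd_threshold = 2,
                              max_clusters = NULL)
  cfg_hi <- clustering_config(energy_fraction = 1, rmsd_threshold = 14,
                              max_clusters = NULL)
  n_lo <- length(cluster_ensemble(pe$ensemble, cfg_lo)$clusters)
  n_hi <- length(cluster_ensemble(pe$ensemble, cfg_hi)$clusters)
  expect_lte(n_hi, n_lo)
})

test_that("inconsistent member shapes are rejected", {
  expect_error(ensemble3d(list(matrix(0, 4, 3), matrix(0, 5, 3)),
                          energy = c(1, 2)), "share")
})
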