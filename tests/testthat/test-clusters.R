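test_that("connectivity controls whether corner-sharing voxels merge", {
  geom <- tiny_geom()
  m <- array(0L, geom$shape)
  m[2, 2, 2] <- 1L
  m[3, 3, 3] <- 1L  # shares only a corner with (2,2,2)
  cs26 <- connected_components(m, 26, geom)
  cs6 <- connected_components(m, 6, geom)
  expect_equal(nrow(cs26$clusters), 1)
  expect_equal(cs26$clusters$size_voxels, 2)
  expect_equal(nrow(cs6$clusters), 2)
  expect_equal(cs6$clusters$size_voxels, c(1, 1))
  # edge-sharing pair merges under 18 but not 6
  m2 <- array(0L, geom$shape)
  m2[2, 2, 2] <- 1L
  m2[3, 3, 2] <- 1L
  expect_equal(nrow(connected_components(m2, 18, geom)$clusters), 1)
  expect_equal(nrow(connected_components(m2, 6, geom)$clusters), 2)
})

test_that("a face-connected L-shape is one cluster under all connectivities", {
  geom <- tiny_geom()
  m <- array(0L, geom$shape)
  m[2:4, 2, 2] <- 1L
  m[4, 3:4, 2] <- 1L
  for (conn in c(6, 18, 26)) {
    cs <- connected_components(m, conn, geom)
    expect_equal(nrow(cs$clusters), 1)
    expect_equal(cs$clusters$size_voxels, 5)
  }
})

test_that("empty masks give zero clusters and invalid connectivity errors", {
  geom <- tiny_geom()
  cs <- connected_components(array(0L, geom$shape), 26, geom)
  expect_equal(nrow(cs$clusters), 0)
  expect_true(all(cs$label_volume == 0))
  expect_error(connected_components(array(0L, geom$shape), 4, geom),
               "connectivity")
})

test_that("cluster sizes are a scan-order invariant and centroids in world mm", {
  geom <- centered_geometry(c(10L, 10L, 10L), 2)
  set.seed(21)
  m <- array(as.integer(runif(1000) < 0.2), geom$shape)
  cs <- connected_components(m, 26, geom)
  # flipping all axes relabels the scan order but not the size multiset
  mf <- m[10:1, 10:1, 10:1]
  csf <- connected_components(mf, 26, geom)
  expect_identical(sort(cs$clusters$size_voxels),
                   sort(csf$clusters$size_voxels))
  expect_identical(sum(cs$clusters$size_voxels), sum(m))
  # sizes reported in decreasing order; ids dense 1..K
  expect_identical(cs$clusters$size_voxels,
                   sort(cs$clusters$size_voxels, decreasing = TRUE))
  expect_identical(cs$clusters$cluster_id, seq_len(nrow(cs$clusters)))
  # single-voxel cluster centroid is that voxel's world coordinate
  m1 <- array(0L, geom$shape); m1[4, 5, 6] <- 1L
  c1 <- connected_components(m1, 6, geom)
  expect_equal(c(c1$clusters$centroid_x_mm, c1$clusters$centroid_y_mm,
                 c1$clusters$centroid_z_mm),
               as.numeric(voxel_to_world(c(3, 4, 5), geom)))
})

test_that("permutation null is deterministic and degenerate cohorts give threshold 0", {
  geom <- tiny_geom(shape = c(8L, 8L, 8L))
  vox <- rbind(c(2, 2, 2), c(3, 2, 2), c(5, 5, 5))
  masks <- c(lapply(1:3, function(i) make_mask(vox[1:i, , drop = FALSE],
                                               geom, paste0("r", i))),
             lapply(1:3, function(i) make_mask(vox[1:i, , drop = FALSE],
                                               geom, paste0("p", i))))
  ch <- assemble_cohort(masks, rep(c("recurrence", "psp"), each = 3))
  n1 <- permutation_null(ch, "enhancing", n_iterations = 50, seed = 9)
  n2 <- permutation_null(ch, "enhancing", n_iterations = 50, seed = 9)
  expect_identical(n1$max_cluster_sizes, n2$max_cluster_sizes)
  # groups are copies of one stack and, at 3 vs 3, the smallest achievable
  # two-tailed p is 2/choose(6,3) = 0.1 > alpha: no permutation finds a signal
  expect_true(all(n1$max_cluster_sizes == 0))
  expect_equal(n1$threshold_voxels, 0)
})

test_that("survival requires size strictly above the null threshold", {
  geom <- tiny_geom(shape = c(20L, 20L, 20L))
  lab <- array(0L, geom$shape)
  lab[1:10, 1:10, 1:5] <- 1L   # 500 voxels
  lab[15:20, 15:20, 15:20] <- 2L  # 216 voxels
  cs <- connected_components(lab > 0, 6, geom)
  expect_equal(cs$clusters$size_voxels, c(500, 216))
  corr <- apply_cluster_correction(cs, 216L)
  expect_identical(corr$clusters$survives_correction, c(TRUE, FALSE))
  corr0 <- apply_cluster_correction(cs, 0L)
  expect_true(all(corr0$clusters$survives_correction))
  empty <- connected_components(array(0L, geom$shape), 26, geom)
  expect_equal(nrow(apply_cluster_correction(empty, 5L)$clusters), 0)
})

test_that("the empirical threshold is the inverse-ECDF 95th percentile", {
  x <- c(rep(0, 50), rep(10, 45), 100, 200, 300, 400, 500)
  # 95 of the 100 values are <= 10, so 10 is the smallest attained value
  # covering 95% of the distribution
  expect_equal(adiffi:::empirical_upper_quantile(x, 0.95), 10)
  expect_equal(adiffi:::empirical_upper_quantile(0:9, 0.95), 9)
  expect_equal(adiffi:::empirical_upper_quantile(rep(7, 5), 0.95), 7)
})

test_that("clusters are designated by the dominant population atlas", {
  geom <- tiny_geom()
  lab <- array(0L, geom$shape)
  lab[2:3, 2, 2] <- 1L
  cs <- connected_components(lab, 26, geom)
  mk_atlas <- function(val) {
    f <- array(0, geom$shape)
    f[2:3, 2, 2] <- val
    structure(list(geometry = geom, group = "recurrence",
                   compartment = "enhancing", freq = f, n_subjects = 10),
              class = "frequency_atlas")
  }
  d1 <- designate_clusters(cs, mk_atlas(0.6), mk_atlas(0.1))
  expect_equal(d1$clusters$designation, "recurrence")
  d2 <- designate_clusters(cs, mk_atlas(0.1), mk_atlas(0.6))
  expect_equal(d2$clusters$designation, "psp")
  d3 <- designate_clusters(cs, mk_atlas(0), mk_atlas(0))
  expect_equal(d3$clusters$designation, "indeterminate")
})

test_that("survival decisions are stable as the permutation count grows", {
  agree <- vapply(1:4, function(s) {
    cfg <- simulation_config(n_recurrence = 12, n_psp = 12,
                             effect_strength = 1, seed = 100 + s)
    sim <- simulate_cohort(cfg)
    pm <- adiffi_map(sim$cohort, "peri_lesional")
    cl <- connected_components(pm)
    n_small <- permutation_null(sim$cohort, "peri_lesional",
                                n_iterations = 200, seed = 42)
    n_big <- permutation_null(sim$cohort, "peri_lesional",
                              n_iterations = 1000, seed = 43)
    identical(
      apply_cluster_correction(cl, n_small)$clusters$survives_correction,
      apply_cluster_correction(cl, n_big)$clusters$survives_correction)
  }, logical(1))
  expect_true(all(agree))
})
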