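test_that("the toy parcellation has all 12 regions, sized and lateralized", {
  parc <- generate_toy_parcellation()
  expect_equal(nrow(parc$table), 12)
  counts <- table(factor(parc$labels[parc$labels > 0], levels = 1:12))
  expect_true(all(counts >= 100))
  expect_setequal(unique(parc$table$region_name),
                  c("frontal", "parietal", "temporal", "occipital",
                    "insula", "putamen"))
  # hemisphere follows world x sign
  idx <- which(parc$labels > 0)
  ijk <- arrayInd(idx, .dim = parc$geometry$shape) - 1L
  x <- voxel_to_world(ijk, parc$geometry)[, 1]
  hemi <- parc$table$hemisphere[match(parc$labels[idx], parc$table$label)]
  expect_true(all(hemi[x > 0] == "right"))
  expect_true(all(hemi[x < 0] == "left"))
  # background exists (ellipsoid strictly inside the box)
  expect_gt(mean(parc$labels == 0), 0)
  expect_error(generate_toy_parcellation(c(6L, 48L, 48L)), "grid too small")
})

test_that("identical configs reproduce cohorts bitwise", {
  cfg <- simulation_config(n_recurrence = 4, n_psp = 4, seed = 77,
                           grid_shape = c(24L, 28L, 24L), voxel_size_mm = 6)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  for (i in seq_along(s1$cohort$masks)) {
    expect_identical(s1$cohort$masks[[i]]$data, s2$cohort$masks[[i]]$data)
  }
  expect_identical(s1$truth$blobs, s2$truth$blobs)
})

test_that("full effect strength plants every recurrence blob in its region", {
  cfg <- simulation_config(n_recurrence = 20, n_psp = 20, effect_strength = 1,
                           recurrence_center_region = "parietal_right",
                           seed = 5)
  sim <- simulate_cohort(cfg)
  rec_blobs <- sim$truth$blobs[sim$truth$blobs$group == "recurrence", ]
  expect_true(all(rec_blobs$planted))
  parietal_right <- sim$parcellation$table$label[
    sim$parcellation$table$region_name == "parietal" &
      sim$parcellation$table$hemisphere == "right"]
  expect_true(all(rec_blobs$region_label == parietal_right))
  expect_equal(sim$truth$recurrence, parietal_right)
  psp_blobs <- sim$truth$blobs[sim$truth$blobs$group == "psp", ]
  expect_true(all(psp_blobs$region_label %in% sim$truth$psp))
})

test_that("lesions never extend outside the brain", {
  cfg <- simulation_config(n_recurrence = 5, n_psp = 5, seed = 8)
  sim <- simulate_cohort(cfg)
  bg <- sim$parcellation$labels == 0L
  for (m in sim$cohort$masks) expect_equal(sum(m$data[bg]), 0)
})

test_that("null cohorts have empty truth and exchangeable generative law", {
  cfg <- simulation_config(n_recurrence = 100, n_psp = 100, seed = 31)
  sim <- simulate_null_cohort(cfg)
  expect_length(sim$truth$recurrence, 0)
  expect_length(sim$truth$psp, 0)
  expect_true(all(!sim$truth$blobs$planted))
  # both groups draw the same number of blobs per subject
  per_subj <- table(sim$truth$blobs$subject_id)
  expect_equal(length(unique(per_subj)), 1)
  # group mean lesion frequencies converge at n = 100 + 100
  fr <- build_frequency_atlas(sim$cohort, "recurrence", "peri_lesional")
  fp <- build_frequency_atlas(sim$cohort, "psp", "peri_lesional")
  expect_lt(mean(abs(fr$freq - fp$freq)), 0.1)
})

test_that("a written cohort reads back identically", {
  cfg <- simulation_config(n_recurrence = 3, n_psp = 3, seed = 12,
                           grid_shape = c(24L, 28L, 24L), voxel_size_mm = 6)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  ch <- read_cohort(dir)
  expect_equal(ch$n_recurrence, 3)
  expect_equal(ch$n_psp, 3)
  for (i in seq_along(ch$masks)) {
    expect_identical(ch$masks[[i]]$data, sim$cohort$masks[[i]]$data)
    expect_identical(ch$masks[[i]]$compartment,
                     sim$cohort$masks[[i]]$compartment)
  }
  parc <- load_parcellation(file.path(dir, "parcellation.nii.gz"),
                            file.path(dir, "parcellation_labels.csv"))
  expect_identical(parc$labels, sim$parcellation$labels)
})

test_that("stronger planted effects yield more significant voxels on average", {
  mean_sig <- vapply(c(0, 0.5, 1), function(es) {
    sig <- vapply(1:10, function(s) {
      cfg <- simulation_config(n_recurrence = 10, n_psp = 10,
                               effect_strength = es, seed = 400 + s,
                               focality = c(1L, 1L))
      sim <- simulate_cohort(cfg)
      sum(adiffi_map(sim$cohort, "peri_lesional")$sig_mask)
    }, numeric(1))
    mean(sig)
  }, numeric(1))
  expect_true(all(diff(mean_sig) >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_recurrence = 0), "n_recurrence")
  expect_error(simulation_config(effect_strength = 1.2), "effect_strength")
  expect_error(simulation_config(lesion_radius_range_mm = c(5, 3)))
  cfg <- simulation_config(recurrence_center_region = "cerebellum_left")
  expect_error(simulate_cohort(cfg), "absent from parcellation")
})
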