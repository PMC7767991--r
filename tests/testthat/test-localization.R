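# parcellation with parietal/occipital blocks split by hemisphere on a grid
# whose world x sign is negative for i <= 5 and positive for i >= 6
loc_parcellation <- function() {
  geom <- centered_geometry(c(10L, 10L, 10L), 2)
  lab <- array(0L, geom$shape)
  lab[1:5, 1:8, ] <- 1L   # parietal left
  lab[6:10, 1:8, ] <- 2L  # parietal right
  lab[1:5, 9:10, ] <- 3L  # occipital left
  lab[6:10, 9:10, ] <- 4L # occipital right
  parcellation_atlas(lab, geom, data.frame(
    label = 1:4,
    region_name = c("parietal", "parietal", "occipital", "occipital"),
    hemisphere = c("left", "right", "left", "right")))
}

test_that("all voxels in one region localize to it at 100%", {
  parc <- loc_parcellation()
  sig <- array(0L, parc$geometry$shape)
  sig[6:8, 2:4, 2:4] <- 1L
  rep <- localize(sig, parc, designations = "recurrence")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$region_name, "parietal")
  expect_equal(rep$hemisphere, "right")
  expect_equal(rep$percent, 100)
  s <- region_summary(rep)
  expect_equal(s$percent, 100)
  expect_equal(s$percent_right_within, 100)
})

test_that("85 of 100 parietal voxels with a 50/35 right-left split reproduce the 85%/59% arithmetic", {
  parc <- loc_parcellation()
  sig <- array(0L, parc$geometry$shape)
  sig[6:10, 1:2, 1:5] <- 1L  # 50 voxels parietal right
  sig[1:5, 1:1, 1:7] <- 1L   # 35 voxels parietal left
  sig[6:10, 9:9, 1:3] <- 1L  # 15 voxels occipital right
  expect_equal(sum(sig), 100)
  rep <- localize(sig, parc, designations = "recurrence")
  s <- region_summary(rep)
  par_row <- s[s$region_name == "parietal", ]
  expect_equal(par_row$percent, 85)
  expect_equal(round(par_row$percent_right_within), 59)
  expect_equal(round(par_row$percent_left_within), 41)
  expect_equal(s[s$region_name == "occipital", "percent"], 15)
  # per-group percents over labelled rows sum to 100
  expect_equal(sum(rep$percent[rep$region_name != "unlabeled"]), 100,
               tolerance = 0.1)
})

test_that("empty significance volumes give an empty report without division by zero", {
  parc <- loc_parcellation()
  rep <- localize(array(0L, parc$geometry$shape), parc,
                  designations = "recurrence")
  expect_equal(nrow(rep), 0)
  expect_equal(describe_localization(rep), "No significant voxels to localize.")
})

test_that("voxel counts partition: every attributed voxel lands in one row", {
  parc <- loc_parcellation()
  set.seed(33)
  lab <- array(0L, parc$geometry$shape)
  lab[sample(1000, 200)] <- sample(1:3, 200, replace = TRUE)
  des <- c("recurrence", "psp", "recurrence")
  rep <- localize(lab, parc, designations = des)
  expect_equal(sum(rep$voxel_count), sum(lab > 0))
  grp_arr <- array("", dim(lab))
  grp_arr[lab > 0] <- des[lab[lab > 0]]
  for (g in c("recurrence", "psp")) {
    idx <- which(grp_arr == g)
    on_label <- sum(parc$labels[idx] > 0)
    r <- rep[rep$group == g & rep$region_name != "unlabeled", ]
    expect_equal(sum(r$voxel_count), on_label)
    if (on_label > 0) expect_equal(sum(r$percent), 100, tolerance = 1e-9)
  }
})

test_that("reports survive parcellation label renumbering", {
  parc <- loc_parcellation()
  sig <- array(0L, parc$geometry$shape)
  sig[c(3, 250, 700, 999)] <- 1L
  rep1 <- localize(sig, parc, designations = "psp")
  relab <- parc
  map <- c(4L, 3L, 2L, 1L)
  relab$labels[parc$labels > 0] <- map[parc$labels[parc$labels > 0]]
  relab$table$label <- map
  rep2 <- localize(sig, relab, designations = "psp")
  key <- function(r) r[order(r$region_name, r$hemisphere),
                       c("region_name", "hemisphere", "voxel_count", "percent")]
  expect_equal(key(rep1), key(rep2), ignore_attr = TRUE)
})

test_that("background voxels are reported as unlabeled with NA percent", {
  parc <- loc_parcellation()
  geom <- parc$geometry
  sig <- array(0L, geom$shape)
  sig[6, 2, 2] <- 1L
  bg <- parc
  bg$labels[6, 2, 2] <- 0L
  sig[7, 2, 2] <- 1L
  rep <- localize(sig, bg, designations = "recurrence")
  un <- rep[rep$region_name == "unlabeled", ]
  expect_equal(un$voxel_count, 1)
  expect_true(is.na(un$percent))
  expect_equal(rep$percent[rep$region_name == "parietal"], 100)
})

test_that("cluster sets localize via their designations, surviving only", {
  parc <- loc_parcellation()
  lab <- array(0L, parc$geometry$shape)
  lab[2:3, 2, 2] <- 1L   # cluster 1, left parietal
  lab[8:9, 2, 2] <- 2L   # cluster 2, right parietal
  cs <- connected_components(lab > 0, 6, parc$geometry)
  cs$clusters$designation <- c("recurrence", "psp")
  cs$clusters$survives_correction <- c(TRUE, FALSE)
  rep <- localize(cs, parc, surviving_only = TRUE)
  expect_equal(unique(rep$group), "recurrence")
  rep_all <- localize(cs, parc, surviving_only = FALSE)
  expect_setequal(unique(rep_all$group), c("recurrence", "psp"))
})

test_that("hemisphere assignment follows world x with a half-voxel midline band", {
  geom <- centered_geometry(c(21L, 5L, 5L), 3)  # odd grid: exact x = 0 column
  expect_equal(hemisphere_of(c(20, 2, 2), geom), "right")  # x = +30
  expect_equal(hemisphere_of(c(0, 2, 2), geom), "left")
  expect_equal(hemisphere_of(c(10, 2, 2), geom), "midline")  # x = 0
  expect_error(hemisphere_of(c(21, 2, 2), geom), "out of range")
  # mirroring the affine's x axis swaps left and right everywhere off-midline
  mir <- geom$affine
  mir[1, ] <- -mir[1, ]
  geom_m <- grid_geometry(geom$shape, mir)
  ijk <- cbind(0:20, 2, 2)
  h <- hemisphere_of(ijk, geom)
  hm <- hemisphere_of(ijk, geom_m)
  swap <- c(left = "right", right = "left", midline = "midline")
  expect_identical(hm, unname(swap[h]))
})
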