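#' Configuration for the synthetic lesion cohort generator
#'
#' Defines the generative law for a two-phenotype cohort of blob-like binary
#' lesions on a toy lobar parcellation. Each subject's enhancing mask is the
#' union of `focality` spheroidal blobs: the blob centre falls inside the
#' group's assigned region with probability `effect_strength` (otherwise
#' uniformly anywhere in-brain), is jittered by isotropic Gaussian noise of
#' `displacement_sd_mm`, and the radius is drawn uniformly from
#' `lesion_radius_range_mm`. The peri-lesional mask is the concentric
#' spheroid with radius scaled by `peri_factor`, emulating the T2/FLAIR
#' hyperintensity around the enhancing core. Defaults mirror a recurrence
#' group concentrated in the right parietal lobe against a multifocal
#' pseudo-progression group spread over frontal/temporal/insula/putamen.
#'
#' @param grid_shape Grid size in voxels (default 48 x 56 x 48).
#' @param voxel_size_mm Isotropic voxel edge, mm (default 3).
#' @param n_recurrence,n_psp Group sizes (defaults 41 and 33).
#' @param lesion_radius_range_mm Enhancing blob radius range, mm.
#' @param recurrence_center_region Region for recurrence blobs: a label id or
#'   a `"region_hemisphere"` name such as `"parietal_right"`.
#' @param psp_center_regions Regions for psp blobs (one drawn per blob).
#' @param focality Blobs per subject, length-2 `(recurrence, psp)` or scalar.
#' @param displacement_sd_mm Gaussian jitter of blob centres, mm.
#' @param effect_strength Probability in \[0, 1\] that a blob is placed in its
#'   group's assigned region rather than uniformly in-brain. 0 gives a null
#'   cohort in which the two groups share one generative law.
#' @param peri_factor Peri-lesional radius multiplier (default 1.6).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(grid_shape = c(48L, 56L, 48L),
                              voxel_size_mm = 3,
                              n_recurrence = 41L, n_psp = 33L,
                              lesion_radius_range_mm = c(10, 20),
                              recurrence_center_region = "parietal_right",
                              psp_center_regions = c("frontal_left",
                                                     "frontal_right",
                                                     "temporal_left",
                                                     "temporal_right",
                                                     "insula_left",
                                                     "insula_right",
                                                     "putamen_left",
                                                     "putamen_right"),
                              focality = c(1L, 3L),
                              displacement_sd_mm = 4,
                              effect_strength = 0.8,
                              peri_factor = 1.6,
                              seed = 1L) {
  if (length(focality) == 1L) focality <- rep(focality, 2L)
  stopifnot(n_recurrence >= 1, n_psp >= 1,
            length(lesion_radius_range_mm) == 2L,
            lesion_radius_range_mm[1] <= lesion_radius_range_mm[2],
            lesion_radius_range_mm[1] > 0,
            effect_strength >= 0, effect_strength <= 1,
            displacement_sd_mm >= 0, peri_factor >= 1,
            all(focality >= 1))
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
         n_recurrence = as.integer(n_recurrence), n_psp = as.integer(n_psp),
         lesion_radius_range_mm = lesion_radius_range_mm,
         recurrence_center_region = recurrence_center_region,
         psp_center_regions = psp_center_regions,
         focality = as.integer(focality),
         displacement_sd_mm = displacement_sd_mm,
         effect_strength = effect_strength, peri_factor = peri_factor,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Toy lobar parcellation on an ellipsoidal brain
#'
#' Partitions an ellipsoidal "brain" (semi-axes 90% of the half field of
#' view) into 12 labelled blocks: frontal, parietal, temporal and occipital
#' lobes split by hemisphere along anterior-posterior/dorsal-ventral planes,
#' plus deep insula and putamen blocks per hemisphere carved out around the
#' midline. Hemispheres follow world x sign (RAS+: x > 0 is right). Voxels
#' outside the ellipsoid are background 0. A stand-in for a labelled
#' anatomical atlas, sized so the full pipeline runs in seconds.
#'
#' @param grid_shape Grid size in voxels; every axis must be at least 8.
#' @param voxel_size_mm Isotropic voxel edge, mm.
#' @return A `parcellation_atlas` with 12 regions.
#' @export
generate_toy_parcellation <- function(grid_shape = c(48L, 56L, 48L),
                                      voxel_size_mm = 3) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 8L)) {
    stop("grid too small: every axis needs at least 8 voxels to host the ",
         "region blocks", call. = FALSE)
  }
  geom <- centered_geometry(grid_shape, voxel_size_mm)
  xs <- axis_world_coords(geom, 1L)
  ys <- axis_world_coords(geom, 2L)
  zs <- axis_world_coords(geom, 3L)
  semi <- 0.9 * (grid_shape * voxel_size_mm) / 2
  X <- array(rep(xs, times = prod(grid_shape[2:3])), grid_shape)
  Y <- array(rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]),
             grid_shape)
  Z <- array(rep(zs, each = prod(grid_shape[1:2])), grid_shape)
  brain <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  # anterior-posterior cuts (y in RAS+ points anterior), placed so lobe
  # volume fractions approximate real cerebral anatomy (frontal ~40%,
  # temporal ~25%, parietal ~18%, occipital ~11%): frontal reaches back to
  # the central-sulcus plane, the mid band splits into dorsal parietal and
  # ventral temporal, occipital takes the posterior cap
  y_front <- 0.10 * semi[2]
  y_occ <- -0.60 * semi[2]
  z_pt <- 0.15 * semi[3]
  lobe <- array("", grid_shape)
  lobe[Y >= y_front] <- "frontal"
  lobe[Y < y_front & Y >= y_occ & Z >= z_pt] <- "parietal"
  lobe[Y < y_front & Y >= y_occ & Z < z_pt] <- "temporal"
  lobe[Y < y_occ] <- "occipital"
  # deep structures: boxes straddling the temporal/parietal band near midline
  deep_y <- abs(Y - semi[2] / 12) <= semi[2] / 5
  deep_z <- abs(Z) <= semi[3] / 4
  insula <- deep_y & deep_z & abs(X) > semi[1] / 4 & abs(X) <= semi[1] * 0.45
  putamen <- deep_y & deep_z & abs(X) <= semi[1] / 4
  lobe[insula] <- "insula"
  lobe[putamen] <- "putamen"
  hemi <- ifelse(X > 0, "right", "left")
  region_names <- c("frontal", "parietal", "temporal", "occipital",
                    "insula", "putamen")
  table <- data.frame(
    label = seq_len(2L * length(region_names)),
    region_name = rep(region_names, each = 2L),
    hemisphere = rep(c("left", "right"), times = length(region_names)),
    stringsAsFactors = FALSE
  )
  key <- paste(table$region_name, table$hemisphere, sep = "_")
  labels <- array(0L, grid_shape)
  inb <- which(brain)
  labels[inb] <- table$label[match(paste(lobe[inb], hemi[inb], sep = "_"),
                                   key)]
  parcellation_atlas(labels, geom, table)
}

# Resolve a region given as label id or "region_hemisphere" name.
resolve_region_label <- function(region, parcellation) {
  tab <- parcellation$table
  if (is.numeric(region)) {
    if (!all(region %in% tab$label)) {
      stop("region label(s) ", paste(setdiff(region, tab$label),
                                     collapse = ", "),
           " absent from parcellation", call. = FALSE)
    }
    return(as.integer(region))
  }
  key <- paste(tab$region_name, tab$hemisphere, sep = "_")
  hit <- match(region, key)
  if (anyNA(hit)) {
    stop("region name(s) ", paste(region[is.na(hit)], collapse = ", "),
         " absent from parcellation (expected e.g. '", key[1], "')",
         call. = FALSE)
  }
  tab$label[hit]
}

#' Simulate a synthetic two-phenotype lesion cohort
#'
#' Draws every subject's blobs from the generative law in
#' [simulation_config()], rasterizes them on the grid (a voxel is lesion when
#' its centre lies inside a blob), clips lesions to the brain (parcellation
#' label > 0), and assembles both compartments into a [assemble_cohort()]
#' cohort. One random stream, seeded from `config$seed`, is consumed in
#' subject order, so cohorts are bitwise reproducible.
#'
#' @param config A `simulation_config`.
#' @param parcellation Optional `parcellation_atlas`; defaults to
#'   [generate_toy_parcellation()] at the config's grid.
#' @return A `synthetic_cohort`: `cohort` (a `mask_cohort` with both
#'   compartments), `parcellation`, and `truth` — the planted region labels
#'   per group plus a per-blob log of centres, radii and intended regions.
#' @export
simulate_cohort <- function(config, parcellation = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(parcellation)) {
    parcellation <- generate_toy_parcellation(config$grid_shape,
                                              config$voxel_size_mm)
  }
  geom <- parcellation$geometry
  rec_label <- resolve_region_label(config$recurrence_center_region,
                                    parcellation)
  psp_labels <- resolve_region_label(config$psp_center_regions, parcellation)
  brain_idx <- which(parcellation$labels > 0L)
  region_idx <- lapply(c(rec_label, psp_labels), function(l) {
    which(parcellation$labels == l)
  })
  names(region_idx) <- as.character(c(rec_label, psp_labels))
  shape <- geom$shape
  xs <- axis_world_coords(geom, 1L)
  ys <- axis_world_coords(geom, 2L)
  zs <- axis_world_coords(geom, 3L)
  vox <- config$voxel_size_mm

  groups <- c(rep("recurrence", config$n_recurrence),
              rep("psp", config$n_psp))
  ids <- sprintf("%s%02d", ifelse(groups == "recurrence", "rec", "psp"),
                 stats::ave(seq_along(groups), groups, FUN = seq_along))
  masks <- vector("list", 2L * length(groups))
  blob_log <- list()

  rasterize_blob <- function(center, radius) {
    # voxels whose centre is within `radius` mm of the blob centre
    ix <- which(abs(xs - center[1]) <= radius)
    iy <- which(abs(ys - center[2]) <= radius)
    iz <- which(abs(zs - center[3]) <= radius)
    if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
    g <- expand.grid(ix, iy, iz)
    d2 <- (xs[g[, 1]] - center[1])^2 + (ys[g[, 2]] - center[2])^2 +
      (zs[g[, 3]] - center[3])^2
    keep <- d2 <= radius^2
    g[keep, 1] + shape[1] * (g[keep, 2] - 1L) +
      shape[1] * shape[2] * (g[keep, 3] - 1L)
  }

  withr::with_seed(config$seed, {
    for (s in seq_along(groups)) {
      grp <- groups[s]
      nf <- config$focality[if (grp == "recurrence") 1L else 2L]
      enh <- array(0L, shape)
      peri <- array(0L, shape)
      for (bl in seq_len(nf)) {
        planted <- stats::runif(1) < config$effect_strength
        if (planted) {
          lab <- if (grp == "recurrence") rec_label
                 else psp_labels[sample.int(length(psp_labels), 1L)]
          pool <- region_idx[[as.character(lab)]]
        } else {
          lab <- NA_integer_
          pool <- brain_idx
        }
        cidx <- pool[sample.int(length(pool), 1L)]
        cijk <- arrayInd(cidx, .dim = shape) - 1L
        center <- as.numeric(voxel_to_world(cijk, geom)) +
          stats::rnorm(3, 0, config$displacement_sd_mm)
        radius <- stats::runif(1, config$lesion_radius_range_mm[1],
                               config$lesion_radius_range_mm[2])
        enh[rasterize_blob(center, radius)] <- 1L
        peri[rasterize_blob(center, radius * config$peri_factor)] <- 1L
        blob_log[[length(blob_log) + 1L]] <- data.frame(
          subject_id = ids[s], group = grp, blob = bl, planted = planted,
          region_label = lab, center_x_mm = center[1],
          center_y_mm = center[2], center_z_mm = center[3],
          radius_mm = radius, stringsAsFactors = FALSE)
      }
      # clip to brain: lesions never extend into background
      enh[parcellation$labels == 0L] <- 0L
      peri[parcellation$labels == 0L] <- 0L
      masks[[2L * s - 1L]] <- binary_mask(enh, geom, ids[s], "enhancing")
      masks[[2L * s]] <- binary_mask(peri, geom, ids[s], "peri_lesional")
    }
  })
  cohort <- assemble_cohort(masks, rep(groups, each = 2L))
  truth <- list(
    recurrence = if (config$effect_strength > 0) rec_label else integer(0),
    psp = if (config$effect_strength > 0) psp_labels else integer(0),
    blobs = do.call(rbind, blob_log)
  )
  structure(list(cohort = cohort, parcellation = parcellation,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Simulate an exchangeable null cohort
#'
#' Forces `effect_strength = 0`, so both groups draw blob centres from one
#' law (uniform in-brain), and equalizes the per-group focality (to the
#' rounded mean of the configured pair), so that subjects of the two groups
#' follow one generative law and the labels are exchangeable — the
#' configuration under which the cluster-size correction's family-wise error
#' is calibrated. Without the focality equalization a differing number of
#' blobs per subject would be a true group difference, not a null.
#'
#' @param config A `simulation_config`; its `effect_strength` and `focality`
#'   are overridden.
#' @param parcellation Optional parcellation, as in [simulate_cohort()].
#' @return A `synthetic_cohort` whose `truth` planted-region sets are empty.
#' @export
simulate_null_cohort <- function(config, parcellation = NULL) {
  config$effect_strength <- 0
  config$focality <- rep(as.integer(round(mean(config$focality))), 2L)
  simulate_cohort(config, parcellation)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> effect_strength = ", x$config$effect_strength,
      ", seed = ", x$config$seed, "\n", sep = "")
  print(x$cohort)
  invisible(x)
}

#' Write a synthetic cohort to disk as NIfTI masks plus a manifest
#'
#' Writes one mask per (subject, compartment) under `dir`, a
#' `cohort.csv` manifest (`subject_id,group,compartment,path`) and the
#' parcellation pair (`parcellation.nii.gz`, `parcellation_labels.csv`).
#'
#' @param sim A `synthetic_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- sim$cohort
  rows <- lapply(seq_along(ch$masks), function(i) {
    m <- ch$masks[[i]]
    fn <- paste0(m$subject_id, "_", m$compartment, ".nii.gz")
    write_mask(m, file.path(dir, fn))
    data.frame(subject_id = m$subject_id, group = ch$labels[i],
               compartment = m$compartment, path = fn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "cohort.csv")
  utils::write.csv(manifest, mf, row.names = FALSE, quote = FALSE)
  write_parcellation(sim$parcellation,
                     file.path(dir, "parcellation.nii.gz"),
                     file.path(dir, "parcellation_labels.csv"))
  invisible(mf)
}

#' Read a cohort written by [write_cohort()] (or hand-made in that layout)
#'
#' @param dir Directory containing `cohort.csv` and the mask files.
#' @return A `mask_cohort`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "cohort.csv")
  if (!file.exists(mf)) stop("no cohort.csv under ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  masks <- lapply(seq_len(nrow(manifest)), function(i) {
    read_mask(file.path(dir, manifest$path[i]),
              compartment = manifest$compartment[i],
              subject_id = manifest$subject_id[i])
  })
  assemble_cohort(masks, manifest$group)
}
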