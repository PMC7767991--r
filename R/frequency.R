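#' Per-group voxel-wise lesion frequency atlas
#'
#' Averages the binary masks of one phenotype group: at each voxel the value
#' is the fraction of that group's subjects whose lesion covers the voxel.
#' This is the "population atlas" summarizing where a phenotype's lesions
#' occur across the cohort.
#'
#' @param cohort A `mask_cohort`.
#' @param group `"recurrence"` or `"psp"`, or `"all"` for the pooled cohort.
#' @param compartment `"enhancing"` or `"peri_lesional"`.
#' @return A `frequency_atlas`: `freq` (3D array in \[0, 1\], stored float64),
#'   `n_subjects`, `group`, `compartment`, `geometry`. `freq * n_subjects` is
#'   an exact integer count at every voxel.
#' @export
build_frequency_atlas <- function(cohort,
                                  group = c("recurrence", "psp", "all"),
                                  compartment = c("enhancing", "peri_lesional")) {
  group <- match.arg(group)
  compartment <- match.arg(compartment)
  cc <- cohort_compartment(cohort, compartment)
  keep <- if (group == "all") rep(TRUE, length(cc$masks)) else cc$labels == group
  if (!any(keep)) {
    stop("composition error: no '", group, "' subjects with '", compartment,
         "' masks", call. = FALSE)
  }
  count <- array(0L, cohort$geometry$shape)
  for (m in cc$masks[keep]) count <- count + m$data
  n <- sum(keep)
  structure(
    list(geometry = cohort$geometry, group = group, compartment = compartment,
         freq = count / n, n_subjects = n),
    class = "frequency_atlas"
  )
}

#' @export
print.frequency_atlas <- function(x, ...) {
  cat("<frequency_atlas> ", x$group, " [", x$compartment, "], n = ",
      x$n_subjects, ", max frequency ", format(max(x$freq), digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Export a frequency atlas as NIfTI plus an axial heat-map mosaic
#'
#' Writes the atlas volume (float32) and a PNG mosaic of evenly spaced axial
#' slices with frequencies > 0 rendered as a heat overlay on a grayscale
#' background. Pass the same `zlim` for the two group atlases so their colour
#' scales are comparable.
#'
#' @param atlas A `frequency_atlas`.
#' @param out_prefix Path prefix; writes `<prefix>.nii.gz` and `<prefix>.png`.
#' @param background Optional 3D array on the same grid shown in grayscale
#'   underneath (e.g. a template or the parcellation); defaults to a flat
#'   background.
#' @param zlim Colour scale range, default `c(0, max(freq))`.
#' @param n_slices Number of axial slices in the mosaic.
#' @return Invisibly, the two written paths.
#' @export
export_overlay <- function(atlas, out_prefix, background = NULL,
                           zlim = NULL, n_slices = 12) {
  nii <- paste0(out_prefix, ".nii.gz")
  png_path <- paste0(out_prefix, ".png")
  dir.create(dirname(nii), showWarnings = FALSE, recursive = TRUE)
  write_volume(atlas, nii)
  shape <- atlas$geometry$shape
  if (!is.null(background)) {
    if (inherits(background, "binary_mask")) {
      stopifnot_same_geometry(atlas$geometry, background$geometry,
                              "atlas and background")
      background <- background$data
    }
    if (!identical(as.integer(dim(background)), shape)) {
      stop("alignment error: background shape differs from atlas",
           call. = FALSE)
    }
  } else {
    background <- array(0, shape)
  }
  if (is.null(zlim)) zlim <- c(0, max(atlas$freq, 1e-12))
  zs <- unique(round(seq(1, shape[3], length.out = n_slices)))
  ncol_grid <- ceiling(sqrt(length(zs)))
  nrow_grid <- ceiling(length(zs) / ncol_grid)
  heat <- grDevices::hcl.colors(64, "Inferno")
  grDevices::png(png_path, width = 160 * ncol_grid, height = 160 * nrow_grid)
  op <- graphics::par(mfrow = c(nrow_grid, ncol_grid),
                      mar = c(0.3, 0.3, 1.2, 0.3))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  for (z in zs) {
    bg <- background[, , z]
    graphics::image(bg, col = grDevices::gray.colors(32, 0, 1),
                    axes = FALSE, useRaster = TRUE)
    fg <- atlas$freq[, , z]
    fg[fg <= 0] <- NA  # overlay only where frequency is positive
    graphics::image(fg, col = heat, zlim = zlim, add = TRUE, useRaster = TRUE)
    graphics::title(main = paste0("z=", z), cex.main = 0.8)
  }
  invisible(c(nii, png_path))
}
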