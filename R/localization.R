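#' Localize significant voxels onto a labelled parcellation
#'
#' Tallies significant voxels by anatomical region and hemisphere, per
#' phenotype. Percentages are taken over each group's significant voxels that
#' fall on labelled (nonzero) parcellation voxels; voxels on background are
#' reported in a separate `"unlabeled"` row whose percent is `NA`, so the
#' labelled rows of a group always sum to 100 (up to rounding).
#'
#' @param x Either a `cluster_set` (voxels are attributed to groups via each
#'   cluster's `designation`) or a binary/labelled 3D array.
#' @param parcellation A `parcellation_atlas` on the same grid.
#' @param designations When `x` is an array: a single group name applied to
#'   all foreground voxels, or a character vector indexed by the array's
#'   positive labels (designation of cluster id k at position k).
#' @param surviving_only When `x` is a `cluster_set`, restrict to clusters
#'   with `survives_correction == TRUE` (default). Ignored otherwise.
#' @param weights Optional 3D numeric array (e.g. a frequency atlas volume):
#'   tallies become sums of weights instead of voxel counts — the
#'   frequency-weighted variant of the report.
#' @return A `localization_report` data.frame with columns `group`,
#'   `region_name`, `hemisphere`, `voxel_count`, `percent`, sorted within
#'   group by decreasing count.
#' @export
localize <- function(x, parcellation, designations = NULL,
                     surviving_only = TRUE, weights = NULL) {
  if (inherits(x, "cluster_set")) {
    stopifnot_same_geometry(x$geometry, parcellation$geometry,
                            "clusters and parcellation")
    cl <- x$clusters
    if (surviving_only && nrow(cl) > 0 &&
        !all(is.na(cl$survives_correction))) {
      cl <- cl[cl$survives_correction %in% TRUE, , drop = FALSE]
    }
    vol <- x$label_volume
    keep_ids <- cl$cluster_id
    idx <- which(vol > 0 & array(vol %in% keep_ids, dim(vol)))
    grp <- cl$designation[match(vol[idx], cl$cluster_id)]
  } else {
    if (!identical(as.integer(dim(x)), parcellation$geometry$shape)) {
      stop("alignment error: volume shape differs from parcellation",
           call. = FALSE)
    }
    idx <- which(x > 0)
    if (is.null(designations)) {
      stop("`designations` is required for a bare array", call. = FALSE)
    }
    grp <- if (length(designations) == 1L) {
      rep(designations, length(idx))
    } else {
      designations[x[idx]]
    }
  }
  tab <- parcellation$table
  out <- list()
  for (g in unique(grp)) {
    gi <- idx[grp == g]
    w <- if (is.null(weights)) rep(1, length(gi)) else weights[gi]
    lab <- parcellation$labels[gi]
    labelled <- lab > 0L
    total <- sum(w[labelled])
    rows <- data.frame(group = character(0), region_name = character(0),
                       hemisphere = character(0), voxel_count = numeric(0),
                       percent = numeric(0), stringsAsFactors = FALSE)
    if (any(labelled)) {
      agg <- tapply(w[labelled], lab[labelled], sum)
      li <- match(as.integer(names(agg)), tab$label)
      rows <- data.frame(group = g, region_name = tab$region_name[li],
                         hemisphere = tab$hemisphere[li],
                         voxel_count = as.numeric(agg),
                         percent = 100 * as.numeric(agg) / total,
                         stringsAsFactors = FALSE)
      rows <- rows[order(-rows$voxel_count), , drop = FALSE]
    }
    if (any(!labelled)) {
      rows <- rbind(rows, data.frame(
        group = g, region_name = "unlabeled", hemisphere = "midline",
        voxel_count = sum(w[!labelled]), percent = NA_real_,
        stringsAsFactors = FALSE))
    }
    out[[g]] <- rows
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(0), region_name = character(0),
               hemisphere = character(0), voxel_count = numeric(0),
               percent = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("localization_report", "data.frame")
  res
}

#' Headline per-region summary with hemisphere splits
#'
#' Aggregates a localization report over hemispheres: per (group, region) the
#' share of that group's labelled significant voxels, alongside the
#' left/right split of the region's own distribution — the form in which
#' anatomical predilection is usually quoted (e.g. "parietal 85%, of which
#' 59% right").
#'
#' @param report A `localization_report` from [localize()].
#' @return Data.frame with `group`, `region_name`, `percent`,
#'   `percent_right_within`, `percent_left_within`, `voxel_count`.
#' @export
region_summary <- function(report) {
  r <- report[report$region_name != "unlabeled", , drop = FALSE]
  if (nrow(r) == 0L) {
    return(data.frame(group = character(0), region_name = character(0),
                      percent = numeric(0),
                      percent_right_within = numeric(0),
                      percent_left_within = numeric(0),
                      voxel_count = numeric(0), stringsAsFactors = FALSE))
  }
  key <- interaction(r$group, r$region_name, drop = TRUE)
  rows <- lapply(split(r, key), function(d) {
    tot <- sum(d$voxel_count)
    data.frame(group = d$group[1], region_name = d$region_name[1],
               percent = sum(d$percent),
               percent_right_within =
                 100 * sum(d$voxel_count[d$hemisphere == "right"]) / tot,
               percent_left_within =
                 100 * sum(d$voxel_count[d$hemisphere == "left"]) / tot,
               voxel_count = tot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, -out$percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plain-language localization summary
#'
#' @param report A `localization_report`.
#' @return Character vector, one sentence per (group, region).
#' @export
describe_localization <- function(report) {
  s <- region_summary(report)
  if (nrow(s) == 0L) return("No significant voxels to localize.")
  vapply(seq_len(nrow(s)), function(i) {
    sprintf(paste0("%s: %.0f%% of significant voxels in the %s ",
                   "(%.0f%% right / %.0f%% left)"),
            s$group[i], s$percent[i], s$region_name[i],
            s$percent_right_within[i], s$percent_left_within[i])
  }, character(1))
}
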