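#' Connected components of a binary significance volume
#'
#' Labels maximal connected sets of foreground voxels under a 6-, 18- or
#' 26-neighbourhood. 26-connectivity (vertex sharing) is the default, the
#' common cluster-forming choice in neuroimaging.
#'
#' @param sig_mask 3D 0/1 array, or a `pvalue_map` (its `sig_mask` is used).
#' @param connectivity One of 6, 18, 26.
#' @param geometry A [grid_geometry()]; taken from `sig_mask` when it is a
#'   `pvalue_map`.
#' @return A `cluster_set`: `label_volume` (3D integer array, 0 = background,
#'   cluster ids 1..K ranked by decreasing size) and `clusters`, a data.frame
#'   with `cluster_id`, `size_voxels`, `centroid_x/y/z_mm`, `designation`
#'   (initially `"indeterminate"`) and `survives_correction` (initially `NA`).
#' @export
connected_components <- function(sig_mask, connectivity = 26,
                                 geometry = NULL) {
  if (inherits(sig_mask, "pvalue_map")) {
    geometry <- sig_mask$geometry
    sig_mask <- sig_mask$sig_mask
  }
  if (is.null(geometry)) stop("`geometry` is required", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  shape <- geometry$shape
  stopifnot(identical(as.integer(dim(sig_mask)), shape))
  idx <- which(sig_mask > 0)
  label_volume <- array(0L, shape)
  if (length(idx) == 0L) {
    return(new_cluster_set(geometry, label_volume, empty_cluster_df()))
  }
  raw <- cc_label_3d(shape, idx - 1L, as.integer(connectivity))
  sizes <- tabulate(raw)
  # rank cluster ids by decreasing size; ties broken by first occurrence
  rank_order <- order(-sizes, seq_along(sizes))
  new_id <- integer(length(sizes))
  new_id[rank_order] <- seq_along(sizes)
  relab <- new_id[raw]
  label_volume[idx] <- relab
  ijk <- arrayInd(idx, .dim = shape) - 1L
  xyz <- voxel_to_world(ijk, geometry)
  df <- data.frame(
    cluster_id = seq_along(sizes),
    size_voxels = sizes[rank_order],
    centroid_x_mm = vapply(split(xyz[, 1], relab), mean, numeric(1)),
    centroid_y_mm = vapply(split(xyz[, 2], relab), mean, numeric(1)),
    centroid_z_mm = vapply(split(xyz[, 3], relab), mean, numeric(1)),
    designation = "indeterminate",
    survives_correction = NA,
    row.names = NULL, stringsAsFactors = FALSE
  )
  new_cluster_set(geometry, label_volume, df)
}

empty_cluster_df <- function() {
  data.frame(cluster_id = integer(0), size_voxels = integer(0),
             centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
             centroid_z_mm = numeric(0), designation = character(0),
             survives_correction = logical(0), stringsAsFactors = FALSE)
}

new_cluster_set <- function(geometry, label_volume, clusters) {
  structure(list(geometry = geometry, label_volume = label_volume,
                 clusters = clusters),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  k <- nrow(x$clusters)
  cat("<cluster_set> ", k, " cluster(s), ", sum(x$label_volume > 0),
      " voxels total\n", sep = "")
  if (k > 0) print(utils::head(x$clusters, 10))
  invisible(x)
}

# Maximum cluster size of a set of significant voxel indices; 0 when empty.
# Shared by the observed and the permuted paths so both use one definition.
max_component_size <- function(idx, shape, connectivity) {
  if (length(idx) == 0L) return(0L)
  raw <- cc_label_3d(shape, idx - 1L, as.integer(connectivity))
  max(tabulate(raw))
}

#' Null distribution of the maximum cluster size under group relabeling
#'
#' Repeatedly permutes the subject-to-phenotype assignment (preserving the
#' observed group sizes), recomputes the voxel-wise exact-test significance
#' map and its connected components, and records the largest cluster size
#' (0 when no voxel is significant). The cluster-size threshold is the
#' empirical 95th percentile of these maxima: the smallest size with at least
#' `1 - alpha_cluster` of the maxima at or below it (inverse ECDF, no
#' interpolation), so only clusters strictly larger arise in fewer than 5% of
#' permutations.
#'
#' @param cohort A `mask_cohort`.
#' @param compartment Lesion compartment.
#' @param n_iterations Number of random permutations (default 500).
#' @param alpha Voxel-wise significance level (default 0.05).
#' @param connectivity Cluster-forming neighbourhood, see
#'   [connected_components()].
#' @param seed Integer seed for the permutation stream.
#' @param alpha_cluster Cluster-level FWE target (default 0.05).
#' @param statistic `"max"` (per-iteration maximum cluster size; default) or
#'   `"pooled"` (all per-iteration cluster sizes pooled before taking the
#'   percentile) — a documented alternative reading of percentile-of-cluster-
#'   sizes correction.
#' @return A `permutation_null`: `max_cluster_sizes` (length `n_iterations`),
#'   `threshold_voxels`, `alpha_cluster`, `seed`, plus mean/sd summaries.
#' @export
permutation_null <- function(cohort,
                             compartment = c("enhancing", "peri_lesional"),
                             n_iterations = 500, alpha = 0.05,
                             connectivity = 26, seed = 1L,
                             alpha_cluster = 0.05,
                             statistic = c("max", "pooled")) {
  compartment <- match.arg(compartment)
  statistic <- match.arg(statistic)
  stopifnot(n_iterations >= 1)
  mm <- mask_matrix(cohort, compartment)
  n_rec <- sum(mm$labels == "recurrence")
  n_psp <- sum(mm$labels == "psp")
  n <- n_rec + n_psp
  shape <- cohort$geometry$shape
  # restrict to the lesion support: (a, c) can only be nonzero there, and
  # the support is invariant under relabeling
  tot <- colSums(mm$mat)
  support <- which(tot >= 1L)
  s_mat <- mm$mat[, support, drop = FALSE]
  pt <- fisher_p_table(n_rec, n_psp)
  maxima <- integer(n_iterations)
  pooled <- if (statistic == "pooled") vector("list", n_iterations) else NULL
  withr::with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      rec_rows <- sample.int(n, n_rec)
      a <- colSums(s_mat[rec_rows, , drop = FALSE])
      c_ <- tot[support] - a
      sig_local <- pt[cbind(a + 1L, c_ + 1L)] < alpha
      idx <- support[sig_local]
      if (length(idx) == 0L) {
        maxima[it] <- 0L
        if (!is.null(pooled)) pooled[[it]] <- integer(0)
      } else {
        raw <- cc_label_3d(shape, idx - 1L, as.integer(connectivity))
        sz <- tabulate(raw)
        maxima[it] <- max(sz)
        if (!is.null(pooled)) pooled[[it]] <- sz
      }
    }
  })
  dist <- if (statistic == "max") maxima else unlist(pooled)
  if (length(dist) == 0L) dist <- 0L
  threshold <- empirical_upper_quantile(dist, 1 - alpha_cluster)
  structure(
    list(compartment = compartment, n_iterations = as.integer(n_iterations),
         seed = as.integer(seed), statistic = statistic,
         max_cluster_sizes = maxima, threshold_voxels = threshold,
         alpha_cluster = alpha_cluster,
         mean_max = mean(maxima), sd_max = stats::sd(maxima)),
    class = "permutation_null"
  )
}

# Smallest observed value q such that at least `prob` of x is <= q.
# Integer-valued inverse ECDF: no interpolation, so the threshold is an
# attainable cluster size.
empirical_upper_quantile <- function(x, prob) {
  xs <- sort(x)
  xs[max(1L, ceiling(prob * length(xs)))]
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> [", x$compartment, "] ", x$n_iterations,
      " iterations; max cluster size mean ", format(x$mean_max, digits = 5),
      " sd ", format(x$sd_max, digits = 5), "; ",
      100 * (1 - x$alpha_cluster), "th percentile threshold ",
      x$threshold_voxels, " voxels\n", sep = "")
  invisible(x)
}

#' Flag clusters that survive the permutation cluster-size threshold
#'
#' A cluster survives when its size is strictly larger than the null
#' threshold, i.e. clusters of its size or larger arose in fewer than
#' `alpha_cluster` of the permutations.
#'
#' @param clusters A `cluster_set`.
#' @param null A `permutation_null` (or a bare integer threshold).
#' @return The `cluster_set` with `survives_correction` filled in; every
#'   cluster is retained in the report with its flag.
#' @export
apply_cluster_correction <- function(clusters, null) {
  threshold <- if (inherits(null, "permutation_null")) {
    null$threshold_voxels
  } else {
    as.integer(null)
  }
  clusters$clusters$survives_correction <-
    clusters$clusters$size_voxels > threshold
  clusters$threshold_voxels <- threshold
  clusters
}

#' Designate clusters by comparing the two population atlases
#'
#' Each cluster is attributed to the phenotype whose frequency atlas has the
#' higher mean over the cluster's voxels; exactly equal means give
#' `"indeterminate"`.
#'
#' @param clusters A `cluster_set`.
#' @param atlas_rec,atlas_psp `frequency_atlas` objects for the two groups on
#'   the same grid.
#' @return The `cluster_set` with `designation` filled in.
#' @export
designate_clusters <- function(clusters, atlas_rec, atlas_psp) {
  stopifnot_same_geometry(clusters$geometry, atlas_rec$geometry,
                          "clusters and recurrence atlas")
  stopifnot_same_geometry(clusters$geometry, atlas_psp$geometry,
                          "clusters and psp atlas")
  if (nrow(clusters$clusters) == 0L) return(clusters)
  lab <- clusters$label_volume
  idx <- which(lab > 0)
  g <- lab[idx]
  mean_rec <- vapply(split(atlas_rec$freq[idx], g), mean, numeric(1))
  mean_psp <- vapply(split(atlas_psp$freq[idx], g), mean, numeric(1))
  ord <- as.integer(names(mean_rec))
  des <- ifelse(mean_rec > mean_psp, "recurrence",
                ifelse(mean_psp > mean_rec, "psp", "indeterminate"))
  clusters$clusters$designation[ord] <- des
  clusters
}

#' Write a cluster report and its labelled volume
#'
#' @param clusters A `cluster_set`.
#' @param dir Output directory.
#' @param compartment Compartment tag used in file names.
#' @return Invisibly, the written paths.
#' @export
write_cluster_set <- function(clusters, dir, compartment) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0("clusters_", compartment, ".csv"))
  nii <- file.path(dir, paste0("clusterlabels_", compartment, ".nii.gz"))
  utils::write.csv(clusters$clusters, csv, row.names = FALSE)
  write_volume(clusters$label_volume, nii, geometry = clusters$geometry,
               datatype = "int32")
  invisible(c(csv, nii))
}
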