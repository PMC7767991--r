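#' Run the full lesion-mapping pipeline
#'
#' Per compartment: build the two phenotype frequency atlases, compute the
#' voxel-wise two-tailed exact-test significance map, extract connected
#' components, calibrate the cluster-size threshold by random group
#' relabeling, flag surviving clusters, designate them against the atlases,
#' and localize them on the parcellation. All randomness flows from one seed,
#' split deterministically per compartment.
#'
#' @param config A list (or YAML/JSON file path) with fields:
#'   * `cohort`: a `mask_cohort`, or `cohort_dir` pointing at a
#'     [write_cohort()] layout, or `simulation` (a [simulation_config()] or
#'     argument list for one);
#'   * `parcellation`: a `parcellation_atlas`, or `parcellation_volume` /
#'     `parcellation_table` paths (defaults to the toy parcellation when
#'     simulating);
#'   * `compartments` (default both), `alpha_voxel` (0.05),
#'     `n_permutations` (500), `connectivity` (26), `cluster_alpha` (0.05),
#'     `seed` (1), `out_dir` (optional: write volumes/CSVs/summary there).
#' @return A `pipeline_result` list: per compartment the atlases, p-value
#'   map, corrected `cluster_set`, `permutation_null`, localization report;
#'   plus a `summary` list (written as `summary.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)  # yaml::read_yaml also parses JSON
  }
  cfg <- utils::modifyList(
    list(compartments = c("enhancing", "peri_lesional"), alpha_voxel = 0.05,
         n_permutations = 500L, connectivity = 26L, cluster_alpha = 0.05,
         seed = 1L, out_dir = NULL),
    config)
  if (!(cfg$alpha_voxel > 0 && cfg$alpha_voxel < 1) ||
      !(cfg$cluster_alpha > 0 && cfg$cluster_alpha < 1)) {
    stop("alpha levels must lie strictly in (0, 1)", call. = FALSE)
  }
  parcellation <- NULL
  if (!is.null(cfg$parcellation)) {
    parcellation <- cfg$parcellation
  } else if (!is.null(cfg$parcellation_volume)) {
    parcellation <- load_parcellation(cfg$parcellation_volume,
                                      cfg$parcellation_table)
  }
  if (!is.null(cfg$cohort)) {
    cohort <- cfg$cohort
  } else if (!is.null(cfg$cohort_dir)) {
    cohort <- read_cohort(cfg$cohort_dir)
  } else if (!is.null(cfg$simulation)) {
    sim_cfg <- cfg$simulation
    if (!inherits(sim_cfg, "simulation_config")) {
      sim_cfg <- do.call(simulation_config, sim_cfg)
    }
    sim <- simulate_cohort(sim_cfg, parcellation)
    cohort <- sim$cohort
    if (is.null(parcellation)) parcellation <- sim$parcellation
  } else {
    stop("config must provide `cohort`, `cohort_dir` or `simulation`",
         call. = FALSE)
  }
  if (is.null(parcellation)) {
    stop("config must provide a parcellation (or simulate one)",
         call. = FALSE)
  }
  stopifnot_same_geometry(cohort$geometry, parcellation$geometry,
                          "cohort and parcellation")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  results <- list()
  summary <- list(n_recurrence = cohort$n_recurrence,
                  n_psp = cohort$n_psp, seed = cfg$seed,
                  alpha_voxel = cfg$alpha_voxel,
                  n_permutations = cfg$n_permutations,
                  connectivity = cfg$connectivity,
                  compartments = list())
  for (ci in seq_along(cfg$compartments)) {
    comp <- cfg$compartments[ci]
    atlas_rec <- build_frequency_atlas(cohort, "recurrence", comp)
    atlas_psp <- build_frequency_atlas(cohort, "psp", comp)
    pmap <- adiffi_map(cohort, comp, alpha = cfg$alpha_voxel)
    clusters <- connected_components(pmap, connectivity = cfg$connectivity)
    null <- permutation_null(cohort, comp,
                             n_iterations = cfg$n_permutations,
                             alpha = cfg$alpha_voxel,
                             connectivity = cfg$connectivity,
                             seed = cfg$seed + 1000L * ci,
                             alpha_cluster = cfg$cluster_alpha)
    clusters <- apply_cluster_correction(clusters, null)
    clusters <- designate_clusters(clusters, atlas_rec, atlas_psp)
    report <- localize(clusters, parcellation, surviving_only = TRUE)
    results[[comp]] <- list(atlas_recurrence = atlas_rec,
                            atlas_psp = atlas_psp, pvalue_map = pmap,
                            clusters = clusters, null = null,
                            localization = report)
    surv <- clusters$clusters[clusters$clusters$survives_correction %in% TRUE,
                              , drop = FALSE]
    summary$compartments[[comp]] <- list(
      tested_voxels = sum(pmap$tested_mask),
      significant_voxels = sum(pmap$sig_mask),
      n_clusters = nrow(clusters$clusters),
      null_threshold_voxels = null$threshold_voxels,
      null_mean_max = null$mean_max, null_sd_max = null$sd_max,
      n_surviving = nrow(surv),
      surviving = lapply(seq_len(nrow(surv)), function(i) {
        list(cluster_id = surv$cluster_id[i],
             size_voxels = surv$size_voxels[i],
             designation = surv$designation[i])
      }),
      top_regions = {
        rs <- region_summary(report)
        do.call(rbind, lapply(split(rs, rs$group), utils::head, 3))
      })
    if (!is.null(out_dir)) {
      zmax <- max(atlas_rec$freq, atlas_psp$freq, 1e-12)
      export_overlay(atlas_rec,
                     file.path(out_dir, paste0("freq_recurrence_", comp)),
                     background = parcellation$labels, zlim = c(0, zmax))
      export_overlay(atlas_psp,
                     file.path(out_dir, paste0("freq_psp_", comp)),
                     background = parcellation$labels, zlim = c(0, zmax))
      write_pvalue_map(pmap, out_dir)
      write_cluster_set(clusters, out_dir, comp)
      utils::write.csv(
        data.frame(iteration = seq_along(null$max_cluster_sizes),
                   max_cluster_size = null$max_cluster_sizes),
        file.path(out_dir, paste0("null_maxima_", comp, ".csv")),
        row.names = FALSE)
      utils::write.csv(report,
                       file.path(out_dir, paste0("localization_", comp,
                                                 ".csv")),
                       row.names = FALSE)
      writeLines(describe_localization(report),
                 file.path(out_dir, paste0("report_", comp, ".txt")))
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(compartments = results, summary = summary,
                 parcellation = parcellation, cohort = cohort),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$summary$n_recurrence, " recurrence vs ",
      x$summary$n_psp, " psp\n", sep = "")
  for (comp in names(x$summary$compartments)) {
    s <- x$summary$compartments[[comp]]
    cat("  [", comp, "] ", s$significant_voxels, "/", s$tested_voxels,
        " significant voxels; threshold ", s$null_threshold_voxels,
        "; ", s$n_surviving, " surviving cluster(s)\n", sep = "")
  }
  invisible(x)
}

#' Welch two-sample comparison of clinical covariates
#'
#' Sanity report comparing each numeric covariate between the two phenotype
#' groups with Welch's unequal-variance t-test. Purely descriptive: never
#' gates the imaging pipeline. A covariate with zero variance in both groups
#' is reported as t = 0, p = 1 with a warning.
#'
#' @param table Data.frame or CSV path with a `group` column
#'   (`recurrence`/`psp`) and numeric or binary covariates.
#' @return Data.frame with `covariate`, `mean_recurrence`, `mean_psp`,
#'   `t_statistic`, `p_value`.
#' @export
compare_clinical_covariates <- function(table) {
  if (is.character(table)) table <- utils::read.csv(table,
                                                    stringsAsFactors = FALSE)
  if (!"group" %in% names(table)) {
    stop("covariate table must contain a `group` column", call. = FALSE)
  }
  g <- table$group
  if (!all(g %in% c("recurrence", "psp"))) {
    stop("group column must contain only 'recurrence' and 'psp'",
         call. = FALSE)
  }
  covs <- setdiff(names(table), "group")
  covs <- covs[vapply(table[covs], is.numeric, logical(1))]
  rows <- lapply(covs, function(v) {
    x <- table[[v]][g == "recurrence"]
    y <- table[[v]][g == "psp"]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      warning("covariate '", v, "' has zero variance in both groups",
              call. = FALSE)
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(x, y)  # Welch by default
    }
    data.frame(covariate = v, mean_recurrence = mean(x), mean_psp = mean(y),
               t_statistic = unname(tt$statistic),
               p_value = unname(tt$p.value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
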