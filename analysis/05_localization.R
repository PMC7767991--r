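#!/usr/bin/env Rscript
# Stage 5: anatomical localization of the surviving clusters.
#
# Surviving clusters' voxels are tallied over the labelled parcellation per
# phenotype, giving the per-region / per-hemisphere percentage breakdowns
# (e.g. "recurrence: 89% of significant voxels in the parietal lobe, mostly
# right"). Outputs CSV reports and a plain-text summary per compartment under
# results/localization/.

library(adiffi)

cohort <- read_cohort("results/cohort")
parc <- load_parcellation("results/cohort/parcellation.nii.gz",
                          "results/cohort/parcellation_labels.csv")
dir.create("results/localization", showWarnings = FALSE, recursive = TRUE)

for (comp in c("enhancing", "peri_lesional")) {
  # resume from the stage-4 artifacts: labelled clusters + their table
  lab_img <- read_mask(file.path("results/clusters",
                                 paste0("clusterlabels_", comp, ".nii.gz")),
                       comp)
  tab <- read.csv(file.path("results/clusters",
                            paste0("clusters_", comp, ".csv")))
  cs <- structure(list(geometry = lab_img$geometry,
                       label_volume = {
                         img <- RNifti::readNifti(file.path(
                           "results/clusters",
                           paste0("clusterlabels_", comp, ".nii.gz")))
                         array(as.integer(img), dim = dim(img))
                       },
                       clusters = tab), class = "cluster_set")
  rep <- localize(cs, parc, surviving_only = TRUE)
  write.csv(rep, file.path("results/localization",
                           paste0("localization_", comp, ".csv")),
            row.names = FALSE)
  txt <- describe_localization(rep)
  writeLines(txt, file.path("results/localization",
                            paste0("report_", comp, ".txt")))
  cat(sprintf("[%s]\n", comp))
  cat(paste0("  ", txt, collapse = "\n"), "\n")
}
cat("localization written to results/localization/\n")
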