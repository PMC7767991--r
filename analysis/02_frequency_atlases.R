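#!/usr/bin/env Rscript
# Stage 2: per-phenotype lesion frequency atlases ("population atlases").
#
# For each group and compartment, the atlas value at a voxel is the fraction
# of that group's subjects whose lesion covers it. The two groups share one
# colour scale per compartment so the heat maps are comparable. Outputs NIfTI
# volumes and axial PNG mosaics under results/atlases/.

library(adiffi)

cohort <- read_cohort("results/cohort")
parc <- load_parcellation("results/cohort/parcellation.nii.gz",
                          "results/cohort/parcellation_labels.csv")
dir.create("results/atlases", showWarnings = FALSE, recursive = TRUE)

for (comp in c("enhancing", "peri_lesional")) {
  ar <- build_frequency_atlas(cohort, "recurrence", comp)
  ap <- build_frequency_atlas(cohort, "psp", comp)
  zmax <- max(ar$freq, ap$freq)
  export_overlay(ar, file.path("results/atlases",
                               paste0("freq_recurrence_", comp)),
                 background = parc$labels, zlim = c(0, zmax))
  export_overlay(ap, file.path("results/atlases", paste0("freq_psp_", comp)),
                 background = parc$labels, zlim = c(0, zmax))
  cat(sprintf("[%s] peak frequency: recurrence %.2f, psp %.2f\n",
              comp, max(ar$freq), max(ap$freq)))
}
cat("atlases written to results/atlases/\n")
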