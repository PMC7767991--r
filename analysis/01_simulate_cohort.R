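#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 41 tumor-recurrence vs 33 pseudo-progression subjects on a 48x56x48 grid at
# 3 mm, two lesion compartments per subject (enhancing core + concentric
# peri-lesional hyperintensity). Recurrence lesions are planted in the right
# parietal block with probability 0.8; PsP lesions are multifocal over
# frontal/temporal/insula/putamen in both hemispheres. Writes the NIfTI masks,
# the cohort manifest and the toy parcellation under results/cohort/.

library(adiffi)

out <- "results/cohort"
cfg <- simulation_config(seed = 20260925L)
sim <- simulate_cohort(cfg)

write_cohort(sim, out)

cat("cohort: ", cfg$n_recurrence, "recurrence +", cfg$n_psp, "psp subjects\n")
cat("grid:   ", paste(cfg$grid_shape, collapse = " x "), "voxels at",
    cfg$voxel_size_mm, "mm\n")
cat("planted recurrence region label:", sim$truth$recurrence, "\n")
tot <- vapply(sim$cohort$masks, function(m) sum(m$data), numeric(1))
cat("median lesion size:",
    stats::median(tot[sim$cohort$compartments == "enhancing"]), "voxels (enhancing),",
    stats::median(tot[sim$cohort$compartments == "peri_lesional"]),
    "voxels (peri-lesional)\n")
cat("wrote", length(sim$cohort$masks), "masks +", "manifest to", out, "\n")
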