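#!/usr/bin/env Rscript
# Stage 3: voxel-wise differential involvement (exact-test significance maps).
#
# At every voxel with a lesion in at least one subject, a two-tailed Fisher's
# exact test compares lesion occurrence between the phenotypes; voxels with
# p < 0.05 form the uncorrected significance map, one per compartment.
# Outputs p-map / significance / tested-mask NIfTIs under results/adiffi/.

library(adiffi)

cohort <- read_cohort("results/cohort")

for (comp in c("enhancing", "peri_lesional")) {
  pm <- adiffi_map(cohort, comp, alpha = 0.05)
  write_pvalue_map(pm, "results/adiffi")
  cat(sprintf("[%s] %d voxels tested, %d significant at p < 0.05 (%.1f%%)\n",
              comp, sum(pm$tested_mask), sum(pm$sig_mask),
              100 * sum(pm$sig_mask) / max(1, sum(pm$tested_mask))))
}
cat("significance maps written to results/adiffi/\n")
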