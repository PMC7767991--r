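---
title: "Voxel-wise lesion mapping with exact tests and permutation cluster correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise lesion mapping with exact tests and permutation cluster correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiffi)
```

## The problem

After treatment for glioblastoma, a new enhancing lesion on follow-up MRI can
be either true tumor recurrence or pseudo-progression (PsP), a benign
radiation-induced change that mimics recurrence. The two entities demand
opposite management, yet routine imaging cannot reliably separate them. One
line of evidence is purely spatial: if the two phenotypes prefer different
brain locations, the lesion's position already carries diagnostic
information. This package implements the statistical machinery for that
question: it takes co-registered binary lesion masks from two patient
groups, quantifies where each phenotype's lesions occur, tests every voxel
for differential involvement, and reports which anatomical regions carry
statistically defensible group differences.

## The procedure

The pipeline has four stages, run independently for each lesion compartment
(the gadolinium-enhancing core, and the surrounding T2/FLAIR peri-lesional
hyperintensity).

**1. Population frequency atlases.** For each phenotype, the per-voxel mean
of the binary masks: `freq(v)` is the fraction of the group's subjects whose
lesion covers voxel `v`. These atlases summarize each phenotype's spatial
predilection and later serve to attribute significant clusters to one
phenotype.

**2. Voxel-wise exact tests.** At each voxel the cohort splits into a 2×2
table: `a`/`b` are the recurrence subjects with and without a lesion there,
`c`/`d` the PsP subjects. With all margins fixed, the first cell follows the
hypergeometric law

$$P(k) = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{k!\,(a+b-k)!\,(a+c-k)!\,(d-a+k)!\,n!},$$

and the two-tailed p-value sums \(P(k)\) over all feasible tables whose
point probability does not exceed the observed one (the "method of small
P"). We compute this in log space with `lgamma`, with a relative slack of
1e-7 in the comparison to absorb log-space rounding — the same convention
`stats::fisher.test` uses, which makes the two directly comparable (and we
test that they agree). Voxels with no lesion in any subject are not tested
and carry p = 1, so downstream clustering remains defined everywhere;
`tested_mask` records the distinction. Significance is strict: `p < alpha`
with `alpha = 0.05`.

Because group sizes are constant across the volume, a voxel's p-value
depends only on `(a, c)`. All maps are therefore computed through a
`(n_rec+1) × (n_psp+1)` lookup table (`fisher_p_table()`), which reduces
hundreds of thousands of voxel tests to at most a few thousand distinct
ones. A `memoize = FALSE` path evaluates each voxel directly; the two agree
bitwise and the equivalence is under test.

**3. Cluster-size correction by random permutation.** Voxel-wise testing at
alpha = 0.05 across tens of thousands of voxels needs multiplicity control.
Significant voxels are first grouped into connected components
(26-connectivity by default; 6 and 18 are available — the neighbourhood
choice is a genuine open point in this literature, so it is an explicit
argument rather than a constant). Then the subject-to-phenotype assignment
is randomly permuted, preserving group sizes; the significance map is
recomputed; and the size of the largest surviving component is recorded.
Over `n_iterations` (500 by default) these maxima form the null
distribution of the biggest cluster one can obtain by chance. The cluster
threshold is the empirical 95th percentile — the smallest attained value
covering at least 95% of the maxima (inverse ECDF, no interpolation, so the
threshold is an integer cluster size) — and a cluster survives only if it is
*strictly larger*. Iterations with no significant voxel contribute a
maximum of 0 rather than being discarded; discarding them would bias the
threshold upward. A pooled variant (percentile of all per-iteration cluster
sizes, not just maxima) is exposed via `statistic = "pooled"` for
comparison, but maxima-based control is the default because it is the
standard family-wise-error construction.

**4. Designation and localization.** Each surviving cluster is designated
recurrence or PsP by whichever population atlas has the higher mean
frequency over the cluster's voxels (exact ties are reported as
indeterminate). Designated voxels are then tallied over an integer-labelled
parcellation, yielding per-region, per-hemisphere percentage breakdowns
("89% of recurrence-attributed significant voxels fall in the parietal
lobe, almost all on the right"). Percentages are taken over each group's
significant voxels on labelled parcellation voxels; background-label voxels
are reported separately as `unlabeled` so region percentages always sum
to 100. Hemispheres follow the RAS+ convention (world x > 0 is right), with
a half-voxel midline band to avoid arbitrarily lateralizing voxels that sit
exactly on the midplane. The tally counts significant voxels; a
frequency-weighted alternative is available through the `weights` argument
of `localize()`.

## The synthetic cohort generator

No patient imaging ships with this package; a seed-controlled generator
produces cohorts with the spatial structure the method is meant to detect,
so every stage is testable end to end.

* **Toy parcellation.** An ellipsoidal "brain" (semi-axes 90% of the half
  field of view) is partitioned into 12 blocks: frontal, parietal, temporal
  and occipital lobes per hemisphere, plus deep insula and putamen blocks.
  The cut planes are placed so lobe volume fractions approximate real
  cerebral anatomy (frontal ≈ 40%, temporal ≈ 27%, parietal ≈ 18%,
  occipital ≈ 11%); an early version with equal-size octants made the
  parietal block twice its realistic share, which distorts any
  region-overlap measure computed against it.
* **Lesions.** Each subject's enhancing mask is the union of `focality`
  spheroidal blobs; a blob's centre falls inside the group's assigned region
  with probability `effect_strength`, otherwise uniformly anywhere
  in-brain, and is then jittered by isotropic Gaussian noise
  (`displacement_sd_mm`, default 4 mm). Radii are uniform on 10–20 mm,
  emulating 2–4 cm lesions; the peri-lesional mask is the concentric
  spheroid with radius scaled by 1.6, emulating the hyperintense rim around
  the core. Blobs are rasterized by voxel-centre inclusion and clipped to
  the brain. Defaults place recurrence (41 subjects, one blob each) in the
  right parietal block with `effect_strength = 0.8`, and PsP (33 subjects,
  three blobs each) multifocally across frontal/temporal/insula/putamen in
  *both* hemispheres, mirroring a lateralized-versus-multifocal contrast.
* **Null cohorts.** `simulate_null_cohort()` forces `effect_strength = 0`
  *and* equalizes the per-group focality. The second step matters: with one
  blob per recurrence subject and three per PsP subject, zero effect
  strength still leaves a real per-voxel lesion-rate difference between
  groups — a true signal, not a null. Exchangeability of the group labels
  is exactly what the permutation correction assumes, so the calibration
  cohorts must have it by construction.

What the generator does *not* emulate: registration error (masks are
perfectly aligned by construction), anatomically shaped lesions (blobs are
spheres, real lesions are not), mass effect, lesion-size/location
correlation, and intensity data of any kind. Passing tests therefore show
that the statistics behave correctly on aligned binary masks with planted
spatial structure — not that segmentation or registration upstream of this
package would succeed on real MRI.

## Numerical and design choices

* **Two-tailed rule.** "Two-tailed" for exact 2×2 tests is ambiguous in
  principle (small-P summation, tail doubling, mid-p). We use small-P
  summation, the dominant convention, which also enables an exact
  cross-check against `stats::fisher.test` and a brute-force enumeration
  oracle in the tests.
* **Strict inequalities.** Both the voxel rule (`p < 0.05`) and the cluster
  rule (`size > threshold`) are strict. At the cluster level this makes the
  threshold itself non-surviving — clusters of exactly the threshold size
  occur in ≥ 5% of permutations.
* **Affine tolerance.** Cohort assembly requires identical shapes and
  affines equal within 1e-4 mm per entry. The masks are supposed to be
  pre-registered to one grid; a looser tolerance would silently accept
  registration bugs, and resampling is deliberately out of scope.
* **Binarization.** Any strictly positive voxel value counts as lesion on
  read, which is robust to annotation tools writing labels other than 1.
* **Degenerate inputs.** Empty masks, empty groups, all-zero cohorts,
  zero-variance covariates and empty cluster sets all have defined,
  tested behaviour (p = 1 maps, composition errors, empty reports) rather
  than NaN propagation.
* **Determinism.** Every stochastic step (simulation, permutation) takes a
  seed and runs under `withr::with_seed`, so cohorts, null distributions
  and whole pipeline runs are bitwise reproducible; the pipeline splits one
  top-level seed deterministically per compartment.

## Problem sizes used in the tests

The default simulation grid is 48×56×48 at 3 mm rather than a 1 mm
whole-brain grid: it preserves the method's behaviour (tens of thousands of
tested voxels, clusters of thousands of voxels) while a full pipeline run
with 500 permutations completes in seconds. The test suite calibrates
family-wise error on 100 null cohorts of 20+20 subjects with 200
permutations each (plus a single 500-iteration spot check), checks
planted-effect recovery over 10 cohorts at full effect strength, and
verifies threshold stability between 200- and 1000-iteration runs; the
exact-test oracle sweep is exhaustive over all tables with n ≤ 30. These
sizes are the package's own trade-off between statistical resolution and a
test suite that runs in a few minutes.

## Known limitations

* The exact test treats voxels independently; spatial dependence is handled
  only at the cluster level, as in the underlying method.
* Cluster designation by atlas-mean comparison can attach a single merged
  cluster spanning both phenotypes' territory to one phenotype; with
  26-connectivity and dense lesion coverage, distinct foci can merge. At
  the default effect strength the recurrence cluster can hover near the
  survival threshold in some cohort draws — the analysis scripts report
  such near-misses explicitly.
* The toy parcellation has no interhemispheric fissure, so clusters can
  connect across the midline anywhere, which real cortical anatomy would
  mostly prevent.
* `compare_clinical_covariates()` is a descriptive Welch-t report, not part
  of the inferential pipeline.
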