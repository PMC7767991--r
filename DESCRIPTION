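Package: adiffi
Title: Voxel-Wise Lesion Mapping with Exact Tests and Permutation Cluster Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-phenotype voxel-wise lesion frequency atlases from
    co-registered binary lesion masks, computes voxel-wise two-tailed Fisher's
    exact-test significance maps (analysis of differential involvement, ADIFFI),
    corrects clusters of significant voxels by the 95th percentile of maximum
    cluster sizes under random group-relabeling permutations, and localizes
    surviving clusters to labeled anatomical regions with hemisphere splits.
    Includes a seed-controlled synthetic cohort generator (blob-like binary
    lesions on a toy lobar parcellation) so the full pipeline is testable
    without patient imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
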