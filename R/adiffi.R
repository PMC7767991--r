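#' Per-voxel 2x2 contingency count maps
#'
#' For one compartment, counts at every voxel how many subjects of each group
#' have a lesion there: `a` = recurrence lesion-positive, `c` = psp
#' lesion-positive; the complements `b = n_rec - a` and `d = n_psp - c` follow
#' from the fixed group sizes.
#'
#' @param cohort A `mask_cohort`.
#' @param compartment `"enhancing"` or `"peri_lesional"`.
#' @return List with 3D integer arrays `a`, `c`, scalars `n_rec`, `n_psp`
#'   (arrays `b`, `d` are implied and omitted to save memory).
#' @export
build_contingency_maps <- function(cohort,
                                   compartment = c("enhancing", "peri_lesional")) {
  compartment <- match.arg(compartment)
  cc <- cohort_compartment(cohort, compartment)
  shape <- cohort$geometry$shape
  a <- array(0L, shape)
  c_ <- array(0L, shape)
  for (i in seq_along(cc$masks)) {
    if (cc$labels[i] == "recurrence") a <- a + cc$masks[[i]]$data
    else c_ <- c_ + cc$masks[[i]]$data
  }
  n_rec <- sum(cc$labels == "recurrence")
  n_psp <- sum(cc$labels == "psp")
  if (n_rec == 0L || n_psp == 0L) {
    stop("composition error: compartment '", compartment,
         "' lacks one of the groups", call. = FALSE)
  }
  list(a = a, c = c_, n_rec = n_rec, n_psp = n_psp)
}

#' Voxel-wise differential-involvement significance map
#'
#' Runs the two-tailed Fisher's exact test at every voxel where at least one
#' subject has a lesion (`tested_mask`), comparing lesion occurrence between
#' recurrence and pseudo-progression. Untested voxels carry p = 1 so that
#' downstream clustering stays total.
#'
#' @param cohort A `mask_cohort`.
#' @param compartment Lesion compartment to analyse.
#' @param alpha Voxel-wise significance level; significant means strictly
#'   `p < alpha`.
#' @param memoize Use the shared `(a, c)` p-value lookup table (default). Set
#'   `FALSE` to call the test per voxel; results are bitwise identical.
#' @return A `pvalue_map` with fields `geometry`, `p` (3D array), `alpha`,
#'   `sig_mask`, `tested_mask` (3D 0/1 integer arrays), and the group sizes.
#' @export
adiffi_map <- function(cohort, compartment = c("enhancing", "peri_lesional"),
                       alpha = 0.05, memoize = TRUE) {
  compartment <- match.arg(compartment)
  if (!(alpha > 0 && alpha < 1)) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  cm <- build_contingency_maps(cohort, compartment)
  shape <- cohort$geometry$shape
  tested <- array(0L, shape)
  tested[cm$a + cm$c >= 1L] <- 1L
  p <- array(1, shape)
  idx <- which(tested == 1L)
  if (length(idx) > 0) {
    av <- cm$a[idx]; cv <- cm$c[idx]
    if (memoize) {
      pt <- fisher_p_table(cm$n_rec, cm$n_psp)
      p[idx] <- pt[cbind(av + 1L, cv + 1L)]
    } else {
      p[idx] <- mapply(function(a, c) {
        fisher_two_tailed(a, cm$n_rec - a, c, cm$n_psp - c)
      }, av, cv)
    }
  }
  sig <- array(0L, shape)
  sig[tested == 1L & p < alpha] <- 1L
  structure(
    list(geometry = cohort$geometry, compartment = compartment, p = p,
         alpha = alpha, sig_mask = sig, tested_mask = tested,
         n_rec = cm$n_rec, n_psp = cm$n_psp),
    class = "pvalue_map"
  )
}

#' @export
print.pvalue_map <- function(x, ...) {
  cat("<pvalue_map> [", x$compartment, "] ", sum(x$tested_mask),
      " tested voxels, ", sum(x$sig_mask), " significant at p < ", x$alpha,
      "\n", sep = "")
  invisible(x)
}

#' Write a significance map's volumes to NIfTI
#'
#' Writes `pmap_<compartment>.nii.gz`, `sigmask_<compartment>.nii.gz` and
#' `tested_<compartment>.nii.gz` under `dir`.
#'
#' @param x A `pvalue_map`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_pvalue_map <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(c("pmap_", "sigmask_", "tested_"),
                                 x$compartment, ".nii.gz"))
  write_volume(x$p, paths[1], geometry = x$geometry, datatype = "float")
  write_volume(x$sig_mask, paths[2], geometry = x$geometry, datatype = "uint8")
  write_volume(x$tested_mask, paths[3], geometry = x$geometry,
               datatype = "uint8")
  invisible(paths)
}
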