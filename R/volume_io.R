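#' Binary lesion mask
#'
#' Wraps a 3D array of 0/1 with its grid geometry, subject identifier and
#' lesion compartment (`"enhancing"` = gadolinium-enhancing core,
#' `"peri_lesional"` = surrounding T2/FLAIR hyperintensity).
#'
#' @param data 3D array; any strictly positive value is treated as lesion.
#' @param geometry A [grid_geometry()].
#' @param subject_id Character scalar.
#' @param compartment `"enhancing"` or `"peri_lesional"`.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, geometry, subject_id,
                        compartment = c("enhancing", "peri_lesional")) {
  compartment <- match.arg(compartment)
  if (length(dim(data)) != 3L) {
    stop("mask data must be a 3D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  }
  if (!identical(as.integer(dim(data)), geometry$shape)) {
    stop("mask shape does not match geometry shape", call. = FALSE)
  }
  bin <- array(0L, dim = dim(data))
  bin[data > 0] <- 1L
  structure(
    list(geometry = geometry, data = bin,
         subject_id = as.character(subject_id), compartment = compartment),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> subject ", x$subject_id, " [", x$compartment, "], ",
      sum(x$data), " lesion voxels on ",
      paste(x$geometry$shape, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Read a binary lesion mask from NIfTI
#'
#' Any strictly positive voxel becomes 1; zeros, negatives and NaN become 0.
#' This is robust to annotation tools writing label values other than 1.
#'
#' @param path A `.nii` or `.nii.gz` file.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param compartment Lesion compartment, see [binary_mask()].
#' @return A `binary_mask`.
#' @export
read_mask <- function(path, compartment = c("enhancing", "peri_lesional"),
                      subject_id = NULL) {
  compartment <- match.arg(compartment)
  if (!file.exists(path)) {
    stop("cannot read mask: file not found: ", path, call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img, dim = d[1:3])  # squeeze a trailing singleton
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("expected a 3D volume, got ", length(d), "D image in ", path,
         call. = FALSE)
  }
  geom <- grid_geometry(d, unclass(RNifti::xform(img)))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  arr <- as.array(img)
  arr[is.na(arr)] <- 0
  binary_mask(arr, geom, subject_id, compartment)
}

#' Write a binary mask (or any 3D volume) as NIfTI
#'
#' @param x A `binary_mask`, `frequency_atlas`, or a plain 3D array (then
#'   `geometry` is required).
#' @param path Output `.nii` or `.nii.gz` path.
#' @param geometry Required when `x` is a bare array.
#' @param datatype NIfTI storage type; masks default to `"uint8"`, real-valued
#'   volumes to `"float"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, geometry = NULL, datatype = NULL) {
  if (inherits(x, "binary_mask")) {
    arr <- x$data; geometry <- x$geometry
    if (is.null(datatype)) datatype <- "uint8"
  } else if (inherits(x, "frequency_atlas")) {
    arr <- x$freq; geometry <- x$geometry
    if (is.null(datatype)) datatype <- "float"
  } else {
    arr <- x
    if (is.null(geometry)) stop("`geometry` is required for bare arrays",
                                call. = FALSE)
    if (is.null(datatype)) {
      datatype <- if (is.integer(arr)) "int32" else "float"
    }
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, sqrt(colSums(geometry$affine[1:3, 1:3]^2)))
  img <- RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(geometry$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "binary_mask"))
  write_volume(x, path)
}

#' Assemble a cohort of aligned masks with group labels
#'
#' Validates that every mask shares one grid (shapes identical, affine entries
#' within 1e-4 mm) and that both phenotypes are represented. Subject order is
#' preserved exactly as given.
#'
#' @param masks List of `binary_mask` objects. A subject may contribute one
#'   mask per compartment; `(subject_id, compartment)` pairs must be unique.
#' @param labels Character vector, per mask, in `c("recurrence", "psp")`;
#'   a subject present with both compartments must carry one label.
#' @return A `mask_cohort` with fields `geometry`, `masks`, `labels`,
#'   `n_recurrence`, `n_psp` (counted over distinct subjects).
#' @export
assemble_cohort <- function(masks, labels) {
  if (length(masks) != length(labels)) {
    stop("`masks` and `labels` must have equal length", call. = FALSE)
  }
  if (length(masks) < 2L) {
    stop("a cohort needs at least 2 masks", call. = FALSE)
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("recurrence", "psp"))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  geom <- masks[[1]]$geometry
  for (m in masks) {
    if (!same_geometry(geom, m$geometry)) {
      stop("alignment error: mask for subject ", m$subject_id,
           " is not on the shared grid", call. = FALSE)
    }
  }
  ids <- vapply(masks, function(m) m$subject_id, character(1))
  comps <- vapply(masks, function(m) m$compartment, character(1))
  key <- paste(ids, comps, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, compartment) pair: ",
         ids[duplicated(key)][1], call. = FALSE)
  }
  subj_label <- tapply(labels, ids, function(v) unique(v))
  if (any(lengths(subj_label) > 1)) {
    stop("subject ", names(subj_label)[lengths(subj_label) > 1][1],
         " carries conflicting group labels", call. = FALSE)
  }
  subj_label <- vapply(subj_label, identity, character(1))
  n_rec <- sum(subj_label == "recurrence")
  n_psp <- sum(subj_label == "psp")
  if (n_rec == 0L || n_psp == 0L) {
    stop("composition error: both groups (recurrence, psp) must be present",
         call. = FALSE)
  }
  structure(
    list(geometry = geom, masks = masks, labels = labels,
         subject_ids = ids, compartments = comps,
         n_recurrence = n_rec, n_psp = n_psp),
    class = "mask_cohort"
  )
}

#' @export
print.mask_cohort <- function(x, ...) {
  cat("<mask_cohort> ", x$n_recurrence, " recurrence + ", x$n_psp,
      " psp subjects, compartments: ",
      paste(unique(x$compartments), collapse = ", "), ", grid ",
      paste(x$geometry$shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}

# Masks of one compartment, in input order, with their subject labels.
cohort_compartment <- function(cohort, compartment) {
  keep <- cohort$compartments == compartment
  if (!any(keep)) {
    stop("composition error: cohort has no '", compartment, "' masks",
         call. = FALSE)
  }
  list(masks = cohort$masks[keep], labels = cohort$labels[keep],
       subject_ids = cohort$subject_ids[keep])
}

# n_subjects x n_voxels 0/1 matrix for one compartment (voxels in array
# order). Row order follows cohort input order.
mask_matrix <- function(cohort, compartment) {
  cc <- cohort_compartment(cohort, compartment)
  nv <- prod(cohort$geometry$shape)
  m <- matrix(0L, length(cc$masks), nv)
  for (i in seq_along(cc$masks)) m[i, ] <- as.integer(cc$masks[[i]]$data)
  list(mat = m, labels = cc$labels, subject_ids = cc$subject_ids)
}

#' Load an integer-labelled anatomical parcellation
#'
#' @param volume_path NIfTI with non-negative integer labels (0 = background).
#' @param table_path CSV with header `label,region_name,hemisphere`;
#'   hemisphere must be one of `left`, `right`, `midline`.
#' @return A `parcellation_atlas` with fields `geometry`, `labels` (3D integer
#'   array) and `table` (data.frame).
#' @export
load_parcellation <- function(volume_path, table_path) {
  img <- RNifti::readNifti(volume_path)
  if (length(dim(img)) != 3L) {
    stop("parcellation volume must be 3D", call. = FALSE)
  }
  geom <- grid_geometry(dim(img), unclass(RNifti::xform(img)))
  lab <- array(as.integer(round(as.array(img))), dim = dim(img))
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  parcellation_atlas(lab, geom, tab)
}

#' Construct a parcellation atlas from in-memory pieces
#'
#' @param labels 3D array of non-negative integer labels.
#' @param geometry A [grid_geometry()].
#' @param table Data frame with columns `label`, `region_name`, `hemisphere`.
#' @return A `parcellation_atlas`.
#' @export
parcellation_atlas <- function(labels, geometry, table) {
  need <- c("label", "region_name", "hemisphere")
  if (!all(need %in% names(table))) {
    stop("parcellation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.integer(dim(labels)), geometry$shape)) {
    stop("parcellation label volume shape does not match geometry",
         call. = FALSE)
  }
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  bad_hemi <- setdiff(unique(table$hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi) > 0) {
    stop("invalid hemisphere value(s): ", paste(bad_hemi, collapse = ", "),
         "; allowed: left, right, midline", call. = FALSE)
  }
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, table$label)
  if (length(missing) > 0) {
    stop("label(s) present in volume but missing from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$label)) {
    stop("duplicate label in parcellation table", call. = FALSE)
  }
  structure(
    list(geometry = geometry,
         labels = array(as.integer(labels), dim = dim(labels)),
         table = as.data.frame(table)[, need]),
    class = "parcellation_atlas"
  )
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat("<parcellation_atlas> ", nrow(x$table), " regions on ",
      paste(x$geometry$shape, collapse = "x"), " grid, ",
      sum(x$labels > 0), " labelled voxels\n", sep = "")
  invisible(x)
}

#' Write a parcellation atlas (volume + label table)
#'
#' @param atlas A `parcellation_atlas`.
#' @param volume_path Output NIfTI path.
#' @param table_path Output CSV path.
#' @return Invisibly, the two paths.
#' @export
write_parcellation <- function(atlas, volume_path, table_path) {
  write_volume(atlas$labels, volume_path, geometry = atlas$geometry,
               datatype = "int32")
  utils::write.csv(atlas$table, table_path, row.names = FALSE, quote = FALSE)
  invisible(c(volume_path, table_path))
}
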