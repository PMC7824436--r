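#' Construct an image volume
#'
#' An `image_volume` is a 3-D scalar intensity array together with its voxel
#' spacing (mm) and 4x4 voxel-to-world affine. It is the common currency of
#' the preprocessing and segmentation stages.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param affine 4x4 voxel-to-world matrix; default diag(spacing) with zero
#'   origin.
#' @param meta free-form named list of header fields.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("expected 3-D volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine, meta = meta),
            class = "image_volume")
}

#' Construct a label map
#'
#' A `label_map` holds a 3-D non-negative integer array aligned to an image
#' grid; 0 is background. Nonzero labels are interpreted through a
#' [label_scheme()].
#'
#' @param labels 3-D integer array, values >= 0.
#' @param spacing,affine,meta as in [image_volume()].
#' @param scheme optional [label_scheme()] the labels refer to; when given,
#'   all nonzero values must appear in it.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), affine = NULL,
                      meta = list(), scheme = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("expected 3-D volume")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  vol <- image_volume(array(0, dim(labels)), spacing, affine, meta)
  obj <- structure(list(labels = labels, spacing = vol$spacing,
                        affine = vol$affine, meta = meta, scheme = scheme),
                   class = "label_map")
  if (!is.null(scheme)) check_labels_in_scheme(obj, scheme)
  obj
}

#' Construct a label scheme
#'
#' Maps integer labels to anatomical regions. Each entry gives the region
#' name and hemisphere; `icv_labels` names the label set whose union defines
#' intracranial volume (default: all nonzero labels).
#'
#' @param entries data.frame with columns `label` (integer, unique, > 0),
#'   `roi` (character) and `hemisphere` (one of "L", "R", NA).
#' @param icv_labels integer vector of labels defining ICV; default all.
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(entries, icv_labels = NULL) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("label", "roi", "hemisphere") %in% names(entries)))
  entries$label <- as.integer(entries$label)
  entries$roi <- as.character(entries$roi)
  entries$hemisphere <- as.character(entries$hemisphere)
  if (anyDuplicated(entries$label)) stop("duplicate labels in scheme")
  if (any(entries$label <= 0L)) stop("scheme labels must be positive")
  if (is.null(icv_labels)) icv_labels <- entries$label
  icv_labels <- as.integer(icv_labels)
  if (!all(icv_labels %in% entries$label))
    stop("icv_labels must be scheme labels")
  structure(list(entries = entries, icv_labels = icv_labels),
            class = "label_scheme")
}

#' The eight reported regions of interest
#' @return character vector of ROI names.
#' @export
roi_names <- function() {
  c("frontal", "parietal", "temporal", "occipital", "cingulate", "insula",
    "hippocampus", "lateral_ventricle")
}

#' Default 17-label scheme
#'
#' Eight regions x two hemispheres plus a remainder ("other") label covering
#' the rest of the intracranial volume. Labels 1..16 enumerate (roi,
#' hemisphere) pairs in [roi_names()] order (L before R); label 17 is
#' "other".
#'
#' @return A [label_scheme()].
#' @export
default_label_scheme <- function() {
  rois <- roi_names()
  entries <- data.frame(
    label = seq_len(17L),
    roi = c(rep(rois, each = 2L), "other"),
    hemisphere = c(rep(c("L", "R"), times = 8L), NA_character_)
  )
  label_scheme(entries)
}

#' Read a label scheme from CSV
#'
#' Expects columns `label,roi,hemisphere` and an optional logical `icv`
#' column marking the labels whose union defines intracranial volume.
#'
#' @param path CSV file path.
#' @return A [label_scheme()].
#' @export
read_label_scheme <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  icv <- if ("icv" %in% names(df)) df$label[as.logical(df$icv)] else NULL
  label_scheme(df[c("label", "roi", "hemisphere")], icv_labels = icv)
}

check_labels_in_scheme <- function(labelmap, scheme) {
  present <- sort(unique(as.vector(labelmap$labels)))
  present <- present[present != 0L]
  orphans <- setdiff(present, scheme$entries$label)
  if (length(orphans))
    stop("labels absent from scheme: ", paste(orphans, collapse = ", "))
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [image_volume()] or, when
#' `as_labels = TRUE`, a [label_map()]. Spacing and affine are taken from the
#' header.
#'
#' @param path NIfTI-1 file.
#' @param as_labels read as an integer label map.
#' @param scheme optional label scheme attached when `as_labels = TRUE`.
#' @return [image_volume()] or [label_map()].
#' @export
read_nifti <- function(path, as_labels = FALSE, scheme = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("expected 3-D volume")
  arr <- array(as.numeric(arr), dim(arr))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  meta <- list(header = RNifti::niftiHeader(img))
  if (as_labels) {
    label_map(round(arr), spacing = spacing, affine = affine, meta = meta,
              scheme = scheme)
  } else {
    image_volume(arr, spacing = spacing, affine = affine, meta = meta)
  }
}

#' Write a volume or label map to NIfTI-1
#'
#' Integer label maps round-trip bit-exactly (written as int16 when the
#' maximum label allows, int32 otherwise); image volumes are written as
#' float32 by default or float64 when `precision = "double"`.
#'
#' @param volume [image_volume()] or [label_map()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param precision `"float"` or `"double"` for image volumes.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, precision = c("double", "float")) {
  precision <- match.arg(precision)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("path must end in .nii or .nii.gz")
  if (inherits(volume, "label_map")) {
    arr <- volume$labels
    dt <- if (max(arr) <= 32767L) "int16" else "int32"
  } else if (inherits(volume, "image_volume")) {
    arr <- volume$data
    dt <- if (precision == "double") "double" else "float"
  } else stop("expected image_volume or label_map")
  img <- RNifti::asNifti(arr, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Per-region volumes from a label map
#'
#' For every (roi, hemisphere) of the scheme, volume in mL is the voxel
#' count times the voxel volume (product of spacings, mm^3) / 1000, computed
#' on the label map's own grid. An `icv` row reports the union of the
#' scheme's `icv_labels`.
#'
#' @param labelmap [label_map()].
#' @param scheme [label_scheme()]; defaults to the map's own scheme.
#' @param subject_id,site_id,visit_id identifiers copied into the table.
#' @return data.frame with columns
#'   `subject_id,site_id,visit_id,roi,hemisphere,volume_ml` (one row per
#'   scheme (roi, hemisphere) plus one `icv` row).
#' @export
compute_roi_volumes <- function(labelmap, scheme = labelmap$scheme,
                                subject_id = "subj", site_id = "site",
                                visit_id = "v1") {
  if (is.null(scheme)) stop("no label scheme available")
  check_labels_in_scheme(labelmap, scheme)
  vox_ml <- prod(labelmap$spacing) / 1000
  counts <- tabulate(labelmap$labels + 1L,
                     nbins = max(scheme$entries$label) + 1L)[-1]
  ent <- scheme$entries
  grp <- paste(ent$roi, ifelse(is.na(ent$hemisphere), "NA", ent$hemisphere))
  agg <- rowsum(counts[ent$label], grp)
  key <- unique(data.frame(roi = ent$roi, hemisphere = ent$hemisphere,
                           grp = grp, stringsAsFactors = FALSE))
  key <- key[match(rownames(agg), key$grp), ]
  out <- data.frame(subject_id = subject_id, site_id = site_id,
                    visit_id = visit_id, roi = key$roi,
                    hemisphere = key$hemisphere,
                    volume_ml = as.numeric(agg) * vox_ml,
                    stringsAsFactors = FALSE)
  icv_count <- sum(counts[scheme$icv_labels])
  out <- rbind(out, data.frame(subject_id = subject_id, site_id = site_id,
                               visit_id = visit_id, roi = "icv",
                               hemisphere = NA_character_,
                               volume_ml = icv_count * vox_ml))
  rownames(out) <- NULL
  out
}

#' Aggregate fine labels into one label per (roi, hemisphere)
#'
#' Maps every fine label of `labelmap` to a coarse label indexed by its
#' (roi, hemisphere) group in `scheme`; voxel counts are conserved within
#' each group. The returned map carries a coarse scheme with one entry per
#' group.
#'
#' @param labelmap fine-grained [label_map()].
#' @param scheme [label_scheme()] covering every nonzero label present.
#' @return A coarse [label_map()].
#' @export
aggregate_labels <- function(labelmap, scheme) {
  check_labels_in_scheme(labelmap, scheme)
  ent <- scheme$entries
  grp <- paste(ent$roi, ifelse(is.na(ent$hemisphere), "NA", ent$hemisphere))
  ugrp <- unique(grp)
  coarse_of_fine <- integer(max(ent$label))
  coarse_of_fine[ent$label] <- match(grp, ugrp)
  lut <- c(0L, coarse_of_fine)  # index by label + 1
  coarse <- array(lut[labelmap$labels + 1L], dim(labelmap$labels))
  first <- !duplicated(grp)
  coarse_scheme <- label_scheme(data.frame(
    label = match(grp, ugrp)[first],
    roi = ent$roi[first], hemisphere = ent$hemisphere[first]))
  label_map(coarse, spacing = labelmap$spacing, affine = labelmap$affine,
            meta = labelmap$meta, scheme = coarse_scheme)
}

#' Write / read an ROI volume table
#'
#' Long-format per-subject/site/visit region volumes with header
#' `subject_id,site_id,visit_id,roi,hemisphere,volume_ml`.
#'
#' @param table data.frame as produced by [compute_roi_volumes()].
#' @param path CSV path.
#' @return `path` / the validated data.frame.
#' @export
write_roi_table <- function(table, path) {
  write.csv(validate_roi_table(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character",
                                site_id = "character",
                                visit_id = "character"))
  df$hemisphere[!is.na(df$hemisphere) & df$hemisphere == ""] <- NA_character_
  validate_roi_table(df)
}

validate_roi_table <- function(df) {
  need <- c("subject_id", "site_id", "visit_id", "roi", "hemisphere",
            "volume_ml")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns ", paste(need, collapse = ","))
  if (any(df$volume_ml < 0, na.rm = TRUE)) stop("negative volume")
  key <- do.call(paste, df[c("subject_id", "site_id", "visit_id", "roi",
                             "hemisphere")])
  if (anyDuplicated(key)) stop("duplicate (subject, site, visit, roi, hemisphere) rows")
  df
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume", paste(dim(x$data), collapse = "x"),
      "spacing", paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  cat("label_map", paste(dim(x$labels), collapse = "x"),
      "spacing", paste(signif(x$spacing, 4), collapse = "x"), "mm;",
      length(setdiff(labs, 0L)), "labels\n")
  invisible(x)
}
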