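#' Preprocessing configuration
#'
#' @param target_spacing isotropic target voxel size in mm.
#' @param pad_multiple_train,pad_multiple_test grid multiples the padded
#'   shape must reach for training (16) and inference (24); both must divide
#'   cleanly through the encoder's pooling levels.
#' @param landmark_percentiles percentiles (strictly increasing, in (0,100))
#'   used as intensity landmarks for histogram matching.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = 1.0,
                              pad_multiple_train = 16L,
                              pad_multiple_test = 24L,
                              landmark_percentiles = c(1, seq(10, 90, 10), 99)) {
  stopifnot(target_spacing > 0, pad_multiple_train > 0, pad_multiple_test > 0)
  p <- as.numeric(landmark_percentiles)
  if (any(diff(p) <= 0) || any(p <= 0) || any(p >= 100))
    stop("landmark percentiles must be strictly increasing in (0, 100)")
  structure(list(target_spacing = target_spacing,
                 pad_multiple_train = as.integer(pad_multiple_train),
                 pad_multiple_test = as.integer(pad_multiple_test),
                 landmark_percentiles = p),
            class = "preprocess_config")
}

#' Resample a volume to an isotropic grid
#'
#' Voxel centers are mapped through physical space; intensities use
#' trilinear interpolation, label maps nearest-neighbor. When the input is
#' already at the target spacing the data are returned unchanged.
#'
#' @param volume [image_volume()] or [label_map()].
#' @param target_spacing isotropic voxel size in mm (> 0).
#' @param interpolation `"linear"` (intensities) or `"nearest"` (labels);
#'   chosen automatically from the input class by default.
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(volume, target_spacing = 1.0,
                               interpolation = NULL) {
  if (target_spacing <= 0) stop("target spacing must be positive")
  is_lab <- inherits(volume, "label_map")
  if (is.null(interpolation)) interpolation <- if (is_lab) "nearest" else "linear"
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (is_lab && interpolation != "nearest")
    stop("label maps must be resampled with nearest-neighbor interpolation")
  arr <- if (is_lab) volume$labels else volume$data
  sp <- volume$spacing
  if (all(abs(sp - target_spacing) < 1e-9)) return(volume)
  dout <- as.integer(pmax(1L, round(dim(arr) * sp / target_spacing)))
  scale <- target_spacing / sp
  res <- cpp_resample3d(arr + 0, dout, scale, if (interpolation == "nearest") 0L else 1L)
  # new affine: voxel axes rescaled, origin shifted so voxel centers map
  # consistently ((out + 0.5) * scale - 0.5 in input voxel coordinates)
  aff <- volume$affine
  S <- diag(c(scale, 1))
  shift <- aff[1:3, 1:3] %*% matrix((scale - 1) / 2, 3)
  aff2 <- aff %*% S
  aff2[1:3, 4] <- aff[1:3, 4] + shift
  if (is_lab) {
    label_map(res, spacing = rep(target_spacing, 3), affine = aff2,
              meta = volume$meta, scheme = volume$scheme)
  } else {
    image_volume(res, spacing = rep(target_spacing, 3), affine = aff2,
                 meta = volume$meta)
  }
}

#' Zero-pad each axis up to the next multiple
#'
#' Pads symmetrically (extra voxel on the high side when the total pad is
#' odd) so each axis becomes the next multiple of `multiple`. The returned
#' `crop_record` inverts the padding exactly via [crop_to_record()].
#'
#' @param volume [image_volume()] or [label_map()].
#' @param multiple positive integer grid multiple (16 for training grids,
#'   24 for inference grids).
#' @return list `(volume, crop_record)`; `crop_record` holds per-axis
#'   `lo`/`hi` pad widths, the original dims, and the original affine.
#' @export
zero_pad <- function(volume, multiple) {
  multiple <- as.integer(multiple)
  if (multiple <= 0L) stop("multiple must be positive")
  is_lab <- inherits(volume, "label_map")
  arr <- if (is_lab) volume$labels else volume$data
  d <- dim(arr)
  target <- ceiling(d / multiple) * multiple
  padtot <- target - d
  lo <- padtot %/% 2L
  hi <- padtot - lo
  out <- array(if (is_lab) 0L else 0, target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- arr
  aff <- volume$affine
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% lo
  rec <- list(lo = lo, hi = hi, dim = d, affine = volume$affine)
  vol2 <- if (is_lab) {
    label_map(out, volume$spacing, aff, volume$meta, volume$scheme)
  } else {
    image_volume(out, volume$spacing, aff, volume$meta)
  }
  list(volume = vol2, crop_record = rec)
}

#' Invert [zero_pad()]
#' @param volume padded volume.
#' @param crop_record record returned by [zero_pad()].
#' @return the unpadded volume with its original affine.
#' @export
crop_to_record <- function(volume, crop_record) {
  is_lab <- inherits(volume, "label_map")
  arr <- if (is_lab) volume$labels else volume$data
  r <- crop_record
  if (!all(dim(arr) == r$dim + r$lo + r$hi)) stop("crop record does not match volume")
  out <- arr[r$lo[1] + seq_len(r$dim[1]), r$lo[2] + seq_len(r$dim[2]),
             r$lo[3] + seq_len(r$dim[3]), drop = FALSE]
  if (is_lab) {
    label_map(out, volume$spacing, r$affine, volume$meta, volume$scheme)
  } else {
    image_volume(out, volume$spacing, r$affine, volume$meta)
  }
}

volume_landmarks <- function(volume, percentiles) {
  x <- as.vector(volume$data)
  # foreground = intensities above the volume mean. On MRI-like bimodal
  # volumes the mean falls in the background/tissue intensity gap, so the
  # selected voxel set is identical before and after the monotone
  # intensity map (exact idempotence) and the landmarks stay inside the
  # tissue range, away from the unstable background/tissue jump.
  fg <- x[x > mean(x)]
  if (!length(fg)) fg <- x
  # type-1 (order-statistic) quantiles: a monotone intensity map carries
  # each landmark exactly onto the mapped order statistic, so matching is
  # exactly idempotent rather than idempotent up to interpolation error
  as.numeric(quantile(fg, percentiles / 100, names = FALSE, type = 1))
}

#' Fit cohort reference landmarks for histogram matching
#'
#' Landmark-based intensity standardization: for each volume the stated
#' percentiles of the foreground intensities (foreground = above the volume
#' mean, which on MRI-like bimodal volumes falls in the background/tissue
#' gap) are extracted, and the reference is their per-percentile mean over
#' the cohort.
#'
#' @param volumes list of [image_volume()] (length >= 1).
#' @param percentiles landmark percentiles.
#' @return object of class `reference_landmarks`: list with `percentiles`
#'   and `values` (non-decreasing).
#' @export
fit_reference_landmarks <- function(volumes,
                                    percentiles = preprocess_config()$landmark_percentiles) {
  if (inherits(volumes, "image_volume")) volumes <- list(volumes)
  if (!length(volumes)) stop("need at least one volume")
  lm <- vapply(volumes, volume_landmarks, numeric(length(percentiles)),
               percentiles = percentiles)
  vals <- rowMeans(matrix(lm, nrow = length(percentiles)))
  structure(list(percentiles = percentiles, values = vals),
            class = "reference_landmarks")
}

#' Histogram-match a volume to reference landmarks
#'
#' Piecewise-linear intensity standardization: the volume's own foreground
#' landmarks are mapped onto the reference landmarks, with linear
#' extrapolation beyond the outermost landmarks. The mapping is monotone
#' non-decreasing, so intensity order is preserved. A constant (degenerate)
#' volume is returned unchanged with a warning.
#'
#' @param volume [image_volume()].
#' @param reference [fit_reference_landmarks()] output.
#' @return intensity-standardized [image_volume()].
#' @export
histogram_match <- function(volume, reference) {
  stopifnot(inherits(reference, "reference_landmarks"))
  src <- volume_landmarks(volume, reference$percentiles)
  if (diff(range(volume$data)) == 0 || diff(range(src)) == 0) {
    warning("degenerate (constant) volume; identity mapping")
    return(volume)
  }
  ref <- reference$values
  # collapse ties in the source landmarks so approx() has unique knots
  keep <- !duplicated(src)
  src_u <- src[keep]; ref_u <- ref[keep]
  x <- as.vector(volume$data)
  y <- approx(src_u, ref_u, xout = x, rule = 2)$y
  n <- length(src_u)
  if (n >= 2) {
    slope_lo <- (ref_u[2] - ref_u[1]) / (src_u[2] - src_u[1])
    slope_hi <- (ref_u[n] - ref_u[n - 1]) / (src_u[n] - src_u[n - 1])
    below <- x < src_u[1]
    above <- x > src_u[n]
    y[below] <- ref_u[1] + slope_lo * (x[below] - src_u[1])
    y[above] <- ref_u[n] + slope_hi * (x[above] - src_u[n])
  }
  image_volume(array(y, dim(volume$data)), volume$spacing, volume$affine,
               volume$meta)
}

#' Full preprocessing chain for one volume
#'
#' Resample to the isotropic target grid, histogram-match to the reference
#' (intensities only), and zero-pad to the requested grid multiple.
#'
#' @param volume [image_volume()] or [label_map()].
#' @param config [preprocess_config()].
#' @param reference [fit_reference_landmarks()] output or `NULL` to skip
#'   intensity standardization.
#' @param mode `"train"` (pad multiple 16) or `"test"` (24).
#' @return list `(volume, crop_record)`.
#' @export
preprocess_volume <- function(volume, config = preprocess_config(),
                              reference = NULL, mode = c("test", "train")) {
  mode <- match.arg(mode)
  v <- resample_isotropic(volume, config$target_spacing)
  if (!is.null(reference) && inherits(v, "image_volume"))
    v <- histogram_match(v, reference)
  mult <- if (mode == "train") config$pad_multiple_train else config$pad_multiple_test
  zero_pad(v, mult)
}
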