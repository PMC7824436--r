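#' Patch sampling / tiling specification
#'
#' @param size cubic patch edge in voxels (default 96).
#' @param overlap voxels of overlap between adjacent sliding windows
#'   (default 16); stride = size - overlap.
#' @param sampling only `"uniform"` is defined.
#' @return list of class `patch_spec`.
#' @export
patch_spec <- function(size = 96L, overlap = 16L, sampling = "uniform") {
  size <- as.integer(size); overlap <- as.integer(overlap)
  stride <- size - overlap
  if (stride <= 0L || stride > size) stop("need 0 < stride <= size")
  sampling <- match.arg(sampling, "uniform")
  structure(list(size = size, overlap = overlap, stride = stride,
                 sampling = sampling), class = "patch_spec")
}

#' Dataset split specification
#'
#' @param n_test_holdout scans set aside for testing before the
#'   train/validation split.
#' @param train_val_ratio ratio splitting the remainder (default 9.5:0.5).
#' @param seed shuffle seed.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(n_test_holdout = 49L, train_val_ratio = c(9.5, 0.5),
                       seed = 1L) {
  stopifnot(n_test_holdout >= 0L, length(train_val_ratio) == 2L,
            all(train_val_ratio > 0))
  structure(list(n_test_holdout = as.integer(n_test_holdout),
                 train_val_ratio = train_val_ratio, seed = as.integer(seed)),
            class = "split_spec")
}

#' Uniformly sample co-located training patch pairs
#'
#' Patch origins are drawn uniformly over all valid origins; the image and
#' label patches share each origin. Reproducible by seed.
#'
#' @param volume [image_volume()].
#' @param labelmap [label_map()] on the same grid.
#' @param spec [patch_spec()].
#' @param n number of patches.
#' @param seed RNG seed.
#' @return list of `list(image, labels, origin)` (origin is the 1-based
#'   corner voxel index).
#' @export
sample_training_patches <- function(volume, labelmap, spec, n, seed = 1L) {
  stopifnot(inherits(spec, "patch_spec"))
  d <- dim(volume$data)
  if (!all(dim(labelmap$labels) == d)) stop("image/label grid mismatch")
  if (any(d < spec$size)) stop("volume smaller than patch size")
  set.seed(seed)
  nvalid <- d - spec$size + 1L
  lapply(seq_len(n), function(i) {
    o <- vapply(nvalid, function(m) sample.int(m, 1L), integer(1))
    ix <- lapply(1:3, function(a) o[a] + seq_len(spec$size) - 1L)
    list(image = volume$data[ix[[1]], ix[[2]], ix[[3]]],
         labels = labelmap$labels[ix[[1]], ix[[2]], ix[[3]]],
         origin = o)
  })
}

#' Split scan ids into train / validation / test
#'
#' Shuffles the ids, sets aside `n_test_holdout` for testing, and splits the
#' remainder by the train:validation ratio (validation size rounded to the
#' nearest integer).
#'
#' @param ids unique identifiers.
#' @param spec [split_spec()].
#' @return list `(train, val, test)`; disjoint and exhaustive.
#' @export
split_dataset <- function(ids, spec = split_spec()) {
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (spec$n_test_holdout >= length(ids)) stop("holdout >= dataset size")
  set.seed(spec$seed)
  ids <- sample(ids)
  test <- head(ids, spec$n_test_holdout)
  rest <- setdiff(ids, test)
  frac_val <- spec$train_val_ratio[2] / sum(spec$train_val_ratio)
  n_val <- round(length(rest) * frac_val)
  val <- head(rest, n_val)
  train <- setdiff(rest, val)
  list(train = train, val = val, test = test)
}

window_starts <- function(n, size, stride) {
  if (size >= n) return(1L)
  s <- seq.int(1L, n - size + 1L, by = stride)
  if (tail(s, 1L) != n - size + 1L) s <- c(s, n - size + 1L)
  s
}

#' Sliding-window whole-volume segmentation
#'
#' Overlapping windows tile the (preprocessed, padded) volume with the last
#' window snapped to the boundary; per-voxel class probabilities are
#' blended over all covering windows and the argmax (ties to the lowest
#' label id) gives the label. Label value k corresponds to class k of the
#' model (0 = background).
#'
#' Blending is center-weighted by default (`weighting = "gaussian"`, sigma
#' = size/4): predictions near a window border are computed with truncated
#' spatial context (the convolutions see zero padding there), so windows
#' whose center is closer to a voxel are more trustworthy for it. Uniform
#' averaging is available via `weighting = "uniform"`.
#'
#' @param model trained [build_model()] output.
#' @param volume preprocessed [image_volume()].
#' @param spec [patch_spec()].
#' @param head supervision head passed to [predict_patch()].
#' @param scheme optional [label_scheme()] attached to the result.
#' @param weighting `"gaussian"` (default) or `"uniform"` window blending.
#' @param blend combine window outputs on the probability scale (`"mean"`,
#'   arithmetic) or the log-probability scale (`"logmean"`, a weighted
#'   geometric mean / product-of-experts, which lets confident
#'   well-centered windows outvote uncertain border predictions).
#' @return [label_map()] on the input grid.
#' @export
sliding_window_segment <- function(model, volume, spec = patch_spec(),
                                   head = "last", scheme = NULL,
                                   weighting = c("gaussian", "uniform"),
                                   blend = c("mean", "logmean")) {
  weighting <- match.arg(weighting)
  blend <- match.arg(blend)
  d <- dim(volume$data)
  K <- model$config$n_labels
  if (any(d < spec$size))
    stop("volume smaller than window; pad first")
  wwin <- if (weighting == "gaussian") {
    ax <- exp(-((seq_len(spec$size) - (spec$size + 1) / 2)^2) /
                (2 * (spec$size / 4)^2))
    outer(outer(ax, ax), ax)
  } else {
    array(1, rep(spec$size, 3))
  }
  acc <- array(0, c(d, K))
  cnt <- array(0, d)
  sx <- window_starts(d[1], spec$size, spec$stride)
  sy <- window_starts(d[2], spec$size, spec$stride)
  sz <- window_starts(d[3], spec$size, spec$stride)
  for (ox in sx) for (oy in sy) for (oz in sz) {
    ix <- ox + seq_len(spec$size) - 1L
    iy <- oy + seq_len(spec$size) - 1L
    iz <- oz + seq_len(spec$size) - 1L
    probs <- predict_patch(model, volume$data[ix, iy, iz], head = head)
    if (blend == "logmean") probs <- log(pmax(probs, 1e-12))
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] +
      array(as.vector(wwin) * matrix(probs, ncol = K), dim(probs))
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + wwin
  }
  if (any(cnt == 0)) stop("internal error: uncovered voxels")
  pm <- matrix(acc, ncol = K) / as.vector(cnt)
  lab <- array(max.col(pm, ties.method = "first") - 1L, d)
  label_map(lab, volume$spacing, volume$affine, volume$meta, scheme)
}

#' Keep only the largest connected component per label
#'
#' For every nonzero label, all but its largest connected component
#' (26-connectivity by default) are reassigned to background. Equal-sized
#' components are broken deterministically by keeping the component that
#' contains the smallest linear voxel index.
#'
#' @param labelmap [label_map()].
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @return filtered [label_map()].
#' @export
connected_component_filter <- function(labelmap, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  lab <- labelmap$labels
  out <- lab
  for (l in setdiff(sort(unique(as.vector(lab))), 0L)) {
    mask <- array(as.integer(lab == l), dim(lab))
    comp <- cpp_label_components(mask, dim(lab), connectivity)
    ncomp <- max(comp)
    if (ncomp <= 1L) next
    counts <- tabulate(comp[comp > 0L], nbins = ncomp)
    # components are numbered by smallest linear index, so which.max's
    # first-winner rule implements the documented tie-break
    keep <- which.max(counts)
    out[lab == l & comp != keep] <- 0L
  }
  label_map(out, labelmap$spacing, labelmap$affine, labelmap$meta,
            labelmap$scheme)
}

#' Map a segmentation back to the original acquisition grid
#'
#' Inverts the preprocessing pad via `crop_record`, then resamples the
#' labels onto the original volume's grid with nearest-neighbor
#' interpolation (which cannot invent labels). Volumes reported downstream
#' are computed on this grid.
#'
#' @param labelmap_iso [label_map()] in the preprocessed (isotropic,
#'   padded) space.
#' @param original_volume the original [image_volume()] defining the target
#'   grid.
#' @param crop_record pad record from [zero_pad()]/[preprocess_volume()];
#'   `NULL` if no padding was applied.
#' @return [label_map()] aligned to the original grid and affine.
#' @export
to_original_space <- function(labelmap_iso, original_volume,
                              crop_record = NULL) {
  lm <- labelmap_iso
  if (!is.null(crop_record)) lm <- crop_to_record(lm, crop_record)
  dout <- dim(original_volume$data)
  if (all(dout == dim(lm$labels)) &&
      all(abs(original_volume$spacing - lm$spacing) < 1e-9)) {
    return(label_map(lm$labels, original_volume$spacing,
                     original_volume$affine, original_volume$meta,
                     lm$scheme))
  }
  scale <- original_volume$spacing / lm$spacing
  res <- cpp_resample3d(lm$labels + 0, as.integer(dout), scale, 0L)
  label_map(res, original_volume$spacing, original_volume$affine,
            original_volume$meta, lm$scheme)
}
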