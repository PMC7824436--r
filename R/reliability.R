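#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)` between the voxels carrying `label` in two label
#' maps on the same grid. Two empty masks are defined as Dice 1 (with a
#' warning).
#'
#' @param a,b [label_map()] objects (or plain arrays) on identical grids.
#' @param label the label compared (default: any nonzero voxel).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b, label = NULL) {
  A <- if (inherits(a, "label_map")) a$labels else as.array(a)
  B <- if (inherits(b, "label_map")) b$labels else as.array(b)
  if (!all(dim(A) == dim(B))) stop("grid mismatch")
  ma <- if (is.null(label)) A != 0L else A == label
  mb <- if (is.null(label)) B != 0L else B == label
  denom <- sum(ma) + sum(mb)
  if (denom == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(ma & mb) / denom
}

#' Measurement matrix for repeated volume measurements
#'
#' @param values numeric n_subjects x k_raters matrix (complete, no NA).
#' @param subject_ids,rater_ids optional dimension names (raters are sites
#'   or visits).
#' @return matrix of class `measurement_matrix`.
#' @export
measurement_matrix <- function(values, subject_ids = NULL, rater_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 subjects and 2 raters")
  if (any(!is.finite(values))) stop("incomplete design: missing cells")
  if (!is.null(subject_ids)) rownames(values) <- subject_ids
  if (!is.null(rater_ids)) colnames(values) <- rater_ids
  class(values) <- c("measurement_matrix", class(values))
  values
}

# Two-way ANOVA mean squares of a complete subjects x raters matrix.
icc_mean_squares <- function(x) {
  x <- unclass(as.matrix(x))
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(n = n, k = k, msr = msr, msc = msc, mse = mse,
       sstot = sum((x - g)^2))
}

icc_result <- function(icc, model, n, k, cutoff = 0.75) {
  structure(list(icc = icc, model = model, n = n, k = k,
                 reliable = is.finite(icc) && icc >= cutoff,
                 cutoff = cutoff),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, single rater) = %.4f  [n=%d, k=%d] %s\n",
              x$model, x$icc, x$n, x$k,
              if (x$reliable) sprintf("reliable (>= %.2f)", x$cutoff)
              else sprintf("below %.2f", x$cutoff)))
  invisible(x)
}

#' Two-way single-rater intraclass correlation, consistency
#'
#' ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E), from the two-way ANOVA
#' mean squares of a complete subjects x raters matrix. Systematic rater
#' offsets are absorbed by the column effect and do not reduce consistency.
#' Used for test-retest designs (visits as raters).
#'
#' @param matrix [measurement_matrix()] or plain n x k matrix.
#' @param cutoff reliability flag threshold (default 0.75).
#' @return `icc_result` with fields `icc`, `model`, `n`, `k`, `reliable`.
#' @export
icc_consistency <- function(matrix, cutoff = 0.75) {
  if (!inherits(matrix, "measurement_matrix"))
    matrix <- measurement_matrix(matrix)
  ms <- icc_mean_squares(matrix)
  if (ms$sstot <= 0) stop("zero total variance; ICC undefined")
  icc <- (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
  icc_result(icc, "consistency", ms$n, ms$k, cutoff)
}

#' Two-way single-rater intraclass correlation, absolute agreement
#'
#' ICC(A,1) = (MS_R - MS_E) /
#' (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)). Rater (site) variance is
#' penalized, so agreement <= consistency whenever MS_C >= MS_E. Used for
#' multi-site designs (sites as raters).
#'
#' @inheritParams icc_consistency
#' @return `icc_result`.
#' @export
icc_agreement <- function(matrix, cutoff = 0.75) {
  if (!inherits(matrix, "measurement_matrix"))
    matrix <- measurement_matrix(matrix)
  ms <- icc_mean_squares(matrix)
  if (ms$sstot <= 0) stop("zero total variance; ICC undefined")
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse))
  icc_result(icc, "agreement", ms$n, ms$k, cutoff)
}

#' Per-region reliability report
#'
#' Pivots a long ROI volume table into one complete subjects x raters
#' matrix per (roi, hemisphere) and computes the two-way single-rater ICC:
#' `mode = "consistency"` treats visits as raters (test-retest),
#' `mode = "agreement"` treats sites as raters (multi-site). Negative
#' estimates are reported as computed and flagged unreliable.
#'
#' @param roi_table long data.frame as from [compute_roi_volumes()] /
#'   [read_roi_table()].
#' @param mode `"consistency"` or `"agreement"` (the ICC form).
#' @param raters which table dimension plays the rater role; defaults to
#'   visits for consistency and sites for agreement.
#' @param cutoff reliability threshold (default 0.75).
#' @return data.frame with columns
#'   `roi, hemisphere, icc, model, n, k, reliable`.
#' @export
reliability_report <- function(roi_table, mode = c("consistency", "agreement"),
                               raters = NULL, cutoff = 0.75) {
  mode <- match.arg(mode)
  roi_table <- validate_roi_table(roi_table)
  if (is.null(raters)) raters <- if (mode == "consistency") "visits" else "sites"
  raters <- match.arg(raters, c("visits", "sites"))
  rater_col <- if (raters == "visits") "visit_id" else "site_id"
  groups <- unique(roi_table[c("roi", "hemisphere")])
  groups <- groups[groups$roi != "icv", , drop = FALSE]
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sel <- roi_table$roi == groups$roi[g] &
      (roi_table$hemisphere == groups$hemisphere[g] |
         (is.na(roi_table$hemisphere) & is.na(groups$hemisphere[g])))
    sub <- roi_table[sel, , drop = FALSE]
    subjects <- sort(unique(sub$subject_id))
    raters <- sort(unique(sub[[rater_col]]))
    m <- matrix(NA_real_, length(subjects), length(raters),
                dimnames = list(subjects, raters))
    m[cbind(match(sub$subject_id, subjects), match(sub[[rater_col]], raters))] <-
      sub$volume_ml
    if (any(is.na(m))) {
      miss <- which(is.na(m), arr.ind = TRUE)
      stop("incomplete design for ", groups$roi[g], "/",
           groups$hemisphere[g], "; missing cells: ",
           paste(paste(subjects[miss[, 1]], raters[miss[, 2]], sep = ":"),
                 collapse = ", "))
    }
    mm <- measurement_matrix(m)
    res <- if (mode == "consistency") icc_consistency(mm, cutoff)
           else icc_agreement(mm, cutoff)
    out[[g]] <- data.frame(roi = groups$roi[g],
                           hemisphere = groups$hemisphere[g],
                           icc = res$icc, model = res$model,
                           n = res$n, k = res$k, reliable = res$reliable,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
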