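# Subject-level cohort tables are wide data.frames: one row per subject
# with demographics (subject_id, age, sex, site_id, group, education, cdr,
# cdr_sob, icv_ml) and one volume column per region, named <roi>_<hemi>_ml
# (e.g. hippocampus_L_ml).

#' Column name of a region volume in a subject table
#' @param roi region name; @param hemisphere "L" or "R".
#' @return column name string.
#' @export
roi_column <- function(roi, hemisphere) paste(roi, hemisphere, "ml", sep = "_")

validate_subject_table <- function(records) {
  need <- c("subject_id", "age", "sex", "site_id", "group", "icv_ml")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(records$age < 0 | records$age > 120)) stop("age out of [0, 120]")
  if (any(records$icv_ml <= 0)) stop("icv must be positive")
  if (!all(records$sex %in% c("F", "M"))) stop("sex must be F or M")
  invisible(records)
}

#' Demographic summary with between-group ANOVA
#'
#' Per-group mean +/- sd for age, CDR, CDR sum-of-boxes, education and ICV,
#' percentage of females, and a one-way ANOVA p-value per continuous
#' variable across groups. With a single group the p column is omitted.
#'
#' @param records subject table (see [roi_column()] for the layout).
#' @param variables continuous variables to summarize (present columns
#'   only).
#' @return data.frame: one row per variable, `mean_sd` columns per group,
#'   and `p_anova` when >= 2 groups.
#' @export
demographic_summary <- function(records,
                                variables = c("age", "cdr", "cdr_sob",
                                              "education", "icv_ml")) {
  validate_subject_table(records)
  groups <- unique(records$group)
  variables <- intersect(variables, names(records))
  rows <- list()
  for (v in variables) {
    cells <- vapply(groups, function(g) {
      x <- records[[v]][records$group == g]
      x <- x[is.finite(x)]
      sprintf("%.1f ± %.1f", mean(x), if (length(x) > 1) sd(x) else 0)
    }, character(1))
    row <- as.list(cells)
    names(row) <- paste0(groups, "_mean_sd")
    if (length(groups) > 1L) {
      ok <- is.finite(records[[v]])
      if (any(tabulate(factor(records$group[ok])) < 2L)) {
        stop("a group has n < 2 for ANOVA on ", v)
      }
      fit <- aov(records[[v]][ok] ~ factor(records$group[ok]))
      row$p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
    rows[[v]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  fem <- vapply(groups, function(g) {
    s <- records$sex[records$group == g]
    sprintf("%.1f (%d)", 100 * mean(s == "F"), sum(s == "F"))
  }, character(1))
  femrow <- as.list(fem)
  names(femrow) <- paste0(groups, "_mean_sd")
  if (length(groups) > 1L) femrow$p_anova <- NA_real_
  rows[["female_pct_n"]] <- as.data.frame(femrow, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out <- cbind(variable = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Decade bins used for normative tables
#' @return data.frame of (lo, hi, bin) closed integer ranges 10-19 ... 90-99.
#' @export
decade_bins <- function() {
  lo <- seq(10, 90, 10)
  data.frame(lo = lo, hi = lo + 9, bin = sprintf("%d-%d", lo, lo + 9))
}

#' Normative age-distribution table
#'
#' For cognitively normal records only: per (region, hemisphere, age bin)
#' order statistics of the volume distribution. Empty bins are omitted; a
#' single-subject bin reports sd 0 and is flagged.
#'
#' @param records subject table restricted to the reference (CN) group; an
#'   error is raised if no CN rows are present, and non-CN rows are dropped
#'   with a message.
#' @param bins data.frame of closed integer ranges (`lo`, `hi`, `bin`),
#'   default [decade_bins()].
#' @param rois regions to tabulate (default the eight reported ones).
#' @return data.frame `roi, hemisphere, bin, n, mean, sd, p5, p25, p50,
#'   p75, p95, single_subject`.
#' @export
build_normative_table <- function(records, bins = decade_bins(),
                                  rois = roi_names()) {
  validate_subject_table(records)
  if (!any(records$group == "CN")) stop("no CN records")
  if (any(records$group != "CN")) {
    message("dropping ", sum(records$group != "CN"), " non-CN records")
    records <- records[records$group == "CN", , drop = FALSE]
  }
  out <- list()
  for (roi in rois) for (h in c("L", "R")) {
    cl <- roi_column(roi, h)
    if (!cl %in% names(records)) next
    for (b in seq_len(nrow(bins))) {
      sel <- records$age >= bins$lo[b] & records$age <= bins$hi[b]
      x <- records[[cl]][sel]
      x <- x[is.finite(x)]
      if (!length(x)) next
      q <- quantile(x, c(.05, .25, .5, .75, .95), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        roi = roi, hemisphere = h, bin = bins$bin[b], n = length(x),
        mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
        p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
        single_subject = length(x) == 1L, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Covariate-adjusted group difference for one region
#'
#' Ordinary least squares (Gaussian identity GLM) of the region volume on a
#' group indicator (CN reference) with covariates age at MRI, sex, site
#' (dummy-coded, first observed site as reference) and intracranial volume.
#' The reported estimate is the group coefficient in mL, with its standard
#' error and a two-sided p-value from the t distribution at residual
#' degrees of freedom.
#'
#' @param records subject table containing CN and the target group.
#' @param roi,hemisphere region selector.
#' @param target_group `"MCI"` or `"dementia"` (any non-CN level present).
#' @return data.frame row of class `adjusted_difference`: `roi, hemisphere,
#'   group, estimate_ml, se_ml, p, n_cn, n_group, covariates`.
#' @export
adjusted_group_difference <- function(records, roi, hemisphere,
                                      target_group) {
  validate_subject_table(records)
  cl <- roi_column(roi, hemisphere)
  if (!cl %in% names(records)) stop("no volume column ", cl)
  dat <- records[records$group %in% c("CN", target_group), , drop = FALSE]
  if (!any(dat$group == target_group)) stop("no records for ", target_group)
  if (!any(dat$group == "CN")) stop("no CN reference records")
  dat$group <- factor(dat$group, levels = c("CN", target_group))
  dat$sex <- factor(dat$sex, levels = c("F", "M"))
  dat$site_id <- factor(dat$site_id, levels = unique(dat$site_id))
  dat$y <- dat[[cl]]
  dat <- dat[complete.cases(dat[c("y", "age", "sex", "site_id", "icv_ml")]), ]
  form <- y ~ group + age + sex + site_id + icv_ml
  fit <- lm(form, data = dat)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  term <- paste0("group", target_group)
  est <- cf[[term]]
  se <- sqrt(diag(vcov(fit)))[[term]]
  p <- 2 * pt(-abs(est / se), df = fit$df.residual)
  structure(data.frame(roi = roi, hemisphere = hemisphere,
                       group = target_group, estimate_ml = est, se_ml = se,
                       p = p, n_cn = sum(dat$group == "CN"),
                       n_group = sum(dat$group == target_group),
                       covariates = "age+sex+site+icv",
                       stringsAsFactors = FALSE),
            class = c("adjusted_difference", "data.frame"))
}

#' Adjusted group differences for every region
#'
#' Fits [adjusted_group_difference()] for each (region, hemisphere, group)
#' combination, each patient group contrasted against CN in its own model.
#' A Bonferroni-adjusted column over the regions within each group is
#' appended as supplementary output (the primary p-values are unadjusted).
#'
#' @param records subject table.
#' @param groups patient groups to contrast (default all non-CN present).
#' @param rois regions (default the eight reported ones).
#' @return data.frame in Table-2 layout with `p_bonferroni` appended.
#' @export
adjusted_group_differences <- function(records, groups = NULL,
                                       rois = roi_names()) {
  if (is.null(groups)) groups <- setdiff(unique(records$group), "CN")
  out <- list()
  for (g in groups) for (roi in rois) for (h in c("L", "R")) {
    if (!roi_column(roi, h) %in% names(records)) next
    out[[length(out) + 1L]] <- adjusted_group_difference(records, roi, h, g)
  }
  res <- do.call(rbind, out)
  res$p_bonferroni <- NA_real_
  for (g in groups) {
    sel <- res$group == g
    res$p_bonferroni[sel] <- pmin(1, res$p[sel] * sum(sel))
  }
  rownames(res) <- NULL
  res
}

#' Age-stratified adjusted group differences
#'
#' Re-runs the covariate-adjusted group contrast within closed integer age
#' bins (default 71-80 and 81-100); age remains a covariate within each
#' bin.
#'
#' @param records subject table.
#' @param bins list of `c(lo, hi)` closed integer ranges.
#' @param groups,rois as in [adjusted_group_differences()].
#' @return data.frame with `age_bin`, per-bin `n_cn`/`n_group`, and the
#'   [adjusted_group_difference()] columns.
#' @export
age_stratified_analysis <- function(records,
                                    bins = list(c(71, 80), c(81, 100)),
                                    groups = NULL, rois = roi_names()) {
  validate_subject_table(records)
  out <- list()
  for (b in bins) {
    sub <- records[records$age >= b[1] & records$age <= b[2], , drop = FALSE]
    lab <- sprintf("%d-%d", b[1], b[2])
    if (is.null(groups)) {
      gg <- setdiff(unique(sub$group), "CN")
    } else gg <- groups
    if (!length(gg) || !any(sub$group == "CN"))
      stop("empty bin-group cell in age bin ", lab)
    for (g in gg) {
      if (!any(sub$group == g) || !any(sub$group == "CN"))
        stop("empty bin-group cell: ", lab, " / ", g)
    }
    res <- adjusted_group_differences(sub, groups = gg, rois = rois)
    res <- cbind(age_bin = lab, res)
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
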