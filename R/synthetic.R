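# Synthetic phantom volumes and cohort tables. The generator's defaults are
# calibrated to the published demographics of a large East Asian multi-site
# normative sample (group sizes, age distributions, intracranial volume
# moments) and to adjusted atrophy/enlargement effect sizes of the magnitude
# reported for MCI and dementia, so that downstream stages are exercised
# under realistic conditions. Every generated cohort carries a truth ledger
# of its injected parameters.

#' Default per-region age trajectories
#'
#' Gray-matter regions follow a "tent" trajectory: volume rises linearly to
#' a peak in the mid-30s and declines linearly thereafter, matching the
#' qualitative rise-then-decline of cortical gray matter; the frontal lobe
#' declines monotonically from the start of the observed age range; the
#' lateral ventricle grows linearly with age. Keeping each segment linear
#' keeps the covariate-adjusted group model well specified for subjects
#' older than the peak, which is where patient groups concentrate.
#'
#' @return data.frame with columns `roi, model, baseline_ml, peak_age,
#'   rise_rate, decline_rate, slope_ml_yr, residual_sd`; rates are
#'   fractional volume change per year, `slope_ml_yr` the ventricle growth
#'   in mL/year, `residual_sd` the subject-level residual standard
#'   deviation in mL.
#' @export
default_roi_trajectories <- function() {
  data.frame(
    roi = c("frontal", "temporal", "parietal", "occipital", "cingulate",
            "insula", "hippocampus", "lateral_ventricle"),
    model = c("tent", "tent", "tent", "tent", "tent", "tent", "tent",
              "linear"),
    baseline_ml = c(90, 60, 55, 35, 10, 7, 3.5, 12),
    peak_age = c(18, 35, 35, 35, 35, 35, 35, NA),
    rise_rate = c(0, 2.35e-3, 2.35e-3, 2.35e-3, 2.35e-3, 2.35e-3, 2.35e-3,
                  NA),
    decline_rate = c(1.54e-3, 2.7e-3, 2.7e-3, 2.7e-3, 2.7e-3, 2.7e-3,
                     2.7e-3, NA),
    slope_ml_yr = c(NA, NA, NA, NA, NA, NA, NA, 0.30),
    residual_sd = c(5.6, 4.0, 3.9, 2.4, 1.1, 0.6, 0.4, 6.0),
    stringsAsFactors = FALSE)
}

#' Default group effect sizes (mL)
#'
#' Additive volume differences of MCI and dementia relative to cognitively
#' normal, per region and hemisphere: negative (atrophy) for tissue
#' regions, positive (enlargement) for the lateral ventricles, at
#' magnitudes typical of covariate-adjusted clinical volumetry.
#'
#' @return data.frame `roi, hemisphere, group, effect_ml`.
#' @export
default_group_effects <- function() {
  rois <- c("frontal", "temporal", "parietal", "occipital", "insula",
            "cingulate", "hippocampus", "lateral_ventricle")
  mci_L <- c(-0.93, -2.18, -1.23, -0.33, -0.15, -0.30, -0.37, 5.68)
  mci_R <- c(-1.15, -2.44, -1.60, -0.42, -0.22, -0.41, -0.39, 5.12)
  dem_L <- c(-3.21, -5.03, -2.74, -1.00, -0.36, -0.68, -0.66, 9.63)
  dem_R <- c(-3.25, -4.76, -3.37, -1.01, -0.51, -0.74, -0.65, 8.87)
  rbind(
    data.frame(roi = rois, hemisphere = "L", group = "MCI", effect_ml = mci_L),
    data.frame(roi = rois, hemisphere = "R", group = "MCI", effect_ml = mci_R),
    data.frame(roi = rois, hemisphere = "L", group = "dementia", effect_ml = dem_L),
    data.frame(roi = rois, hemisphere = "R", group = "dementia", effect_ml = dem_R))
}

#' Default site table
#'
#' Five acquisition sites with cohort weights matching the source mix of a
#' large multi-site normative sample (three hospital sites and two young
#' open-data sites); patient groups are recruited at the first site only.
#' Site effects default to intensity-only (`gain`, `gamma`,
#' `bias_amplitude` act on phantom images); `volume_bias` is a
#' multiplicative volume perturbation for stress tests, 1 = none.
#'
#' @return data.frame `site_id, cn_weight, gain, gamma, bias_amplitude,
#'   volume_bias`.
#' @export
default_sites <- function() {
  data.frame(
    site_id = c("K1", "K2", "K3", "O3", "O2"),
    cn_weight = c(647, 62, 29, 198, 57) / 993,
    gain = c(1.00, 1.06, 0.95, 1.10, 0.92),
    gamma = c(1.00, 1.04, 0.97, 0.95, 1.05),
    bias_amplitude = c(0, 0.05, 0.04, 0.06, 0.05),
    volume_bias = 1,
    stringsAsFactors = FALSE)
}

#' Cohort generation specification
#'
#' @param n_per_group named vector of group sizes; defaults to the
#'   normative-sample scale (992 CN, 524 MCI, 163 dementia).
#' @param age_range closed age range for the CN group (uniform ages).
#' @param group_ages mean/sd of the (truncated normal) patient-group age
#'   distributions.
#' @param icv per-group intracranial volume mean/sd in mL.
#' @param sites site table as [default_sites()].
#' @param roi_trajectory per-region age model as
#'   [default_roi_trajectories()].
#' @param group_effects injected additive effects as
#'   [default_group_effects()]; set `effect_ml` to 0 for null simulations.
#' @param female_frac probability a subject is female, per group.
#' @param testretest_noise_cv default within-subject coefficient of
#'   variation for repeated measurements.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(CN = 992, MCI = 524, dementia = 163),
                        age_range = c(18, 96),
                        group_ages = list(MCI = c(mean = 75.2, sd = 8.2),
                                          dementia = c(mean = 78.9, sd = 8.4)),
                        icv = list(CN = c(mean = 1519.3, sd = 136.5),
                                   MCI = c(mean = 1487.9, sd = 132.5),
                                   dementia = c(mean = 1476.5, sd = 137.3)),
                        sites = default_sites(),
                        roi_trajectory = default_roi_trajectories(),
                        group_effects = default_group_effects(),
                        female_frac = c(CN = 0.641, MCI = 0.677,
                                        dementia = 0.706),
                        testretest_noise_cv = 0.01,
                        seed = 1L) {
  stopifnot(all(n_per_group >= 0), age_range[1] < age_range[2],
            all(roi_trajectory$residual_sd >= 0),
            all(is.finite(group_effects$effect_ml)),
            testretest_noise_cv >= 0)
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  structure(list(n_per_group = n_per_group, age_range = age_range,
                 group_ages = group_ages, icv = icv, sites = sites,
                 roi_trajectory = roi_trajectory,
                 group_effects = group_effects, female_frac = female_frac,
                 testretest_noise_cv = testretest_noise_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

# Relative (fraction-of-baseline) age factor for tissue regions.
tent_factor <- function(age, peak, rise, decline) {
  ifelse(age >= peak, 1 - decline * (age - peak), 1 - rise * (peak - age))
}

#' Generate a synthetic cohort table
#'
#' Per subject: group-specific age, sex, site, intracranial volume and
#' clinical scores; per region volume = baseline x age factor + baseline x
#' (ICV/reference - 1) + group effect + Gaussian residual. Negative draws
#' are truncated at 0.1 mL and counted. The returned truth ledger records
#' every injected parameter; downstream recovery tests read truth from it.
#'
#' @param spec [cohort_spec()].
#' @return list with `records` (wide subject table, see [roi_column()]) and
#'   `truth` (injected parameters, truncation count, seed).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  traj <- spec$roi_trajectory
  groups <- names(spec$n_per_group)[spec$n_per_group > 0]
  rows <- list()
  sid <- 0L
  n_trunc <- 0L
  for (g in groups) {
    n <- spec$n_per_group[[g]]
    age <- if (g == "CN") {
      runif(n, spec$age_range[1], spec$age_range[2])
    } else {
      ga <- spec$group_ages[[g]]
      rnorm_trunc(n, ga[["mean"]], ga[["sd"]],
                  spec$age_range[1], spec$age_range[2])
    }
    sex <- ifelse(runif(n) < spec$female_frac[[g]], "F", "M")
    site <- if (g == "CN") {
      sample(spec$sites$site_id, n, replace = TRUE,
             prob = spec$sites$cn_weight)
    } else rep(spec$sites$site_id[1], n)
    icv <- rnorm(n, spec$icv[[g]][["mean"]], spec$icv[[g]][["sd"]])
    cdr <- switch(g, CN = rep(0, n), MCI = rep(0.5, n),
                  sample(c(1, 2), n, replace = TRUE, prob = c(0.7, 0.3)))
    cdr_sob <- switch(g,
                      CN = abs(rnorm(n, 0.1, 0.3)),
                      MCI = rnorm_trunc(n, 1.8, 1.2, 0),
                      rnorm_trunc(n, 7.2, 3.5, 0))
    edu <- switch(g,
                  CN = rnorm_trunc(n, 12.1, 4.2, 0),
                  MCI = rnorm_trunc(n, 9.5, 5.2, 0),
                  rnorm_trunc(n, 8.5, 5.6, 0))
    df <- data.frame(subject_id = sprintf("S%05d", sid + seq_len(n)),
                     group = g, age = age, sex = sex, site_id = site,
                     education = edu, cdr = cdr, cdr_sob = cdr_sob,
                     icv_ml = icv, stringsAsFactors = FALSE)
    sid <- sid + n
    icv_ref <- spec$icv[["CN"]][["mean"]]
    site_bias <- spec$sites$volume_bias[match(site, spec$sites$site_id)]
    for (r in seq_len(nrow(traj))) {
      roi <- traj$roi[r]
      base <- traj$baseline_ml[r]
      fage <- if (traj$model[r] == "tent") {
        base * tent_factor(age, traj$peak_age[r], traj$rise_rate[r],
                           traj$decline_rate[r])
      } else {
        base + traj$slope_ml_yr[r] * (age - spec$age_range[1])
      }
      for (h in c("L", "R")) {
        eff <- spec$group_effects$effect_ml[
          spec$group_effects$roi == roi &
            spec$group_effects$hemisphere == h &
            spec$group_effects$group == g]
        if (!length(eff)) eff <- 0
        v <- (fage + base * (icv / icv_ref - 1) + eff +
                rnorm(n, 0, traj$residual_sd[r])) * site_bias
        n_trunc <- n_trunc + sum(v < 0.1)
        df[[roi_column(roi, h)]] <- pmax(v, 0.1)
      }
    }
    rows[[g]] <- df
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  if (n_trunc > 0)
    warning(n_trunc, " volume draws truncated at 0.1 mL")
  list(records = records,
       truth = list(group_effects = spec$group_effects,
                    roi_trajectory = traj, icv = spec$icv,
                    n_per_group = spec$n_per_group,
                    n_truncated = n_trunc, seed = spec$seed))
}

#' Generate repeated (test-retest) measurements
#'
#' Same anatomy per subject; each visit adds independent measurement noise
#' with the given coefficient of variation. Without a supplied subject
#' table, per-subject true volumes are drawn around the default regional
#' baselines with the stated between-subject coefficient of variation.
#'
#' @param records optional wide subject table whose volumes serve as the
#'   per-subject truth; when `NULL` a cohort of `n` subjects is drawn.
#' @param n number of subjects when `records` is `NULL` (default 57).
#' @param k_visits number of visits (>= 2).
#' @param between_cv between-subject coefficient of variation used when
#'   drawing true volumes (default 0.10).
#' @param noise_cv within-subject measurement coefficient of variation per
#'   visit (>= 0, default 0.01).
#' @param seed RNG seed.
#' @return long ROI volume table (one site, `k_visits` visits per subject).
#' @export
generate_testretest <- function(records = NULL, n = 57L, k_visits = 2L,
                                between_cv = 0.10, noise_cv = 0.01,
                                seed = 1L) {
  if (k_visits < 2L) stop("need k_visits >= 2")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  set.seed(seed)
  traj <- default_roi_trajectories()
  if (is.null(records)) {
    truth <- list()
    ids <- sprintf("S%03d", seq_len(n))
    for (r in seq_len(nrow(traj))) for (h in c("L", "R")) {
      base <- traj$baseline_ml[r]
      truth[[roi_column(traj$roi[r], h)]] <-
        pmax(rnorm(n, base, between_cv * base), 0.1)
    }
    records <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
                     as.data.frame(truth))
  }
  vol_cols <- grep("_ml$", names(records), value = TRUE)
  vol_cols <- setdiff(vol_cols, "icv_ml")
  out <- list()
  for (cl in vol_cols) {
    parts <- strsplit(sub("_ml$", "", cl), "_(?=[LR]$)", perl = TRUE)[[1]]
    truev <- records[[cl]]
    for (v in seq_len(k_visits)) {
      meas <- truev * (1 + rnorm(length(truev), 0, noise_cv))
      out[[length(out) + 1L]] <- data.frame(
        subject_id = records$subject_id, site_id = "S1",
        visit_id = sprintf("v%d", v), roi = parts[1], hemisphere = parts[2],
        volume_ml = pmax(meas, 0), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_roi_table(res)
}

#' Generate traveling-subject multi-site measurements
#'
#' The same subjects are measured at every site (identical anatomy); each
#' site applies its multiplicative volume bias (1 = intensity-only site
#' differences, the default) and independent measurement noise.
#'
#' @param records optional wide subject table as in
#'   [generate_testretest()]; default draws `n` subjects.
#' @param n number of traveling subjects (default 3).
#' @param sites character vector of site ids (default 10 sites) or a
#'   data.frame with `site_id` and `volume_bias` columns.
#' @param between_cv,noise_cv as in [generate_testretest()].
#' @param seed RNG seed.
#' @return long ROI volume table (one visit per site).
#' @export
generate_multisite <- function(records = NULL, n = 3L,
                               sites = sprintf("M%02d", 1:10),
                               between_cv = 0.10, noise_cv = 0.01,
                               seed = 1L) {
  if (is.character(sites))
    sites <- data.frame(site_id = sites, volume_bias = 1,
                        stringsAsFactors = FALSE)
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  if (nrow(sites) < 2L) stop("need at least 2 sites")
  set.seed(seed)
  traj <- default_roi_trajectories()
  if (is.null(records)) {
    truth <- list()
    for (r in seq_len(nrow(traj))) for (h in c("L", "R")) {
      base <- traj$baseline_ml[r]
      truth[[roi_column(traj$roi[r], h)]] <-
        pmax(rnorm(n, base, between_cv * base), 0.1)
    }
    records <- cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                                stringsAsFactors = FALSE),
                     as.data.frame(truth))
  }
  vol_cols <- setdiff(grep("_ml$", names(records), value = TRUE), "icv_ml")
  out <- list()
  for (cl in vol_cols) {
    parts <- strsplit(sub("_ml$", "", cl), "_(?=[LR]$)", perl = TRUE)[[1]]
    truev <- records[[cl]]
    for (s in seq_len(nrow(sites))) {
      meas <- truev * sites$volume_bias[s] *
        (1 + rnorm(length(truev), 0, noise_cv))
      out[[length(out) + 1L]] <- data.frame(
        subject_id = records$subject_id, site_id = sites$site_id[s],
        visit_id = "v1", roi = parts[1], hemisphere = parts[2],
        volume_ml = pmax(meas, 0), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_roi_table(res)
}

#' Phantom image specification
#'
#' A phantom is a stack of analytically defined ellipsoids on a regular
#' grid: structures are painted in order, so an enclosing "other"
#' (intracranial) ellipsoid is listed first and regions of interest carve
#' into it. True volumes are known in closed form (4/3 pi abc), up to
#' voxelization.
#'
#' @param grid_shape integer length-3 grid size in voxels.
#' @param spacing voxel size in mm (isotropic scalar or length-3).
#' @param structures data.frame with columns `label, roi, hemisphere,
#'   tissue, cx, cy, cz, a, b, c` (centers and semi-axes in mm).
#' @param intensities named list of `c(mean, sd)` per tissue, including
#'   `background`.
#' @param jitter_mm uniform center jitter amplitude per subject.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L), spacing = 1,
                         structures = NULL, intensities = NULL,
                         jitter_mm = 1.5) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(structures)) {
    # inner structure sized to the cohort generator's hippocampus baseline
    # (4/3 pi * 9.5 * 8.5 * 10.5 / 1000 = 3.55 mL) with all semi-axes
    # >= 8 mm, the regime where closed-form ellipsoid volumes track the
    # voxelized label volume within ~2%
    structures <- data.frame(
      label = c(2L, 1L),
      roi = c("other", "hippocampus"),
      hemisphere = c(NA, "L"),
      tissue = c("wm", "gm"),
      cx = c(24, 21), cy = c(24, 25), cz = c(24, 24),
      a = c(19, 9.5), b = c(17, 8.5), c = c(18, 10.5),
      stringsAsFactors = FALSE)
  }
  if (is.null(intensities)) {
    intensities <- list(background = c(5, 5), csf = c(35, 6),
                        gm = c(70, 7), wm = c(110, 8))
  }
  stopifnot(all(structures$tissue %in% names(intensities)))
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 structures = structures, intensities = intensities,
                 jitter_mm = jitter_mm),
            class = "phantom_spec")
}

#' Generate one phantom image/label pair
#'
#' Labels come from the analytic ellipsoids (optionally scaled per subject
#' and jittered); the image adds per-tissue Gaussian noise and an optional
#' site intensity transform (gain, gamma on a fixed 0-150 working range,
#' smooth multiplicative bias field).
#'
#' @param spec [phantom_spec()].
#' @param subject_scale isotropic anatomical scale factor (volumes scale
#'   with its cube).
#' @param site_transform `NULL` or list/row with `gain`, `gamma`,
#'   `bias_amplitude`.
#' @param seed RNG seed; same seed gives bit-identical output.
#' @param scheme [label_scheme()] attached to the label map; default
#'   derived from the structures.
#' @return list `(image, labels, truth)`; `truth` is a data.frame of
#'   closed-form structure volumes in mL (enclosing structures minus the
#'   carved-out regions).
#' @export
generate_phantom <- function(spec = phantom_spec(), subject_scale = 1,
                             site_transform = NULL, seed = 1L,
                             scheme = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  d <- spec$grid_shape
  sp <- spec$spacing
  st <- spec$structures
  # voxel centers in mm
  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3]
  lab <- array(0L, d)
  jit <- matrix(runif(3 * nrow(st), -spec$jitter_mm, spec$jitter_mm), ncol = 3)
  ell_ml <- numeric(nrow(st))
  for (s in seq_len(nrow(st))) {
    ax <- c(st$a[s], st$b[s], st$c[s]) * subject_scale
    ct <- c(st$cx[s], st$cy[s], st$cz[s]) + jit[s, ]
    if (any(ct - ax < 0) || any(ct + ax > d * sp))
      stop("structure ", st$roi[s], " overflows the grid")
    u2 <- outer(outer(((xs - ct[1]) / ax[1])^2, ((ys - ct[2]) / ax[2])^2, "+"),
                ((zs - ct[3]) / ax[3])^2, "+")
    lab[u2 <= 1] <- st$label[s]
    ell_ml[s] <- 4 / 3 * pi * prod(ax) / 1000
  }
  # closed-form truth: each ellipsoid minus structures painted after it
  # that lie inside it (nested design: later structures carve earlier ones)
  truth_ml <- ell_ml
  if (nrow(st) > 1)
    for (s in seq_len(nrow(st) - 1L))
      truth_ml[s] <- ell_ml[s] - sum(ell_ml[(s + 1):nrow(st)])
  mu <- vapply(spec$intensities, `[`, numeric(1), 1L)
  sdv <- vapply(spec$intensities, `[`, numeric(1), 2L)
  tiss <- c("background", st$tissue)[match(lab, c(0L, st$label))]
  img <- array(mu[tiss] + rnorm(length(lab)) * sdv[tiss], d)
  if (!is.null(site_transform)) {
    gain <- if (!is.null(site_transform$gain)) site_transform$gain else 1
    gamma <- if (!is.null(site_transform$gamma)) site_transform$gamma else 1
    amp <- if (!is.null(site_transform$bias_amplitude))
      site_transform$bias_amplitude else 0
    img <- pmax(img, 0)
    img <- gain * 150 * (img / 150)^gamma
    if (amp > 0) {
      bias <- 1 + amp *
        outer(outer(sin(pi * seq_len(d[1]) / d[1]),
                    sin(pi * seq_len(d[2]) / d[2]), "*"),
              sin(pi * seq_len(d[3]) / d[3]), "*")
      img <- img * bias
    }
  }
  if (is.null(scheme)) {
    scheme <- label_scheme(st[c("label", "roi", "hemisphere")])
  }
  list(image = image_volume(img, spacing = sp),
       labels = label_map(lab, spacing = sp, scheme = scheme),
       truth = data.frame(label = st$label, roi = st$roi,
                          hemisphere = st$hemisphere,
                          volume_ml = truth_ml,
                          ellipsoid_ml = ell_ml,
                          stringsAsFactors = FALSE))
}
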