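test_that("phantom label volumes match the closed-form ellipsoid volume", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48),
                       structures = data.frame(
                         label = 1L, roi = "hippocampus", hemisphere = "L",
                         tissue = "gm", cx = 24, cy = 24, cz = 24,
                         a = 10, b = 10, c = 10),
                       jitter_mm = 0)
  ph <- generate_phantom(spec, seed = 1)
  vox_ml <- sum(ph$labels$labels == 1L) / 1000
  expect_equal(ph$truth$volume_ml, 4 / 3 * pi, tolerance = 1e-6)
  expect_lt(abs(vox_ml - 4 / 3 * pi) / (4 / 3 * pi), 0.02)
  # subject_scale scales voxel counts by its cube
  ph2 <- generate_phantom(spec, subject_scale = 1.1, seed = 1)
  ratio <- sum(ph2$labels$labels == 1L) / sum(ph$labels$labels == 1L)
  expect_lt(abs(ratio - 1.1^3) / 1.1^3, 0.02)
  # seed determinism is bit-exact
  pa <- generate_phantom(spec, seed = 9)
  pb <- generate_phantom(spec, seed = 9)
  expect_identical(pa$image$data, pb$image$data)
  expect_identical(pa$labels$labels, pb$labels$labels)
  # structures must fit inside the grid
  bad <- phantom_spec(grid_shape = c(20, 20, 20),
                      structures = data.frame(
                        label = 1L, roi = "other", hemisphere = NA,
                        tissue = "wm", cx = 10, cy = 10, cz = 10,
                        a = 15, b = 5, c = 5), jitter_mm = 0)
  expect_error(generate_phantom(bad, seed = 1), "overflows")
})

test_that("site transforms change intensities but not labels", {
  ph0 <- generate_phantom(seed = 2)
  ph1 <- generate_phantom(seed = 2,
                          site_transform = list(gain = 1.1, gamma = 0.95,
                                                bias_amplitude = 0.05))
  expect_identical(ph0$labels$labels, ph1$labels$labels)
  expect_gt(mean(abs(ph0$image$data - ph1$image$data)), 1)
})

test_that("cohort generator is deterministic in the age trend limit", {
  spec <- cohort_spec(n_per_group = c(CN = 300),
                      sites = default_sites()[1, ],
                      seed = 3)
  spec$roi_trajectory$residual_sd <- 0
  spec$icv <- list(CN = c(mean = 1519.3, sd = 0))
  res <- generate_cohort(spec)
  rec <- res$records
  # zero noise: volume is an exact function of age
  traj <- spec$roi_trajectory
  r <- traj[traj$roi == "temporal", ]
  expected <- r$baseline_ml *
    brainvol:::tent_factor(rec$age, r$peak_age, r$rise_rate, r$decline_rate)
  expect_equal(rec$temporal_L_ml, expected, tolerance = 1e-12)
  # decade means peak in the bin containing the peak age
  tab <- build_normative_table(rec, rois = "temporal")
  tl <- tab[tab$hemisphere == "L", ]
  expect_equal(tl$bin[which.max(tl$mean)], "30-39")
})

test_that("cohort defaults reproduce the calibration moments", {
  res <- suppressWarnings(generate_cohort(cohort_spec(seed = 4)))
  rec <- res$records
  expect_equal(nrow(rec), 992 + 524 + 163)
  cn <- rec[rec$group == "CN", ]
  # CN mean ICV within 2 standard errors of the calibration target
  expect_lt(abs(mean(cn$icv_ml) - 1519.3), 2 * 136.5 / sqrt(992))
  expect_true(all(rec$site_id[rec$group != "CN"] == "K1"))
  expect_gt(mean(rec$age[rec$group == "dementia"]),
            mean(rec$age[rec$group == "CN"]))
  # truth ledger carries the injected parameters
  expect_identical(res$truth$group_effects, default_group_effects())
  expect_equal(res$truth$seed, 4L)
})

test_that("test-retest generator produces the designed reliability", {
  # zero measurement noise: identical visits, perfect consistency
  tr0 <- generate_testretest(n = 8, k_visits = 2, noise_cv = 0, seed = 5)
  rep0 <- reliability_report(tr0, "consistency")
  expect_true(all(rep0$icc == 1))
  # increasing noise strictly decreases the expected ICC
  mean_icc <- function(cv) {
    mean(vapply(1:6, function(s) {
      min(reliability_report(generate_testretest(n = 40, k_visits = 2,
                                                 noise_cv = cv,
                                                 seed = 100 + s),
                             "consistency")$icc)
    }, numeric(1)))
  }
  iccs <- vapply(c(0.01, 0.05, 0.15), mean_icc, numeric(1))
  expect_true(all(diff(iccs) < 0))
  expect_error(generate_testretest(k_visits = 1), "k_visits")
  expect_error(generate_testretest(noise_cv = -1), "noise_cv")
})

test_that("multi-site generator matches the traveling-subject design", {
  ms <- generate_multisite(n = 3, seed = 6)
  expect_equal(length(unique(ms$site_id)), 10)
  expect_equal(length(unique(ms$subject_id)), 3)
  expect_equal(nrow(ms), 3 * 10 * 16)
  # identity transforms and no noise: perfect agreement
  ms0 <- generate_multisite(n = 5, sites = c("A", "B", "C"), noise_cv = 0,
                            seed = 7)
  rep0 <- reliability_report(ms0, "agreement")
  expect_true(all(rep0$icc == 1))
  # a multiplicative per-site volume bias penalizes agreement only
  sites <- data.frame(site_id = c("A", "B"), volume_bias = c(1, 1.02))
  msb <- generate_multisite(n = 30, sites = sites, noise_cv = 0.01, seed = 8)
  agr <- reliability_report(msb, "agreement")
  con <- reliability_report(msb, "consistency", raters = "sites")
  expect_true(all(agr$icc < con$icc))
  expect_error(generate_multisite(sites = c("A", "A")), "duplicate")
})
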