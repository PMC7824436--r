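test_that("patch sampling respects shapes, seeds and uniformity", {
  ph <- tiny_phantom(seed = 1, grid = 32)
  spec <- patch_spec(size = 32, overlap = 16)
  # a patch the size of the volume has a single possible origin
  p <- sample_training_patches(ph$image, ph$labels, spec, n = 3, seed = 1)
  expect_true(all(vapply(p, function(q) all(q$origin == c(1, 1, 1)),
                         logical(1))))
  expect_equal(dim(p[[1]]$image), c(32, 32, 32))
  # same seed, same patches
  big <- image_volume(array(rnorm(40^3), c(40, 40, 40)))
  biglab <- label_map(array(0L, c(40, 40, 40)))
  s8 <- patch_spec(size = 8, overlap = 4)
  a <- sample_training_patches(big, biglab, s8, n = 5, seed = 7)
  b <- sample_training_patches(big, biglab, s8, n = 5, seed = 7)
  expect_identical(lapply(a, `[[`, "origin"), lapply(b, `[[`, "origin"))
  # empirical origin distribution is uniform over valid origins
  n <- 3000
  draws <- sample_training_patches(big, biglab, s8, n = n, seed = 11)
  for (ax in 1:3) {
    ori <- vapply(draws, function(q) q$origin[ax], integer(1))
    tab <- tabulate(ori, nbins = 33)
    expect_gt(chisq.test(tab)$p.value, 0.01)
  }
  expect_error(sample_training_patches(ph$image, ph$labels,
                                       patch_spec(size = 64, overlap = 0),
                                       1, 1),
               "smaller than patch")
})

test_that("dataset splitting honors holdout, ratio and determinism", {
  ids <- sprintf("d%03d", 1:388)
  sp <- split_spec(n_test_holdout = 49, seed = 5)
  s <- split_dataset(ids, sp)
  expect_length(s$test, 49)
  expect_length(s$val, 17)    # round(339 * 0.05)
  expect_length(s$train, 322)
  expect_setequal(c(s$train, s$val, s$test), ids)
  expect_identical(split_dataset(ids, sp), s)
  s0 <- split_dataset(ids, split_spec(n_test_holdout = 0, seed = 1))
  expect_length(s0$test, 0)
  expect_error(split_dataset(ids, split_spec(n_test_holdout = 388)),
               "holdout")
  expect_error(split_dataset(c("a", "a"), split_spec(n_test_holdout = 0)),
               "unique")
})

test_that("sliding windows tile every voxel for any stride", {
  for (n in c(48, 50, 73)) for (stride in c(4, 7, 16, 32)) {
    starts <- brainvol:::window_starts(n, 32, stride)
    cov <- integer(n)
    for (s in starts) cov[s:(s + 31)] <- cov[s:(s + 31)] + 1L
    expect_true(all(cov >= 1L))
    expect_lte(max(starts), n - 32 + 1)
  }
})

test_that("stitched segmentation is stride-invariant for a constant model", {
  nc <- network_config(n_levels = 2, base_channels = 2, n_labels = 3)
  m <- build_model(nc, seed = 1)
  # force a constant preference for class 2 through the head bias
  for (h in grep("^H.*\\.b$", names(m$params), value = TRUE))
    m$params[[h]] <- c(0, 0, 3)
  vol <- image_volume(array(rnorm(48^3), c(48, 48, 48)))
  for (ov in c(0, 16)) {
    seg <- sliding_window_segment(m, vol, patch_spec(size = 32, overlap = ov))
    expect_true(all(seg$labels == 2L))
  }
})

test_that("argmax ties break to the lowest label id", {
  nc <- network_config(n_levels = 2, base_channels = 2, n_labels = 3)
  m <- build_model(nc, seed = 1)  # zero heads: exact three-way tie
  vol <- image_volume(array(rnorm(32^3), c(32, 32, 32)))
  seg <- sliding_window_segment(m, vol, patch_spec(size = 32, overlap = 0))
  expect_true(all(seg$labels == 0L))
})

test_that("connected-component filtering keeps the largest component only", {
  lab <- array(0L, c(20, 20, 20))
  lab[2:11, 2:11, 2:11] <- 1L            # 1000-voxel blob
  lab[15:16, 15:16, 15] <- 1L            # 4-voxel speckle, wraps to bg
  lab[18, 18, 18] <- 1L                  # lone voxel
  lm <- label_map(lab)
  f <- connected_component_filter(lm)
  expect_equal(sum(f$labels == 1L), 1000)
  expect_equal(f$labels[15, 15, 15], 0L)
  # single-component maps are untouched
  single <- label_map(array(rep(c(0L, 1L), c(500, 500)), c(10, 10, 10)))
  expect_identical(connected_component_filter(single)$labels, single$labels)
  # equal-size components: the one containing the smallest linear index wins
  two <- array(0L, c(10, 10, 10))
  two[1:2, 1, 1] <- 1L
  two[9:10, 10, 10] <- 1L
  ft <- connected_component_filter(label_map(two))
  expect_equal(ft$labels[1, 1, 1], 1L)
  expect_equal(ft$labels[10, 10, 10], 0L)
  # never increases any label's count
  ph <- tiny_phantom(seed = 2)
  before <- tabulate(ph$labels$labels + 1L, 3)
  after <- tabulate(connected_component_filter(ph$labels)$labels + 1L, 3)
  expect_true(all(after[-1] <= before[-1]))
  # 6- vs 26-connectivity: a diagonal touch splits only under 6
  diagl <- array(0L, c(4, 4, 4))
  diagl[1, 1, 1] <- 1L; diagl[2, 2, 2] <- 1L; diagl[2, 2, 3] <- 1L
  f26 <- connected_component_filter(label_map(diagl), connectivity = 26)
  f6 <- connected_component_filter(label_map(diagl), connectivity = 6)
  expect_equal(sum(f26$labels == 1L), 3)
  expect_equal(sum(f6$labels == 1L), 2)
})

test_that("mapping back to the original grid preserves identity and volumes", {
  ph <- tiny_phantom(seed = 3, grid = 32)
  # identity: original already isotropic 1 mm, no padding
  back <- to_original_space(ph$labels, ph$image, crop_record = NULL)
  expect_identical(back$labels, ph$labels$labels)
  # pad then crop via the record
  pz <- zero_pad(ph$labels, 24)
  back2 <- to_original_space(pz$volume, ph$image, pz$crop_record)
  expect_identical(back2$labels, ph$labels$labels)
  # synthetic 1.2 mm original: resample to 1 mm and back, volumes within 5%
  lab12 <- label_map(ph$labels$labels, spacing = c(1.2, 1.2, 1.2),
                     scheme = ph$labels$scheme)
  orig <- image_volume(ph$image$data, spacing = c(1.2, 1.2, 1.2))
  iso <- resample_isotropic(lab12, 1)
  round_trip <- to_original_space(iso, orig, crop_record = NULL)
  for (l in 1:2) {
    v0 <- sum(lab12$labels == l) * 1.2^3
    v1 <- sum(round_trip$labels == l) * 1.2^3
    expect_lt(abs(v1 - v0) / v0, 0.05)
  }
  # nearest-neighbor mapping cannot invent labels
  expect_true(all(unique(as.vector(round_trip$labels)) %in%
                    unique(as.vector(lab12$labels))))
})
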