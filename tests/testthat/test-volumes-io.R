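test_that("domain type constructors enforce their invariants", {
  expect_error(image_volume(array(0, c(4, 4))), "3-D")
  expect_error(image_volume(array(0, c(4, 4, 4)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(image_volume(array(0, c(4, 4, 4)),
                            affine = matrix(0, 4, 4)), "invertible")
  expect_error(label_map(array(-1L, c(2, 2, 2))), "non-negative")
  sch <- default_label_scheme()
  expect_error(label_map(array(99L, c(2, 2, 2)), scheme = sch),
               "absent from scheme: 99")
  expect_error(label_scheme(data.frame(label = c(1, 1), roi = "a",
                                       hemisphere = "L")), "duplicate")
  expect_setequal(unique(sch$entries$roi), c(roi_names(), "other"))
  expect_equal(nrow(sch$entries), 17)
})

test_that("NIfTI round-trips preserve data, spacing and affine", {
  withr::local_seed(1)
  arr <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  aff <- diag(c(1.5, 1.5, 2, 1)); aff[1:3, 4] <- c(-10, 5, 3)
  vol <- image_volume(arr, spacing = c(1.5, 1.5, 2), affine = aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(vol, f)
  back <- read_nifti(f)
  expect_equal(back$data, arr, ignore_attr = TRUE)
  expect_equal(back$spacing, c(1.5, 1.5, 2))
  expect_equal(unname(back$affine), unname(aff), tolerance = 1e-6)
  # integer label maps round-trip bit exactly
  lab <- label_map(array(sample(0:16, 5^3, TRUE), c(5, 5, 5)),
                   spacing = c(2, 2, 2))
  f2 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(lab, f2)
  back2 <- read_nifti(f2, as_labels = TRUE)
  expect_identical(back2$labels, lab$labels)
  expect_error(write_nifti(vol, "x.txt"), "\\.nii")
  expect_error(read_nifti("does_not_exist.nii"), "not found")
})

test_that("reading a 4-D file is rejected", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, f)
  expect_error(read_nifti(f), "3-D")
})

test_that("ROI volumes follow count x voxel-volume / 1000", {
  sch <- label_scheme(data.frame(label = 1:2,
                                 roi = c("hippocampus", "hippocampus"),
                                 hemisphere = c("L", "R")))
  lab <- array(0L, c(20, 20, 20))
  lab[seq_len(1000)] <- 1L                      # 1000 voxels
  lm1 <- label_map(lab, spacing = c(1, 1, 1), scheme = sch)
  t1 <- compute_roi_volumes(lm1, sch)
  expect_equal(t1$volume_ml[t1$roi == "hippocampus" & t1$hemisphere == "L"], 1)
  # empty label still gets a zero row
  expect_equal(t1$volume_ml[t1$roi == "hippocampus" & t1$hemisphere == "R"], 0)
  # 100 voxels at 2 mm isotropic: 100 x 8 mm3 = 0.8 mL
  lab2 <- array(0L, c(10, 10, 10)); lab2[seq_len(100)] <- 1L
  lm2 <- label_map(lab2, spacing = c(2, 2, 2), scheme = sch)
  t2 <- compute_roi_volumes(lm2, sch)
  expect_equal(t2$volume_ml[t2$roi == "hippocampus" & t2$hemisphere == "L"],
               0.8)
  # ICV row equals union of icv labels (default: all nonzero)
  expect_equal(t2$volume_ml[t2$roi == "icv"], 0.8)
  expect_error(compute_roi_volumes(label_map(array(3L, c(2, 2, 2))), sch),
               "absent from scheme")
})

test_that("volume bookkeeping conserves the grid", {
  withr::local_seed(2)
  sch <- default_label_scheme()
  lab <- array(sample(0:17, 12^3, TRUE, prob = c(5, rep(1, 17))) - 0L,
               c(12, 12, 12))
  lab[lab == 17L] <- 0L  # keep labels within 1..16 plus background
  lm <- label_map(lab, spacing = c(1.2, 0.9, 1.1), scheme = sch)
  tab <- compute_roi_volumes(lm, sch)
  grid_ml <- prod(dim(lab)) * prod(lm$spacing) / 1000
  fg_ml <- sum(tab$volume_ml[tab$roi != "icv"])
  bg_ml <- sum(lab == 0L) * prod(lm$spacing) / 1000
  expect_equal(fg_ml + bg_ml, grid_ml, tolerance = 1e-12)
})

test_that("label aggregation merges groups and conserves voxel counts", {
  fine <- label_scheme(data.frame(
    label = c(3L, 8L, 5L),
    roi = c("hippocampus", "hippocampus", "insula"),
    hemisphere = c("L", "L", "R")))
  lab <- array(0L, c(6, 6, 6))
  lab[1:40] <- 3L; lab[41:70] <- 8L; lab[71:80] <- 5L
  lm <- label_map(lab, scheme = fine)
  agg <- aggregate_labels(lm, fine)
  expect_equal(sum(agg$labels != 0L), sum(lab != 0L))
  hip <- agg$scheme$entries$label[agg$scheme$entries$roi == "hippocampus"]
  expect_length(hip, 1)
  expect_equal(sum(agg$labels == hip), 70)
  # identity scheme: map unchanged up to relabeling by group
  ident <- label_scheme(data.frame(label = 1:2, roi = c("a", "b"),
                                   hemisphere = c("L", "R")))
  lab2 <- array(rep(0:2, each = 8), c(2, 3, 4))
  agg2 <- aggregate_labels(label_map(lab2, scheme = ident), ident)
  expect_identical(agg2$labels, lab2)
  expect_error(aggregate_labels(lm, ident), "absent from scheme")
})

test_that("ROI tables validate and round-trip through CSV", {
  tab <- compute_roi_volumes(
    label_map(array(1L, c(4, 4, 4)),
              scheme = label_scheme(data.frame(label = 1, roi = "frontal",
                                               hemisphere = "L"))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_roi_table(tab, f)
  back <- read_roi_table(f)
  expect_equal(back$volume_ml, tab$volume_ml)
  expect_true(is.na(back$hemisphere[back$roi == "icv"]))
  bad <- rbind(tab, tab[1, ])
  expect_error(write_roi_table(bad, f), "duplicate")
})
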