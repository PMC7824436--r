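test_that("nested topology has the expected node and head counts", {
  for (L in 2:4) {
    nc <- network_config(n_levels = L, base_channels = 2, n_labels = 3)
    m <- build_model(nc, seed = 1)
    nodes <- unique(sub("\\.(u1|u2|up|sk[0-9]+)\\..*$", "",
                        grep("^X", names(m$params), value = TRUE)))
    expect_length(nodes, L * (L + 1) / 2)
    heads <- unique(sub("\\..*$", "", grep("^H", names(m$params),
                                           value = TRUE)))
    expect_length(heads, L - 1)
  }
  # deep supervision off: a single head at the deepest top-row node
  m1 <- build_model(network_config(n_levels = 4, base_channels = 2,
                                   n_labels = 2, deep_supervision = FALSE),
                    seed = 1)
  expect_equal(unique(sub("\\..*$", "", grep("^H", names(m1$params),
                                             value = TRUE))), "H3")
})

test_that("forward pass emits a probability simplex at the input shape", {
  nc <- network_config(n_levels = 2, base_channels = 4, n_labels = 3)
  m <- build_model(nc, seed = 2)
  p <- predict_patch(m, array(0, c(8, 8, 8)), head = "last")
  expect_equal(dim(p), c(8, 8, 8, 3))
  expect_true(all(is.finite(p)))
  expect_equal(apply(p, 1:3, sum), array(1, c(8, 8, 8)), tolerance = 1e-5)
  # every head produces the input shape
  f <- brainvol:::unet_forward(m, array(rnorm(8^3), c(8, 8, 8)))
  for (h in f$heads) expect_equal(dim(h)[1:3], c(8, 8, 8))
  expect_error(predict_patch(m, array(0, c(8, 8, 8)), head = 9),
               "unknown head")
  expect_error(brainvol:::unet_forward(m, array(0, c(7, 7, 7))),
               "divisible")
})

test_that("training reduces the loss and is seed-deterministic", {
  withr::local_seed(3)
  # tiny intensity-separable task
  pairs <- lapply(1:4, function(i) {
    lab <- array(0L, c(16, 16, 16))
    lab[4:12, 4:12, 4:12] <- 1L
    img <- array(rnorm(16^3, 10 + 60 * lab, 6), c(16, 16, 16))
    list(image = img, labels = lab)
  })
  nc <- network_config(n_levels = 2, base_channels = 4, n_labels = 2)
  tc <- train_config(n_iterations = 40, patch_size = 16, seed = 9)
  m <- train_model(build_model(nc, seed = 9), pairs, tc)
  expect_equal(nrow(m$training_log), 40)
  expect_true(all(is.finite(m$training_log$loss)))
  expect_lt(mean(tail(m$training_log$loss, 10)),
            mean(head(m$training_log$loss, 10)))
  m2 <- train_model(build_model(nc, seed = 9), pairs, tc)
  expect_identical(m$training_log$loss, m2$training_log$loss)
  expect_identical(m$params, m2$params)
})

test_that("zero learning rate leaves parameters untouched", {
  pairs <- list(list(image = array(rnorm(8^3), c(8, 8, 8)),
                     labels = array(0L, c(8, 8, 8))))
  nc <- network_config(n_levels = 2, base_channels = 2, n_labels = 2)
  m0 <- build_model(nc, seed = 4)
  m <- train_model(m0, pairs,
                   train_config(learning_rate = 0, n_iterations = 5,
                                patch_size = 8, seed = 1,
                                prior_bias_init = FALSE))
  expect_identical(m$params, m0$params)
  # with prior initialization on, only the head biases may differ
  m2 <- train_model(m0, pairs,
                    train_config(learning_rate = 0, n_iterations = 5,
                                 patch_size = 8, seed = 1))
  keep <- setdiff(names(m0$params), grep("^H.*\\.b$", names(m0$params),
                                         value = TRUE))
  expect_identical(m2$params[keep], m0$params[keep])
})

test_that("single-class targets drive the loss to the class log-probability", {
  withr::local_seed(5)
  pairs <- list(list(image = array(rnorm(8^3, 50, 5), c(8, 8, 8)),
                     labels = array(1L, c(8, 8, 8))))
  nc <- network_config(n_levels = 2, base_channels = 4, n_labels = 2)
  tc <- train_config(n_iterations = 60, patch_size = 8, seed = 2)
  m <- train_model(build_model(nc, seed = 2), pairs, tc)
  final <- tail(m$training_log$loss, 1)
  expect_lt(final, m$training_log$loss[1])
  p <- predict_patch(m, pairs[[1]]$image)
  expect_lt(abs(final - mean(-log(p[, , , 2]))), 0.02)
})

test_that("labels outside the class range are rejected before training", {
  pairs <- list(list(image = array(0, c(8, 8, 8)),
                     labels = array(5L, c(8, 8, 8))))
  nc <- network_config(n_levels = 2, base_channels = 2, n_labels = 2)
  expect_error(train_model(build_model(nc, seed = 1), pairs,
                           train_config(n_iterations = 1, patch_size = 8,
                                        seed = 1)),
               "n_labels")
})

test_that("checkpoints round-trip through save/load with a JSON sidecar", {
  nc <- network_config(n_levels = 2, base_channels = 2, n_labels = 2)
  m <- build_model(nc, seed = 6)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$config$n_levels, 2)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
})
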