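small_cfg <- function(...) {
  network_config(depth = 2, base_channels = 4, ...)
}

test_that("model construction follows the nested-grid contracts", {
  m <- build_model(small_cfg(), seed = 1)
  # node count of the nested topology is d(d+1)/2
  expect_equal(model_node_count(m), 3L)
  m3 <- build_model(network_config(depth = 3, base_channels = 4), seed = 1)
  expect_equal(model_node_count(m3), 6L)
  m5 <- build_model(network_config(depth = 5, base_channels = 2), seed = 1)
  expect_equal(model_node_count(m5), 15L)
  # channel conservation holds for every layer
  tab <- model_layer_table(m3)
  expect_true(all(tab$cout_high + tab$cout_low == tab$cout_total))
  # two builds from the same seed are bit-identical
  a <- build_model(small_cfg(), seed = 7)
  b <- build_model(small_cfg(), seed = 7)
  for (nm in names(a$params)) {
    expect_identical(a$params[[nm]]$value, b$params[[nm]]$value)
  }
  expect_error(network_config(depth = 1), "depth")
})

test_that("alpha = 0 degrades the octave grid to a plain-convolution network", {
  m <- build_model(small_cfg(alpha = 0), seed = 1)
  tab <- model_layer_table(m)
  expect_true(all(tab$cin_low == 0))
  expect_true(all(tab$cout_low == 0))
  # forward still works
  p <- predict_prob(m, matrix(0.5, 16, 16))
  expect_equal(dim(p), c(16, 16))
})

test_that("forward pass preserves shape, range and determinism", {
  m <- build_model(small_cfg(), seed = 2)
  img <- matrix(runif(16 * 16), 16, 16)
  p1 <- predict_prob(m, img)
  expect_equal(dim(p1), c(16, 16))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict_prob(m, img))
  # zero image is valid
  p0 <- predict_prob(m, matrix(0, 16, 16))
  expect_true(all(is.finite(p0)))
  # non-multiple sizes are letterboxed and cropped back
  img2 <- matrix(runif(15 * 18), 15, 18)
  expect_equal(dim(predict_prob(m, img2)), c(15, 18))
  expect_error(predict_prob(m, matrix(2, 8, 8)), "\\[0, 1\\]")
})

test_that("predict_mask thresholds monotonically", {
  expect_true(all(predict_mask(matrix(1, 3, 3))))
  expect_false(any(predict_mask(matrix(0, 3, 3))))
  set.seed(502)
  p <- matrix(runif(64), 8, 8)
  prev <- predict_mask(p, 0)
  for (th in seq(0.1, 1, by = 0.1)) {
    cur <- predict_mask(p, th)
    expect_true(all(prev | !cur)) # masks only shrink as threshold rises
    prev <- cur
  }
  expect_error(predict_mask(p, 1.5), "threshold")
})

test_that("training runs, is seeded-deterministic, and decreases the loss", {
  set.seed(503)
  mk <- function() {
    img <- matrix(runif(256), 16, 16)
    msk <- matrix(FALSE, 16, 16)
    msk[5:12, 5:12] <- TRUE
    img[msk] <- img[msk] * 0.2
    list(image = img, mask = msk)
  }
  data <- list(mk(), mk())
  m1 <- train_model(build_model(small_cfg(), seed = 3), data,
                    epochs = 1, seed = 3)
  expect_true(all(is.finite(m1$history$loss)))
  expect_equal(nrow(m1$history), 1L)
  # same seed, same data: identical history and parameters
  m2 <- train_model(build_model(small_cfg(), seed = 3), data,
                    epochs = 1, seed = 3)
  expect_identical(m1$history, m2$history)
  expect_identical(lapply(m1$params, function(p) p$value),
                   lapply(m2$params, function(p) p$value))
  # moving-average loss decreases over the first 20 steps at overfit scale
  m3 <- train_model(build_model(small_cfg(), seed = 4), data,
                    epochs = 12, seed = 4, val_every = 100)
  sl <- m3$step_losses
  ma <- stats::filter(sl, rep(1 / 4, 4), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[min(20, length(ma))], ma[1])
  expect_error(train_model(build_model(small_cfg(), seed = 1), list()),
               "empty")
})

test_that("a scaled-down model can memorize four phantom images", {
  # the standard overfit oracle: training AOM >= 0.95 within ~300 steps
  cfg <- phantom_config(height = 64, width = 64,
                        chamber_axes = c(14, 10), n_frames = 4,
                        cycle_frames = 4, seed = 77)
  ph <- generate_sequence(cfg)
  data <- phantom_pairs(list(ph))
  m <- build_model(network_config(depth = 2, base_channels = 8), seed = 77)
  m <- train_model(m, data, loss = "tversky_focal", epochs = 60,
                   lr = 3e-3, seed = 77, val_every = 20)
  expect_gte(utils::tail(m$history$val_aom, 1), 0.95)
})
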