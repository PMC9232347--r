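test_that("maximum-intensity projection equals the per-pixel maximum", {
  # single frame: projection is the frame itself
  f <- matrix(runif(12), 3, 4)
  expect_identical(max_intensity_projection(list(f)), f)

  # two-frame worked example (intensities scaled into [0, 1])
  a <- matrix(c(1, 3, 2, 0) / 5, 2, 2)
  b <- matrix(c(0, 2, 4, 5) / 5, 2, 2)
  expect_equal(max_intensity_projection(list(a, b)),
               matrix(c(1, 3, 4, 5) / 5, 2, 2))

  # seeded random stack vs brute-force loop oracle
  set.seed(11)
  frames <- replicate(5, matrix(runif(64), 8, 8), simplify = FALSE)
  expect_equal(max_intensity_projection(frames), oracle_mip(frames))
})

test_that("projection is permutation-invariant, monotone, and idempotent", {
  set.seed(12)
  frames <- replicate(6, matrix(runif(100), 10, 10), simplify = FALSE)
  proj <- max_intensity_projection(frames)
  for (rep in 1:5) {
    expect_identical(max_intensity_projection(sample(frames)), proj)
  }
  # adding a frame never decreases any pixel
  more <- c(frames, list(matrix(runif(100), 10, 10)))
  expect_true(all(max_intensity_projection(more) >= proj))
  # every frame is dominated by the projection
  for (f in frames) expect_true(all(proj >= f))
  # projecting the projection returns it unchanged
  expect_identical(max_intensity_projection(list(proj)), proj)
})

test_that("projection rejects empty or mismatched sequences", {
  expect_error(max_intensity_projection(list()), "empty")
  expect_error(
    max_intensity_projection(list(matrix(0, 2, 2), matrix(0, 3, 3))),
    "same height")
  expect_error(echo_sequence(list()), "at least one frame")
  expect_error(echo_sequence(list(matrix(c(0, NA, 0, 0), 2, 2))), "finite")
})

test_that("sequence normalization min-max rescales over the whole sequence", {
  frames <- list(matrix(c(2, 4, 6, 8), 2, 2), matrix(c(4, 6, 8, 12), 2, 2))
  seq <- echo_sequence(frames)
  vals <- unlist(seq$frames)
  expect_equal(min(vals), 0)
  expect_equal(max(vals), 1)
  # inter-frame relations preserved: frame 2 still brighter where it was
  expect_equal(seq$frames[[1]], (frames[[1]] - 2) / 10)
})

test_that("thresholding separates a bimodal image and matches the Otsu oracle", {
  # well-separated modes: exactly the bright region is foreground
  img <- matrix(0.05, 20, 20)
  img[5:15, 5:15] <- 0.9
  th <- threshold_projection(img)
  expect_identical(matrix(th, nrow(th)), img >= 0.5)

  # degenerate constant image: warning and full foreground
  expect_warning(thc <- threshold_projection(matrix(0, 4, 4)), "constant")
  expect_true(all(thc))

  # seeded two-Gaussian mixture vs exhaustive 256-bin oracle
  set.seed(21)
  mix <- matrix(pmin(pmax(c(rnorm(300, 0.25, 0.06), rnorm(300, 0.75, 0.06)), 0), 1),
                20, 30)
  got <- threshold_projection(mix)
  expect_equal(matrix(got, nrow(got)), mix >= oracle_otsu(mix))
})

test_that("sector refinement fills holes, keeps the largest component, stays connected", {
  # quarter-disk with small punched holes: closing repairs them
  h <- 60
  yy <- row(matrix(0, h, h)); xx <- col(matrix(0, h, h))
  disk <- (yy^2 + xx^2) <= 45^2
  set.seed(31)
  holes <- cbind(sample(5:35, 20, TRUE), sample(5:35, 20, TRUE))
  raw <- disk
  raw[holes] <- FALSE
  ref <- refine_sector(raw, radius = 5)
  expect_equal(count_components(ref$mask), 1L)
  expect_true(all(ref$mask[holes]))

  # largest-component rule: the 10 px blob dies, the big one survives
  two <- matrix(FALSE, 50, 50)
  two[5:36, 5:36] <- TRUE   # ~1000 px
  two[45:46, 45:49] <- TRUE # 10 px
  ref2 <- refine_sector(two, radius = 1)
  expect_false(any(ref2$mask[45:46, 45:49]))
  expect_true(any(ref2$mask[10, 10]))
  expect_equal(count_components(ref2$mask), 1L)

  # seeded noisy sector: always exactly one component (checked by BFS oracle)
  ph <- generate_sequence(phantom_config(seed = 5))
  det <- detect_sector(ph)
  expect_equal(oracle_count_components(det$sector$mask), 1L)

  expect_error(refine_sector(matrix(FALSE, 4, 4)), "no foreground")
})

test_that("8-connected labelling agrees with the BFS oracle", {
  set.seed(33)
  for (i in 1:10) {
    m <- random_mask(12, 12, p = 0.35)
    expect_equal(count_components(m), oracle_count_components(m, 8))
  }
})

test_that("apply_sector zeroes outside and preserves inside", {
  set.seed(41)
  f <- matrix(runif(400), 20, 20)
  half <- matrix(FALSE, 20, 20)
  half[, 1:10] <- TRUE
  sec <- structure(list(mask = half, area_px = sum(half)), class = "sector_mask")
  out <- apply_sector(f, sec)
  expect_identical(out[, 1:10], f[, 1:10])
  expect_true(all(out[, 11:20] == 0))
  # all-true sector is the identity
  expect_identical(apply_sector(f, matrix(TRUE, 20, 20)), f)
  expect_error(apply_sector(f, matrix(TRUE, 5, 5)), "shapes differ")
  # an all-false mask cannot be a sector
  expect_error(refine_sector(matrix(FALSE, 3, 3)))
})
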