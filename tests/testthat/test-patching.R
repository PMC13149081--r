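# Shift-window patch grids, extraction, and crop-and-stitch aggregation.

test_that("overlap_fraction reproduces the analytic overlap rule", {
  expect_equal(overlap_fraction(48, 12), 75)
  for (s in c(5, 16, 48, 240)) expect_equal(overlap_fraction(s, s), 0)
  expect_equal(overlap_fraction(48, 6), 87.5)
  expect_equal(round(overlap_fraction(48, 4), 2), 91.67)
  expect_error(overlap_fraction(48, 49), "stride")
  expect_error(overlap_fraction(48, 0), "stride")
  # default-stride rule: stride = size/4 gives 75% for any size
  for (s in c(16, 32, 48, 64, 96, 128, 192, 240)) {
    expect_equal(overlap_fraction(s, s / 4), 75)
  }
  # strictly decreasing in stride
  expect_true(all(diff(overlap_fraction(48, 1:48)) < 0))
})

test_that("build_grid tiles the bounding box with a clamped final origin", {
  g <- build_grid(c(0L, 0L, 96L, 96L), c(240L, 240L), 48L, 12L)
  expect_equal(nrow(g$origins), 25L)
  expect_equal(sort(unique(g$origins[, 1])), seq(0, 48, by = 12))

  g1 <- build_grid(c(0L, 0L, 48L, 48L), c(240L, 240L), 48L, 12L)
  expect_equal(nrow(g1$origins), 1L)

  g2 <- build_grid(c(0L, 0L, 50L, 48L), c(240L, 240L), 48L, 12L)
  expect_equal(nrow(g2$origins), 2L)
  expect_equal(sort(g2$origins[, 1]), c(0L, 2L))  # clamped second origin

  # small masks are inflated to one full patch containing the region
  mask <- matrix(FALSE, 64, 64)
  mask[30:38, 28:34] <- TRUE
  gm <- build_grid(mask, c(64L, 64L), 48L, 12L)
  expect_equal(nrow(gm$origins), 1L)
  o <- gm$origins[1, ]
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] > o[1] &
                    which(mask, arr.ind = TRUE)[, 1] <= o[1] + 48))

  # every region pixel inside >= 1 patch
  covered <- matrix(FALSE, 64, 64)
  for (i in seq_len(nrow(gm$origins))) {
    oo <- gm$origins[i, ]
    covered[oo[1] + 1:48, oo[2] + 1:48] <- TRUE
  }
  expect_true(all(covered[mask]))

  expect_error(build_grid(matrix(FALSE, 20, 20), c(20L, 20L), 8L, 4L),
               "empty")
  expect_error(build_grid(c(0L, 0L, 30L, 30L), c(20L, 20L), 8L, 4L),
               "larger")
})

test_that("extract_patches cuts channel-complete patches and labels identically", {
  vol <- tiny_volume(60L, 60L, seq(-1, 1, by = 0.5))
  g <- build_grid(c(0L, 0L, 60L, 60L), c(60L, 60L), 24L, 12L)
  labs <- matrix(seq_len(3600), 60, 60)
  ps <- extract_patches(vol, g, labels = labs)
  expect_length(ps$patches, nrow(g$origins))
  expect_true(all(sapply(ps$patches, function(p) all(dim(p) == c(24, 24, 5)))))
  # pure cropping: a pixel covered by several patches has identical values
  for (i in seq_along(ps$patches)) {
    o <- g$origins[i, ]
    expect_identical(ps$patches[[i]],
                     vol$data[o[1] + 1:24, o[2] + 1:24, , drop = FALSE])
    expect_identical(ps$label_patches[[i]], labs[o[1] + 1:24, o[2] + 1:24])
  }
  expect_error(extract_patches(vol, g, labels = matrix(0, 10, 10)),
               "extent")
})

test_that("aggregate_patches averages central windows, matching the dense oracle", {
  # constant predictions aggregate to the constant
  mask <- matrix(FALSE, 64, 64)
  mask[8:56, 10:58] <- TRUE
  g <- build_grid(mask, c(64L, 64L), 24L, 8L)
  preds <- constant_predictions(g, 0.8)
  m <- aggregate_patches(preds, g, crop = 8L)
  expect_equal(unique(as.vector(m$data[, , 2][m$valid])), 0.8)
  expect_true(all(abs(m$data[, , 1] + m$data[, , 2] - 1)[m$valid] < 1e-12))

  # single patch, crop 0: identity
  g1 <- build_grid(c(0L, 0L, 24L, 24L), c(64L, 64L), 24L, 24L)
  p1 <- list(array(runif(24 * 24 * 2), c(24, 24, 2)))
  m1 <- aggregate_patches(p1, g1, crop = 0L)
  expect_equal(m1$data[1:24, 1:24, ], p1[[1]])
  expect_true(all(is.na(m1$data[30, 30, ])))
  expect_false(m1$valid[30, 30])

  # random predictions vs. cell-by-cell brute-force accumulator
  set.seed(5)
  preds <- lapply(seq_len(nrow(g$origins)), function(i)
    array(runif(24 * 24 * 2), c(24, 24, 2)))
  m2 <- aggregate_patches(preds, g, crop = 8L)
  oracle <- aggregate_bruteforce(preds, g, crop = 8L)
  expect_equal(m2$data, oracle, tolerance = 1e-12)

  # two half-overlapping patches: overlap zone is the plain average
  gh <- build_grid(c(0L, 0L, 36L, 24L), c(64L, 64L), 24L, 12L)
  expect_equal(nrow(gh$origins), 2L)
  ph <- list(array(0.2, c(24, 24, 2)), array(0.6, c(24, 24, 2)))
  mh <- aggregate_patches(ph, gh, crop = 0L)
  expect_equal(unique(as.vector(mh$data[13:24, 1:24, 1])), 0.4)

  expect_error(aggregate_patches(preds, g, crop = 12L), "crop")
})

test_that("extract -> aggregate with the identity predictor reconstructs the input", {
  vol <- tiny_volume(64L, 64L, c(0, 1))
  mask <- matrix(FALSE, 64, 64)
  mask[5:65 - 1, 12:60] <- TRUE
  g <- build_grid(mask, c(64L, 64L), 24L, 8L)
  ps <- extract_patches(vol, g)
  m <- aggregate_patches(ps$patches, g, crop = 8L)
  bb <- g$bbox
  inside <- matrix(FALSE, 64, 64)
  inside[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]] <- TRUE
  expect_true(all(m$valid[inside]))
  for (k in 1:2) {
    expect_equal(m$data[, , k][inside], vol$data[, , k][inside],
                 tolerance = 1e-12)
  }
})
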