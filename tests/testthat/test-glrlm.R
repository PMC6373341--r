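test_that("quantization follows fixed-bin-number edges", {
  img <- voxel_grid(array(0:255, c(256, 1, 1)))
  msk <- binary_mask(array(TRUE, c(256, 1, 1)))
  q <- quantize(img, msk, 32)
  expect_equal(sort(unique(as.vector(q))), 1:32)
  expect_equal(which(q[, 1, 1] == 1L), 1:8)      # intensities 0..7
  expect_equal(q[256, 1, 1], 32L)                # max maps to top level
  # constant ROI collapses to level 1
  cimg <- voxel_grid(array(5, c(4, 4, 4)))
  cq <- quantize(cimg, binary_mask(array(TRUE, c(4, 4, 4))), 32)
  expect_true(all(cq == 1L))
  expect_error(quantize(img, msk, 1), "at least 2")
})

test_that("quantization is invariant under bin-edge-preserving transforms", {
  set.seed(5)
  img <- voxel_grid(array(runif(64, 0, 1), c(4, 4, 4)))
  msk <- binary_mask(array(TRUE, c(4, 4, 4)))
  q1 <- quantize(img, msk, 8)
  img2 <- img; img2$values <- 10 + 3 * img$values  # affine: same bin edges
  expect_identical(q1, quantize(img2, msk, 8))
})

test_that("the hand-enumerated 1D example reproduces exactly", {
  q <- array(0L, c(5, 1, 1)); q[, 1, 1] <- c(1L, 1L, 2L, 2L, 2L)
  m <- build_glrlm(q, c(1, 0, 0), n_levels = 2)
  expect_equal(m[1, 2], 1L)  # one run of level 1, length 2
  expect_equal(m[2, 3], 1L)  # one run of level 2, length 3
  expect_equal(attr(m, "Nr"), 2L)
  expect_equal(attr(m, "Np"), 5L)
  f <- rlm_features(m)
  expect_equal(f[["sre"]], (1 / 4 + 1 / 9) / 2, tolerance = 1e-12)
  expect_equal(f[["rperc"]], 0.4, tolerance = 1e-12)
  expect_equal(f[["glnu"]], 1, tolerance = 1e-12)
  expect_equal(f[["lre"]], (4 + 9) / 2, tolerance = 1e-12)
})

test_that("degenerate and alternating patterns behave as enumerated", {
  # single voxel: one run of length 1
  q <- array(0L, c(3, 3, 3)); q[2, 2, 2] <- 1L
  m <- build_glrlm(q, c(1, 0, 0), n_levels = 1)
  expect_equal(attr(m, "Nr"), 1L)
  expect_equal(m[1, 1], 1L)
  # checkerboard along the direction: all runs have length 1
  q2 <- array(0L, c(8, 1, 1)); q2[, 1, 1] <- rep(c(1L, 2L), 4)
  m2 <- build_glrlm(q2, c(1, 0, 0), n_levels = 2)
  expect_equal(attr(m2, "Nr"), 8L)
  expect_equal(ncol(m2), 1L)
  # single-level run of length L: closed forms
  q3 <- array(0L, c(6, 1, 1)); q3[, 1, 1] <- 1L
  f3 <- rlm_features(build_glrlm(q3, c(1, 0, 0), n_levels = 1))
  expect_equal(f3[["sre"]], 1 / 36)
  expect_equal(f3[["lre"]], 36)
  expect_equal(f3[["rperc"]], 1 / 6)
})

test_that("zero directions are rejected", {
  q <- array(1L, c(2, 2, 2))
  expect_error(build_glrlm(q, c(0, 0, 0)), "non-zero")
})

test_that("run counting agrees exactly with the brute-force enumerator", {
  set.seed(101)
  dirs <- glrlm_directions()
  for (rep in 1:6) {
    q <- array(0L, c(6, 6, 6))
    roi <- array(runif(216) < 0.6, c(6, 6, 6))
    q[roi] <- sample(1:4, sum(roi), replace = TRUE)
    for (d in seq_len(nrow(dirs))) {
      got <- build_glrlm(q, dirs[d, ], n_levels = 4)
      want <- brute_glrlm(q, dirs[d, ], n_levels = 4)
      expect_equal(unclass(got)[, seq_len(ncol(want)), drop = FALSE],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("voxel conservation holds in every direction for random ROIs", {
  set.seed(55)
  dirs <- glrlm_directions()
  for (rep in 1:5) {
    q <- array(0L, c(7, 5, 6))
    roi <- array(runif(210) < 0.5, c(7, 5, 6))
    q[roi] <- sample(1:3, sum(roi), replace = TRUE)
    np <- sum(roi)
    if (np == 0) next
    for (d in seq_len(nrow(dirs))) {
      m <- build_glrlm(q, dirs[d, ], n_levels = 3)
      expect_equal(sum(m * col(m)), np)
    }
  }
})

test_that("feature bounds and homogenisation direction hold", {
  set.seed(77)
  img <- voxel_grid(array(rnorm(1000, 100, 15), c(10, 10, 10)))
  msk <- binary_mask(array(runif(1000) < 0.7, c(10, 10, 10)))
  f <- rlm_features(lapply(seq_len(13), function(d)
    build_glrlm(quantize(img, msk, 16), glrlm_directions()[d, ], 16)))
  expect_lte(f[["sre"]], 1)
  expect_gt(f[["rperc"]], 0)
  expect_lte(f[["rperc"]], 1)
  # homogenising (all voxels one level) never decreases lre
  homog <- img; homog$values[] <- 100
  fh <- rlm_features(lapply(seq_len(13), function(d)
    build_glrlm(quantize(homog, msk, 16), glrlm_directions()[d, ], 16)))
  expect_gte(fh[["lre"]], f[["lre"]])
  expect_lte(fh[["rperc"]], f[["rperc"]])
})

test_that("mean-over-directions aggregation matches a manual mean", {
  set.seed(31)
  img <- voxel_grid(array(rnorm(343, 50, 8), c(7, 7, 7)))
  msk <- binary_mask(array(runif(343) < 0.8, c(7, 7, 7)))
  q <- quantize(img, msk, 8)
  dirs <- glrlm_directions()
  mats <- lapply(seq_len(nrow(dirs)), function(d)
    build_glrlm(q, dirs[d, ], n_levels = 8))
  agg <- rlm_features(mats)
  per <- sapply(mats, function(m) rlm_features(m))
  expect_equal(agg, rowMeans(per), tolerance = 1e-12)
})
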