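test_that("read_pair binarizes labels and rejects mismatched grids", {
  dir <- withr::local_tempdir()
  img <- volume_grid(array(rnorm(4 * 5 * 3), c(4, 5, 3)), c(1, 1, 2))
  lab <- array(0L, c(4, 5, 3)); lab[2:3, 2:3, 2] <- 2L
  msk <- roi_mask(lab, c(1, 1, 2))
  write_pair(img, msk, file.path(dir, "i.nii.gz"), file.path(dir, "m.nii.gz"))
  pr <- read_pair(file.path(dir, "i.nii.gz"), file.path(dir, "m.nii.gz"))
  expect_setequal(unique(as.vector(pr$mask$values)), c(0L, 1L))
  expect_equal(pr$image$values, img$values, tolerance = 0)

  bad <- roi_mask(array(1L, c(3, 5, 3)), c(1, 1, 2))
  expect_error(radrobust:::check_same_grid(img, bad), "geometry")
})

test_that("identity resampling with NN leaves an isotropic image unchanged", {
  v <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  img <- volume_grid(v, c(2, 2, 2))
  m <- array(0L, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- 1L
  msk <- roi_mask(m, c(2, 2, 2))
  rp <- resample_pair(img, msk, preproc_setting(2, "NN", 5))
  expect_equal(rp$image$values, v, tolerance = 0)
  expect_identical(rp$mask$values, m)
})

test_that("every interpolator reproduces a constant image", {
  v <- array(42, c(8, 8, 6))
  img <- volume_grid(v, c(1.1, 1.1, 2.5))
  m <- array(0L, c(8, 8, 6)); m[3:6, 3:6, 2:5] <- 1L
  msk <- roi_mask(m, c(1.1, 1.1, 2.5))
  for (ip in interpolators()) {
    rp <- resample_pair(img, msk, preproc_setting(1.5, ip, 5))
    expect_equal(max(abs(rp$image$values - 42)), 0, tolerance = 1e-9,
                 label = paste("constant under", ip))
    expect_gt(sum(rp$mask$values), 0)
  }
})

test_that("linear and B-spline resampling of a ramp match the analytic ramp", {
  # HU = x coordinate (mm)
  nd <- c(21, 9, 9)
  xs <- (seq_len(nd[1]) - 1) * 1.0
  v <- array(rep(xs, times = prod(nd[2:3])), nd)
  img <- volume_grid(v, c(1, 1, 1))
  msk <- roi_mask(array(1L, nd), c(1, 1, 1))
  # trilinear is exact on a linear field; the B-spline interpolant is exact
  # up to the mirror-boundary influence, which decays geometrically inward
  for (ip in c("L", "BS")) {
    rp <- resample_pair(img, msk, preproc_setting(2, ip, 5))
    out <- rp$image
    ox <- out$origin[1] + (seq_len(dim(out$values)[1]) - 1) * out$spacing[1]
    interior <- ox > 5 & ox < max(xs) - 5
    got <- out$values[interior, ceiling(dim(out$values)[2] / 2),
                      ceiling(dim(out$values)[3] / 2)]
    expect_equal(got, ox[interior],
                 tolerance = if (ip == "BS") 1e-3 else 1e-8,
                 label = paste("ramp under", ip))
  }
})

test_that("mask resampling is nearest-neighbor regardless of interpolator", {
  spec <- toy_spec(seed = 3)
  s <- make_subject(spec, 0)
  masks <- lapply(interpolators(), function(ip) {
    resample_pair(s$image, s$mask, preproc_setting(1.9, ip, 5))$mask$values
  })
  for (k in 2:length(masks)) expect_identical(masks[[k]], masks[[1]])
})

test_that("resegmentation keeps the boundary value and drops strictly-below voxels", {
  v <- array(0, c(3, 1, 1)); v[, 1, 1] <- c(-600, -500, 0)
  img <- volume_grid(v, c(1, 1, 1))
  msk <- roi_mask(array(1L, c(3, 1, 1)), c(1, 1, 1))
  rs <- resegment(img, msk, -500)
  expect_identical(as.vector(rs$values), c(0L, 1L, 1L))

  # nothing below the floor: mask unchanged
  v2 <- array(runif(27, -100, 100), c(3, 3, 3))
  img2 <- volume_grid(v2, c(1, 1, 1))
  msk2 <- roi_mask(array(1L, c(3, 3, 3)), c(1, 1, 1))
  expect_identical(resegment(img2, msk2, -500)$values, msk2$values)

  # all below the floor: degenerate ROI
  img3 <- volume_grid(array(-900, c(2, 2, 2)), c(1, 1, 1))
  msk3 <- roi_mask(array(1L, c(2, 2, 2)), c(1, 1, 1))
  expect_error(resegment(img3, msk3, -500), "degenerate")
})

test_that("resegmentation matches an independent scan on an air-bearing subject", {
  spec <- cohort_spec(n_subjects = 2, seed = 6, air_fraction = c(0.015, 0.02),
                      lesion_diameter_mm = c(18, 24))
  s <- make_subject(spec, 0)
  rp <- resample_pair(s$image, s$mask, preproc_setting(1.6, "L", 5))
  rs <- resegment(rp$image, rp$mask, -500)
  removed <- sum(rp$mask$values) - sum(rs$values)
  expect_equal(removed, sum(rp$image$values[rp$mask$values == 1L] < -500))
})

test_that("discretization follows the fixed-bin-width formula", {
  v <- array(0, c(3, 1, 1)); v[, 1, 1] <- c(-10, -5, 0)
  img <- volume_grid(v, c(1, 1, 1))
  msk <- roi_mask(array(1L, c(3, 1, 1)), c(1, 1, 1))
  d <- discretize(img, msk, 5)
  expect_identical(as.vector(d$levels), 1:3)
  expect_equal(d$n_levels, 3L)
  expect_equal(d$anchor, -10)

  # constant ROI: one level
  dc <- discretize(volume_grid(array(7, c(2, 2, 2)), c(1, 1, 1)),
                   roi_mask(array(1L, c(2, 2, 2)), c(1, 1, 1)), 5)
  expect_equal(dc$n_levels, 1L)
  expect_true(all(dc$levels == 1L))

  # 320 HU range at W = 5: 65 levels, within the 30-130 band
  v3 <- array(seq(0, 320, length.out = 64), c(4, 4, 4))
  d3 <- discretize(volume_grid(v3, c(1, 1, 1)),
                   roi_mask(array(1L, c(4, 4, 4)), c(1, 1, 1)), 5)
  expect_equal(d3$n_levels, 65L)
  expect_equal(check_level_budget(d3), "within")

  expect_error(discretize(img, msk, 0), "config")
})

test_that("discretization is shift-equivariant and monotone", {
  set.seed(42)
  v <- array(runif(5^3, -40, 220), c(5, 5, 5))
  img <- volume_grid(v, c(1, 1, 1))
  msk <- roi_mask(array(1L, c(5, 5, 5)), c(1, 1, 1))
  W <- 7
  d1 <- discretize(img, msk, W)
  d2 <- discretize(volume_grid(v + 3 * W, c(1, 1, 1)), msk, W)
  expect_identical(d1$levels, d2$levels)
  # monotone level map
  ord <- order(as.vector(v))
  expect_true(all(diff(as.vector(d1$levels)[ord]) >= 0))
})

test_that("level budget flags below/within/above", {
  mk <- function(rng) {
    v <- array(seq(0, rng, length.out = 27), c(3, 3, 3))
    discretize(volume_grid(v, c(1, 1, 1)),
               roi_mask(array(1L, c(3, 3, 3)), c(1, 1, 1)), 5)
  }
  expect_equal(check_level_budget(mk(0)), "below")
  expect_equal(check_level_budget(mk(320)), "within")
  expect_equal(check_level_budget(mk(1000)), "above")
})
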