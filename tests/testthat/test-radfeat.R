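test_that("the direction set has 13 antipodal-free vectors covering all 26 neighbors", {
  ds <- direction_set()
  expect_equal(nrow(ds), 13)
  expect_false(any(duplicated(ds)))
  keys <- apply(ds, 1, paste, collapse = ",")
  neg <- apply(-ds, 1, paste, collapse = ",")
  expect_length(intersect(keys, neg), 0)
  expect_equal(nrow(unique(rbind(ds, -ds))), 26)
})

test_that("shape features match closed-form solids", {
  # single voxel at 1 mm isotropic
  m1 <- array(0L, c(5, 5, 5)); m1[3, 3, 3] <- 1L
  sv <- shape_features(roi_mask(m1, c(1, 1, 1)))
  expect_equal(unname(sv["shape_voxel_volume"]), 1)

  # digital ball radius 10 mm at 1 mm spacing
  n <- 25; ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array(as.integer((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 100),
                c(n, n, n))
  sb <- shape_features(roi_mask(ball, c(1, 1, 1)))
  expect_gte(unname(sb["shape_sphericity"]), 0.95)
  expect_lte(unname(sb["shape_sphericity"]), 1.0)
  expect_gte(unname(sb["shape_elongation"]), 0.95)
  expect_gte(unname(sb["shape_flatness"]), 0.95)
  expect_equal(unname(sb["shape_maximum_3d_diameter"]), 20, tolerance = 0.1)
  expect_equal(unname(sb["shape_voxel_volume"]), sum(ball))

  # axis-aligned 20 x 10 x 5 mm box: covariance closed form
  mb <- array(0L, c(26, 16, 11)); mb[4:23, 4:13, 4:8] <- 1L
  sbx <- shape_features(roi_mask(mb, c(1, 1, 1)))
  expect_equal(unname(sbx["shape_elongation"]), 0.5, tolerance = 0.05)
  expect_equal(unname(sbx["shape_flatness"]), 0.25, tolerance = 0.05)
})

test_that("shape features are intensity- and bin-width-independent by construction", {
  spec <- toy_spec(seed = 17)
  s <- make_subject(spec, 0)
  f1 <- extract_all(s$image, s$mask, preproc_setting(1.9, "BS", 3))
  f2 <- extract_all(s$image, s$mask, preproc_setting(1.9, "BS", 8))
  reg <- feature_registry()
  shp <- reg$name[reg$class == "shape"]
  expect_identical(f1[shp], f2[shp])
  # 16 intensity first-order features are also bin-width invariant
  fo <- setdiff(reg$name[reg$class == "firstorder"],
                c("firstorder_entropy", "firstorder_uniformity"))
  expect_identical(f1[fo], f2[fo])
  expect_false(f1[["firstorder_entropy"]] == f2[["firstorder_entropy"]])
})

test_that("first-order features match hand computations", {
  v <- array(0, c(4, 1, 1)); v[, 1, 1] <- c(1, 2, 3, 4)
  img <- volume_grid(v, c(1, 1, 1))
  msk <- roi_mask(array(1L, c(4, 1, 1)), c(1, 1, 1))
  d <- discretize(img, msk, 1)
  fo <- firstorder_features(img, msk, d)
  expect_equal(unname(fo["firstorder_mean"]), 2.5)
  expect_equal(unname(fo["firstorder_energy"]), 30)
  expect_equal(unname(fo["firstorder_range"]), 3)
  expect_equal(unname(fo["firstorder_uniformity"]), 0.25)
  expect_equal(unname(fo["firstorder_entropy"]), 2)
  expect_equal(unname(fo["firstorder_total_energy"]), 30) # 1 mm^3 voxels
  expect_equal(unname(fo["firstorder_median"]), 2.5)
})

test_that("constant ROI hits the degenerate first-order conventions", {
  img <- volume_grid(array(55, c(3, 3, 3)), c(1, 1, 1))
  msk <- roi_mask(array(1L, c(3, 3, 3)), c(1, 1, 1))
  d <- discretize(img, msk, 5)
  fo <- firstorder_features(img, msk, d)
  expect_equal(unname(fo["firstorder_entropy"]), 0)
  expect_equal(unname(fo["firstorder_uniformity"]), 1)
  expect_equal(unname(fo["firstorder_variance"]), 0)
  expect_equal(unname(fo["firstorder_skewness"]), 0)
  expect_equal(unname(fo["firstorder_kurtosis"]), 0)
})

test_that("kurtosis uses the Pearson convention (Gaussian -> 3)", {
  set.seed(8)
  v <- array(rnorm(40^3), c(40, 40, 40))
  img <- volume_grid(v, c(1, 1, 1))
  msk <- roi_mask(array(1L, c(40, 40, 40)), c(1, 1, 1))
  d <- discretize(img, msk, 1)
  fo <- firstorder_features(img, msk, d)
  expect_equal(unname(fo["firstorder_kurtosis"]), 3, tolerance = 0.05)
})

test_that("GLCM counts on the 3x3 checker plane match the exhaustive oracle", {
  lev <- array(0L, c(3, 3, 1))
  lev[, , 1] <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2, 1), 3, byrow = TRUE)
  d <- make_droi(lev)
  mats <- glcm_matrices(d)
  m100 <- mats[["1,0,0"]]
  expect_equal(m100[1, 2], 6)
  expect_equal(m100[2, 1], 6)
  expect_equal(m100[1, 1], 0)
  expect_equal(m100[2, 2], 0)
  ds <- direction_set()
  for (k in seq_len(nrow(ds)))
    expect_equal(mats[[k]], oracle_glcm_dir(lev, ds[k, ], d$n_levels),
                 ignore_attr = TRUE)
})

test_that("constant-ROI GLCM features hit the degenerate conventions", {
  d <- make_droi(array(1L, c(3, 3, 3)))
  f <- glcm_features(d)
  expect_equal(unname(f["glcm_joint_energy"]), 1)
  expect_equal(unname(f["glcm_maximum_probability"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_joint_entropy"]), 0)
  expect_equal(unname(f["glcm_correlation"]), 1)
  expect_equal(unname(f["glcm_imc1"]), 0)
  expect_equal(unname(f["glcm_imc2"]), 0)
})

test_that("GLRLM hand examples: single run and a 2+2 split", {
  # constant 1x1x5 line: one run of length 5
  d1 <- make_droi(array(1L, c(1, 1, 5)))
  f1 <- glrlm_features(d1)
  # the axial direction sees one run among 5 voxels; run percentage is
  # averaged over all 13 directions
  m <- glrlm_matrices(d1)
  expect_equal(sum(m[["0,0,1"]]), 1)
  expect_equal(which(m[["0,0,1"]][1, ] > 0), 5)

  # 1x1x4 levels (1,1,2,2) along z
  lev <- array(0L, c(1, 1, 4)); lev[1, 1, ] <- c(1L, 1L, 2L, 2L)
  d2 <- make_droi(lev)
  m2 <- glrlm_matrices(d2)[["0,0,1"]]
  expect_equal(m2[1, 2], 1)
  expect_equal(m2[2, 2], 1)
  expect_equal(sum(m2), 2)
  # long/short run emphasis of that direction alone
  f <- radrobust:::glrlm_features_one(m2, np = 4)
  expect_equal(unname(f["glrlm_long_run_emphasis"]), 4)
  expect_equal(unname(f["glrlm_short_run_emphasis"]), 1 / 4)
})

test_that("GLSZM zones match connected-component reasoning", {
  # two single-voxel islands of level 1 in a level-2 sea
  lev <- array(2L, c(4, 4, 1))
  lev[1, 1, 1] <- 1L
  lev[4, 4, 1] <- 1L
  # islands touch the sea diagonally but not each other
  M <- glszm_matrix(make_droi(lev))
  expect_equal(M[1, 1], 2)       # level 1: two zones of size 1
  expect_equal(sum(M[2, ]), 1)   # level 2: a single connected sea
  expect_equal(which(M[2, ] > 0), 14)

  # checkerboard: with 26-connectivity diagonal same-level cells connect,
  # giving one zone per level
  cb <- array(0L, c(4, 4, 1))
  cb[, , 1] <- (outer(1:4, 1:4, "+") %% 2) + 1L
  Mcb <- glszm_matrix(make_droi(cb))
  expect_equal(sum(Mcb), 2)
  f <- glszm_features(make_droi(cb))
  expect_equal(unname(f["glszm_zone_percentage"]), 2 / 16)
})

test_that("GLDM dependence counts match neighborhood geometry", {
  d <- make_droi(array(1L, c(3, 3, 3)))
  M <- gldm_matrix(d)
  # center voxel: 26 dependent neighbors; corners: 7
  expect_equal(M[1, 27], 1)
  expect_equal(M[1, 8], 8)
  expect_equal(sum(M), 27)

  # single voxel: one entry at dependence 0
  ds <- make_droi(array(1L, c(1, 1, 1)))
  Ms <- gldm_matrix(ds)
  expect_equal(dim(Ms), c(1L, 1L))
  expect_equal(Ms[1, 1], 1)
})

test_that("NGTDM table matches the 1x1x3 hand computation", {
  lev <- array(0L, c(1, 1, 3)); lev[1, 1, ] <- c(1L, 2L, 1L)
  tb <- ngtdm_table(make_droi(lev))
  # ends see only the middle voxel (level 2): |1 - 2| = 1 each; the middle
  # sees two level-1 voxels: |2 - 1| = 1
  expect_equal(tb$n, c(2, 1))
  expect_equal(tb$s, c(2, 1))
  expect_equal(sum(tb$p), 1)
})

test_that("constant-ROI NGTDM features hit the degenerate conventions", {
  f <- ngtdm_features(make_droi(array(1L, c(3, 3, 3))))
  expect_equal(unname(f["ngtdm_coarseness"]), 1e6)
  expect_equal(unname(f["ngtdm_contrast"]), 0)
  expect_equal(unname(f["ngtdm_busyness"]), 0)
})

test_that("texture matrices satisfy their conservation laws on random ROIs", {
  set.seed(31)
  for (rep in 1:20) {
    d <- random_droi()
    np <- sum(d$levels > 0)
    ds <- direction_set()

    mats <- glcm_matrices(d)
    for (k in seq_len(nrow(ds))) {
      expect_true(isSymmetric(unname(mats[[k]])))
      # sum equals valid in-ROI pairs counted both ways
      expect_equal(sum(mats[[k]]), sum(oracle_glcm_dir(d$levels, ds[k, ], d$n_levels)))
    }
    for (m in glrlm_matrices(d))
      expect_equal(sum(sweep(m, 2, seq_len(ncol(m)), "*")), np)
    Msz <- glszm_matrix(d)
    expect_equal(sum(sweep(Msz, 2, seq_len(ncol(Msz)), "*")), np)
    expect_equal(sum(gldm_matrix(d)), np)
    tb <- ngtdm_table(d)
    expect_equal(sum(tb$p), 1)
  }
})

test_that("extraction yields the 105-feature census deterministically", {
  spec <- toy_spec(seed = 19)
  s <- make_subject(spec, 1)
  st <- preproc_setting(2.2, "G", 5)
  fv <- extract_all(s$image, s$mask, st)
  expect_length(fv, 105)
  reg <- feature_registry()
  expect_identical(names(fv), reg$name)
  expect_equal(as.integer(table(reg$class)[c("shape", "firstorder", "glcm",
                                             "gldm", "glrlm", "glszm",
                                             "ngtdm")]),
               c(14L, 18L, 22L, 14L, 16L, 16L, 5L))
  expect_true(all(is.finite(fv)))
  fv2 <- extract_all(s$image, s$mask, st)
  expect_identical(fv, fv2)
})

test_that("a constant-intensity subject extracts without NaN", {
  spec <- cohort_spec(n_subjects = 2, seed = 23, hu_sd = c(0, 0),
                      air_fraction = c(0, 0), lesion_diameter_mm = c(18, 22))
  s <- make_subject(spec, 0)
  # flatten the background too so the interpolated ROI stays constant
  s$image$values[] <- 40
  fv <- extract_all(s$image, s$mask, preproc_setting(1.6, "BS", 5))
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["firstorder_entropy"]), 0)
  expect_equal(unname(fv["glcm_correlation"]), 1)
  expect_equal(unname(fv["ngtdm_coarseness"]), 1e6)
})
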