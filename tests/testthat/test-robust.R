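test_that("ANOVA decomposition matches hand computations and aov", {
  M <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2) # identical raters
  dec <- anova_decompose(M)
  expect_equal(dec$MS_E, 0)
  expect_equal(dec$MS_C, 0)
  expect_equal(dec$MS_R, 2)

  expect_equal(anova_decompose(matrix(5, 3, 4))$MS_R, 0)

  set.seed(14)
  for (rep in 1:10) {
    M <- matrix(rnorm(20), 5, 4)
    dec <- anova_decompose(M)
    # decomposition identity
    expect_equal(dec$SS_rows + dec$SS_cols + dec$SS_err,
                 sum((M - mean(M))^2), tolerance = 1e-10)
    # full ICC pipeline against the aov-based oracle
    expect_equal(icc_a1(M)$icc, oracle_icc_a1(M), tolerance = 1e-10)
  }
  expect_error(anova_decompose(matrix(1:3, 3, 1)), "design error")
})

test_that("ICC handles perfect agreement and the degenerate all-equal case", {
  M <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2)
  expect_equal(icc_a1(M)$icc, 1)
  expect_equal(icc_a1(matrix(7, 4, 3))$icc, 1)
  # hand-checkable 3x2 design
  M2 <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2)
  expect_equal(icc_a1(M2)$icc, oracle_icc_a1(M2), tolerance = 1e-12)
})

test_that("ICC strata boundaries are as printed", {
  expect_equal(stratify_icc(0.5), "poor")
  expect_equal(stratify_icc(0.5000001), "moderate")
  expect_equal(stratify_icc(0.75), "moderate")
  expect_equal(stratify_icc(0.9), "good")
  expect_equal(stratify_icc(0.9000001), "excellent")
  expect_equal(stratify_icc(1), "excellent")
  expect_equal(stratify_icc(-0.1), "poor")
})

test_that("ICC is invariant to positive affine maps and penalized by rater offsets", {
  set.seed(77)
  # real subject effect so the ICC numerator is positive
  M <- matrix(rnorm(6, 10, 4), 6, 4) + matrix(rnorm(24, 0, 1), 6, 4)
  base <- icc_a1(M)$icc
  expect_equal(icc_a1(3.2 * M + 11)$icc, base, tolerance = 1e-10)
  # a pure column offset strictly decreases absolute-agreement ICC
  M2 <- M
  M2[, 2] <- M2[, 2] + 5
  expect_lt(icc_a1(M2)$icc, base)
})

test_that("CV follows its definition, scale invariance, and zero-mean flag", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  u <- cv_percent(c(2, -2))
  expect_true(is.na(u) && isTRUE(attr(u, "undefined")))
  set.seed(3)
  v <- runif(8, 5, 10)
  expect_equal(cv_percent(2.5 * v), cv_percent(v), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cv_percent(v + 3), cv_percent(v))))
  expect_error(cv_percent(5), "design error")
})

test_that("rmcorr recovers noiseless within-subject lines and matches the ANCOVA oracle", {
  x <- rep(1:4, 3)
  subj <- rep(1:3, each = 4)
  y_up <- 2 * x + c(0, 10, 50)[subj]
  r <- rmcorr(x, y_up, subj)
  expect_equal(r$r_rm, 1)
  expect_lt(r$p_raw, 1e-10)
  expect_equal(r$df, 8L)
  y_dn <- -x + c(0, 10, 50)[subj]
  expect_equal(rmcorr(x, y_dn, subj)$r_rm, -1)

  set.seed(5)
  for (rep in 1:10) {
    y <- 0.7 * x + c(0, 4, 9)[subj] + rnorm(12)
    got <- rmcorr(x, y, subj)
    want <- oracle_rmcorr(x, y, subj)
    expect_equal(got$r_rm, want$r, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p_raw, want$p, tolerance = 1e-10)
  }
  expect_error(rmcorr(rep(1, 6), rnorm(6), rep(1:3, each = 2)), "design error")
})

test_that("rmcorr equals plain correlation for a single shared intercept", {
  set.seed(6)
  x <- rep(1:6, 2)
  y <- 1.5 * x + rnorm(12)
  subj <- rep(1, 12)
  # one subject: centering removes a single intercept, as plain correlation does
  expect_equal(rmcorr(x, y, subj)$r_rm, cor(x, y), tolerance = 1e-12)
})

test_that("Bonferroni caps at one and respects the family size", {
  out <- bonferroni(c(0.0001, 0.01), family_size = 105)
  expect_equal(out$p_adj, c(0.0105, 1))
  expect_identical(out$significant, c(TRUE, FALSE))
  expect_equal(bonferroni(0.03, family_size = 1)$p_adj, 0.03)
})

test_that("ICC recovers the simulated variance ratio as raters grow", {
  # y_ij = mu + s_i + e_ij with var(s) = 4, var(e) = 1: target 0.8
  set.seed(123)
  iccs <- replicate(200, {
    s <- rnorm(50, 0, 2)
    M <- matrix(s, 50, 20) + matrix(rnorm(1000), 50, 20)
    icc_a1(M)$icc
  })
  expect_lt(abs(mean(iccs) - 0.8), 0.05)
})
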