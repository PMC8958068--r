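#' Two-way ANOVA decomposition of a subjects x raters matrix
#'
#' Mean squares for rows (subjects), columns (raters) and error from the
#' complete two-way layout without replication:
#' `SS_rows = k sum_i (ybar_i. - ybar..)^2`,
#' `SS_cols = n sum_j (ybar_.j - ybar..)^2`,
#' `SS_err = SS_tot - SS_rows - SS_cols` (clipped at 0 within 1e-12).
#'
#' @param M numeric matrix, subjects in rows, raters (the varied
#'   preprocessing item) in columns; complete design, `n >= 2`, `k >= 2`.
#' @return An object of class `anova_decomp` with `MS_R`, `MS_C`, `MS_E`,
#'   `n`, `k` and the sums of squares.
#' @export
anova_decompose <- function(M) {
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("design error: missing cells", call. = FALSE)
  n <- nrow(M); k <- ncol(M)
  if (n < 2 || k < 2) stop("design error: need n >= 2 subjects and k >= 2 raters",
                           call. = FALSE)
  g <- mean(M)
  ss_rows <- k * sum((rowMeans(M) - g)^2)
  ss_cols <- n * sum((colMeans(M) - g)^2)
  ss_tot <- sum((M - g)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_err < -1e-12 * max(ss_tot, 1)) stop("ANOVA decomposition failed")
  # snap rounding residue to an exact zero so identical raters give ICC = 1
  if (abs(ss_err) <= 1e-12 * max(ss_tot, 1)) ss_err <- 0
  structure(list(MS_R = ss_rows / (n - 1), MS_C = ss_cols / (k - 1),
                 MS_E = ss_err / ((n - 1) * (k - 1)),
                 SS_rows = ss_rows, SS_cols = ss_cols, SS_err = ss_err,
                 n = n, k = k),
            class = "anova_decomp")
}

#' Two-way mixed-effects absolute-agreement single-rater ICC
#'
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`. If both
#' numerator and denominator vanish (all cells identical) the ICC is 1 by
#' convention: raters agree perfectly on the observed data.
#'
#' @param x an [anova_decompose()] result, or a subjects x raters matrix.
#' @return An object of class `icc_result`: `icc`, `stratum`, `decomp`.
#' @export
icc_a1 <- function(x) {
  decomp <- if (inherits(x, "anova_decomp")) x else anova_decompose(x)
  num <- decomp$MS_R - decomp$MS_E
  den <- decomp$MS_R + (decomp$k - 1) * decomp$MS_E +
    (decomp$k / decomp$n) * (decomp$MS_C - decomp$MS_E)
  scale <- max(decomp$MS_R, decomp$MS_C, decomp$MS_E, 1e-300)
  icc <- if (abs(den) <= 1e-12 * scale || den == 0) {
    stopifnot(abs(num) <= 1e-12 * scale) # den = 0 forces num = 0
    1
  } else num / den
  structure(list(icc = icc, stratum = stratify_icc(icc), decomp = decomp),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f [%s] (n = %d subjects, k = %d raters)\n",
              x$icc, x$stratum, x$decomp$n, x$decomp$k))
  invisible(x)
}

#' Stratify an ICC value
#'
#' Boundary values belong to the lower stratum: poor (ICC <= 0.5), moderate
#' (0.5 < ICC <= 0.75), good (0.75 < ICC <= 0.9), excellent (0.9 < ICC <= 1).
#' Negative estimates stratify as poor.
#'
#' @param icc numeric ICC estimate, at most 1.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
stratify_icc <- function(icc) {
  stopifnot(icc <= 1 + 1e-12)
  if (icc <= 0.5) "poor"
  else if (icc <= 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
}

#' Percentage coefficient of variation
#'
#' `100 * sd(x) / |mean(x)|` with the sample SD. A mean within `zero_tol` of
#' zero makes the CV undefined: `NA` is returned with attribute
#' `undefined = TRUE` so aggregation can exclude (and log) it.
#'
#' @param values at least two feature estimates of one quantity.
#' @param zero_tol absolute tolerance for a zero mean.
#' @return Nonnegative percentage, or flagged `NA` when undefined.
#' @export
cv_percent <- function(values, zero_tol = 1e-12) {
  if (length(values) < 2) stop("design error: CV needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (abs(m) <= zero_tol) return(structure(NA_real_, undefined = TRUE))
  100 * sd(values) / abs(m)
}

#' Repeated-measures correlation
#'
#' Common within-subject linear association between a covariate `x` and a
#' response `y`, adjusting for between-subject differences with
#' subject-specific intercepts (ANCOVA). The coefficient is
#' `r_rm = sign(b) sqrt(SS_x / (SS_x + SS_err))` where `SS_x` is the sum of
#' squares removed by the common slope after subject effects and `SS_err` the
#' residual; `df = N - n_subjects - 1`; p-value from `F(1, df)`.
#'
#' @param x covariate, one value per observation; must vary within subjects.
#' @param y response, one value per observation.
#' @param subject subject identifier per observation; each subject needs at
#'   least two observations.
#' @return An object of class `rmcorr_result`: `r_rm`, `df`, `p_raw`,
#'   `slope`, `slope_sign`.
#' @export
rmcorr <- function(x, y, subject) {
  subject <- factor(subject)
  if (any(table(subject) < 2))
    stop("design error: every subject needs >= 2 observations", call. = FALSE)
  # center within subject; a common slope on centered data is the ANCOVA slope
  xc <- x - ave(x, subject)
  yc <- y - ave(y, subject)
  sxx <- sum(xc^2)
  if (sxx <= 1e-12 * max(1, mean(x^2)))
    stop("design error: covariate constant within all subjects", call. = FALSE)
  b <- sum(xc * yc) / sxx
  ss_x <- b^2 * sxx
  ss_err <- sum((yc - b * xc)^2)
  df <- length(y) - nlevels(subject) - 1L
  if (df < 1) stop("design error: not enough observations", call. = FALSE)
  r <- sign(b) * sqrt(ss_x / (ss_x + ss_err))
  if (ss_x + ss_err == 0) r <- 0 # no within-subject variation at all
  fstat <- if (ss_err > 0) ss_x / (ss_err / df) else Inf
  p <- pf(fstat, 1, df, lower.tail = FALSE)
  structure(list(r_rm = r, df = df, p_raw = p, slope = b,
                 slope_sign = sign(b)),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr r = %.4f (df = %d, p = %.3g)\n", x$r_rm, x$df, x$p_raw))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * family_size)`, with the family size defaulting to the
#' number of supplied p-values.
#'
#' @param p vector of raw p-values.
#' @param family_size size of the test family (>= `length(p)` in typical
#'   use; configurable because the analysis adjusts per feature column).
#' @param alpha significance level for the returned flag.
#' @return Data frame with `p_raw`, `p_adj`, `significant`.
#' @export
bonferroni <- function(p, family_size = length(p), alpha = 0.05) {
  p_adj <- pmin(1, p * family_size)
  data.frame(p_raw = p, p_adj = p_adj, significant = p_adj < alpha)
}
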