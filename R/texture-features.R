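#' Gray level co-occurrence features
#'
#' The 22 GLCM features, computed per directional matrix and averaged over
#' the 13 directions (feature-level averaging). Directions with no valid
#' voxel pair are excluded from the average. Degenerate conventions for a
#' single-level direction: correlation 1, Imc1 0, Imc2 0.
#'
#' @param d a [discretize()] result.
#' @return Named numeric vector of the 22 `glcm_*` features.
#' @export
glcm_features <- function(d) {
  mats <- glcm_matrices(d)
  per_dir <- lapply(mats, function(m) {
    tot <- sum(m)
    if (tot == 0) return(NULL)
    glcm_features_one(m / tot)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (length(per_dir) == 0)
    stop("degenerate-ROI error: no valid co-occurrence pairs", call. = FALSE)
  colMeans(do.call(rbind, per_dir))
}

# features of one normalized symmetric co-occurrence matrix
glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P) # == colSums by symmetry
  iv <- seq_len(ng)
  mu <- sum(iv * px)
  sig2 <- sum((iv - mu)^2 * px)

  # difference and sum margins
  dm <- abs(i - j)
  pd <- vapply(0:(ng - 1), function(k) sum(P[dm == k]), numeric(1))
  sm <- i + j
  ps <- vapply(2:(2 * ng), function(k) sum(P[sm == k]), numeric(1))
  kd <- 0:(ng - 1)
  da <- sum(kd * pd)

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(P)
  hx <- ent(px)
  pij_marg <- outer(px, px)
  sel <- P > 0 & pij_marg > 0
  hxy1 <- -sum(P[sel] * log2(pij_marg[sel]))
  hxy2 <- ent(pij_marg)

  autocorr <- sum(P * i * j)
  correlation <- if (sig2 > 1e-12) (autocorr - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  offdiag <- dm > 0

  c(glcm_autocorrelation = autocorr,
    glcm_joint_average = mu,
    glcm_cluster_prominence = sum(P * (i + j - 2 * mu)^4),
    glcm_cluster_shade = sum(P * (i + j - 2 * mu)^3),
    glcm_cluster_tendency = sum(P * (i + j - 2 * mu)^2),
    glcm_contrast = sum(P * (i - j)^2),
    glcm_correlation = correlation,
    glcm_difference_average = da,
    glcm_difference_entropy = ent(pd),
    glcm_difference_variance = sum(pd * (kd - da)^2),
    glcm_joint_energy = sum(P^2),
    glcm_joint_entropy = hxy,
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    glcm_id = sum(P / (1 + abs(i - j))),
    glcm_idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_inverse_variance = sum(P[offdiag] / (i - j)[offdiag]^2),
    glcm_maximum_probability = max(P),
    glcm_sum_entropy = ent(ps),
    glcm_sum_squares = sum(P * (i - mu)^2))
}

#' Gray level run length features
#'
#' The 16 GLRLM features per directional run-length matrix, averaged over the
#' 13 directions.
#'
#' @param d a [discretize()] result.
#' @return Named numeric vector of the 16 `glrlm_*` features.
#' @export
glrlm_features <- function(d) {
  np <- sum(d$levels > 0L)
  mats <- glrlm_matrices(d)
  per_dir <- lapply(mats, function(m) {
    if (sum(m) == 0) return(NULL)
    glrlm_features_one(m, np)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  colMeans(do.call(rbind, per_dir))
}

glrlm_features_one <- function(P, np) {
  nr <- sum(P)
  p <- P / nr
  iv <- seq_len(nrow(P))
  jv <- seq_len(ncol(P))
  pg <- rowSums(p) # level marginal
  pr <- colSums(p) # run-length marginal
  mug <- sum(iv * pg)
  mur <- sum(jv * pr)
  pp <- p[p > 0]
  c(glrlm_gray_level_nonuniformity = sum(rowSums(P)^2) / nr,
    glrlm_gray_level_nonuniformity_normalized = sum(pg^2),
    glrlm_gray_level_variance = sum(pg * (iv - mug)^2),
    glrlm_high_gray_level_run_emphasis = sum(pg * iv^2),
    glrlm_long_run_emphasis = sum(pr * jv^2),
    glrlm_long_run_high_gray_level_emphasis = sum(p * outer(iv^2, jv^2)),
    glrlm_long_run_low_gray_level_emphasis = sum(p * outer(1 / iv^2, jv^2)),
    glrlm_low_gray_level_run_emphasis = sum(pg / iv^2),
    glrlm_run_entropy = -sum(pp * log2(pp)),
    glrlm_run_length_nonuniformity = sum(colSums(P)^2) / nr,
    glrlm_run_length_nonuniformity_normalized = sum(pr^2),
    glrlm_run_percentage = nr / np,
    glrlm_run_variance = sum(pr * (jv - mur)^2),
    glrlm_short_run_emphasis = sum(pr / jv^2),
    glrlm_short_run_high_gray_level_emphasis = sum(p * outer(iv^2, 1 / jv^2)),
    glrlm_short_run_low_gray_level_emphasis = sum(p * outer(1 / iv^2, 1 / jv^2)))
}

#' Gray level size zone features
#'
#' The 16 GLSZM features from the single zone-size matrix (26-connected
#' zones of equal level).
#'
#' @param d a [discretize()] result.
#' @return Named numeric vector of the 16 `glszm_*` features.
#' @export
glszm_features <- function(d) {
  np <- sum(d$levels > 0L)
  P <- glszm_matrix(d)
  nz <- sum(P)
  p <- P / nz
  iv <- seq_len(nrow(P))
  jv <- seq_len(ncol(P))
  pg <- rowSums(p)
  psz <- colSums(p)
  mug <- sum(iv * pg)
  musz <- sum(jv * psz)
  pp <- p[p > 0]
  c(glszm_gray_level_nonuniformity = sum(rowSums(P)^2) / nz,
    glszm_gray_level_nonuniformity_normalized = sum(pg^2),
    glszm_gray_level_variance = sum(pg * (iv - mug)^2),
    glszm_high_gray_level_zone_emphasis = sum(pg * iv^2),
    glszm_large_area_emphasis = sum(psz * jv^2),
    glszm_large_area_high_gray_level_emphasis = sum(p * outer(iv^2, jv^2)),
    glszm_large_area_low_gray_level_emphasis = sum(p * outer(1 / iv^2, jv^2)),
    glszm_low_gray_level_zone_emphasis = sum(pg / iv^2),
    glszm_size_zone_nonuniformity = sum(colSums(P)^2) / nz,
    glszm_size_zone_nonuniformity_normalized = sum(psz^2),
    glszm_small_area_emphasis = sum(psz / jv^2),
    glszm_small_area_high_gray_level_emphasis = sum(p * outer(iv^2, 1 / jv^2)),
    glszm_small_area_low_gray_level_emphasis = sum(p * outer(1 / iv^2, 1 / jv^2)),
    glszm_zone_entropy = -sum(pp * log2(pp)),
    glszm_zone_percentage = nz / np,
    glszm_zone_variance = sum(psz * (jv - musz)^2))
}

#' Gray level dependence features
#'
#' The 14 GLDM features (coarseness parameter alpha = 0: a neighbor is
#' dependent iff its level matches exactly). Column index `j` corresponds to
#' dependence `j - 1`.
#'
#' @param d a [discretize()] result.
#' @param alpha dependence tolerance.
#' @return Named numeric vector of the 14 `gldm_*` features.
#' @export
gldm_features <- function(d, alpha = 0L) {
  P <- gldm_matrix(d, alpha)
  nd <- sum(P)
  p <- P / nd
  iv <- seq_len(nrow(P))
  jv <- seq_len(ncol(P))
  pg <- rowSums(p)
  pdep <- colSums(p)
  mug <- sum(iv * pg)
  mud <- sum(jv * pdep)
  pp <- p[p > 0]
  c(gldm_dependence_entropy = -sum(pp * log2(pp)),
    gldm_dependence_nonuniformity = sum(colSums(P)^2) / nd,
    gldm_dependence_nonuniformity_normalized = sum(pdep^2),
    gldm_dependence_variance = sum(pdep * (jv - mud)^2),
    gldm_gray_level_nonuniformity = sum(rowSums(P)^2) / nd,
    gldm_gray_level_variance = sum(pg * (iv - mug)^2),
    gldm_high_gray_level_emphasis = sum(pg * iv^2),
    gldm_large_dependence_emphasis = sum(pdep * jv^2),
    gldm_large_dependence_high_gray_level_emphasis = sum(p * outer(iv^2, jv^2)),
    gldm_large_dependence_low_gray_level_emphasis = sum(p * outer(1 / iv^2, jv^2)),
    gldm_low_gray_level_emphasis = sum(pg / iv^2),
    gldm_small_dependence_emphasis = sum(pdep / jv^2),
    gldm_small_dependence_high_gray_level_emphasis = sum(p * outer(iv^2, 1 / jv^2)),
    gldm_small_dependence_low_gray_level_emphasis = sum(p * outer(1 / iv^2, 1 / jv^2)))
}

#' Neighbouring gray tone difference features
#'
#' The 5 NGTDM features. Conventions: coarseness is capped at 1e6 when the
#' weighted difference sum vanishes; busyness and strength are 0 when their
#' denominators vanish; contrast is 0 with a single occupied level.
#'
#' @param d a [discretize()] result.
#' @param coarseness_cap upper bound for coarseness.
#' @return Named numeric vector of the 5 `ngtdm_*` features.
#' @export
ngtdm_features <- function(d, coarseness_cap = 1e6) {
  tb <- ngtdm_table(d)
  occ <- tb$p > 0
  ngp <- sum(occ)
  nvp <- sum(tb$n)
  if (nvp == 0) {
    # isolated-voxel ROI: no voxel has an in-ROI neighbor
    return(c(ngtdm_busyness = 0, ngtdm_coarseness = coarseness_cap,
             ngtdm_complexity = 0, ngtdm_contrast = 0, ngtdm_strength = 0))
  }
  i <- tb$level[occ]
  p <- tb$p[occ]
  s <- tb$s[occ]
  ps <- sum(p * s)
  coarseness <- if (ps > 0) min(1 / ps, coarseness_cap) else coarseness_cap
  contrast <- if (ngp > 1)
    (sum(outer(p, p) * outer(i, i, "-")^2) / (ngp * (ngp - 1))) * (sum(s) / nvp)
  else 0
  bden <- sum(abs(outer(i * p, i * p, "-")))
  busyness <- if (bden > 0) ps / bden else 0
  complexity <- sum(abs(outer(i, i, "-")) *
                    (outer(p * s, p * s, "+") / outer(p, p, "+"))) / nvp
  strength <- if (sum(s) > 0) sum(outer(p, p, "+") * outer(i, i, "-")^2) / sum(s) else 0
  c(ngtdm_busyness = busyness, ngtdm_coarseness = coarseness,
    ngtdm_complexity = complexity, ngtdm_contrast = contrast,
    ngtdm_strength = strength)
}
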