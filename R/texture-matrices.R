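#' The 13 unique 3D direction vectors
#'
#' One integer offset per unique axis through the 26-connected neighborhood:
#' 13 vectors in `{-1,0,1}^3`, none the negation of another, zero excluded,
#' in deterministic lexicographic order.
#'
#' @return A 13 x 3 integer matrix (columns dx, dy, dz).
#' @export
direction_set <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  # keep the lexicographically positive member of each antipodal pair
  pos <- g[, 1] > 0 | (g[, 1] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 3] > 0)))
  g <- g[pos, , drop = FALSE]
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- apply(g, 1, paste, collapse = ",")
  g
}

#' Gray level co-occurrence matrices
#'
#' Symmetric co-occurrence counts at Chebyshev distance 1, one matrix per
#' direction of [direction_set()]; each in-ROI voxel pair is counted in both
#' orders.
#'
#' @param d a [discretize()] result.
#' @return List of 13 `Ng x Ng` integer matrices, named by direction.
#' @export
glcm_matrices <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  dirs <- direction_set()
  arr <- glcm_cpp(d$levels, dim(d$levels), d$n_levels, dirs)
  out <- lapply(seq_len(nrow(dirs)), function(k) arr[, , k, drop = TRUE])
  names(out) <- rownames(dirs)
  lapply(out, function(m) matrix(m, d$n_levels, d$n_levels))
}

#' Gray level run length matrices
#'
#' Counts of maximal same-level runs along each direction, clipped by the ROI
#' boundary; one `Ng x Rmax` matrix per direction.
#'
#' @param d a [discretize()] result.
#' @return List of 13 integer matrices (rows: level, columns: run length).
#' @export
glrlm_matrices <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  dirs <- direction_set()
  arr <- glrlm_cpp(d$levels, dim(d$levels), d$n_levels, dirs)
  rmax <- dim(arr)[2]
  used <- 0L
  for (k in seq_len(nrow(dirs)))
    used <- max(used, max(c(0L, which(colSums(matrix(arr[, , k], d$n_levels, rmax)) > 0))))
  used <- max(used, 1L)
  out <- lapply(seq_len(nrow(dirs)), function(k)
    matrix(arr[, , k], d$n_levels, rmax)[, seq_len(used), drop = FALSE])
  names(out) <- rownames(dirs)
  out
}

#' Gray level size zone matrix
#'
#' Counts of 26-connected zones of equal level, by level and zone size.
#'
#' @param d a [discretize()] result.
#' @return An `Ng x Smax` integer matrix (rows: level, columns: zone size).
#' @export
glszm_matrix <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  glszm_cpp(d$levels, dim(d$levels), d$n_levels)
}

#' Gray level dependence matrix
#'
#' For each ROI voxel, the dependence is the number of in-ROI Chebyshev-1
#' neighbors whose level differs by at most `alpha`. Column `j` stores
#' dependence `j - 1` so the feature formulas stay finite at zero dependence.
#'
#' @param d a [discretize()] result.
#' @param alpha coarseness tolerance (default 0: exact level match).
#' @return An `Ng x (Dmax + 1)` integer matrix.
#' @export
gldm_matrix <- function(d, alpha = 0L) {
  stopifnot(inherits(d, "discretized_roi"))
  m <- gldm_cpp(d$levels, dim(d$levels), d$n_levels, as.integer(alpha))
  used <- max(which(colSums(m) > 0))
  m[, seq_len(used), drop = FALSE]
}

#' Neighbouring gray tone difference table
#'
#' Per level `i`: `n_i`, the number of ROI voxels of level `i` with at least
#' one in-ROI neighbor; `p_i = n_i / sum(n)`; and
#' `s_i = sum |i - mean(in-ROI neighbors)|` over those voxels.
#'
#' @param d a [discretize()] result.
#' @return Data frame with columns `level`, `n`, `p`, `s`.
#' @export
ngtdm_table <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  m <- ngtdm_cpp(d$levels, dim(d$levels), d$n_levels)
  nvp <- sum(m[, 1])
  data.frame(level = seq_len(d$n_levels), n = m[, 1],
             p = if (nvp > 0) m[, 1] / nvp else m[, 1] * 0, s = m[, 2])
}
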