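#' Shape features of a binary ROI
#'
#' Fourteen morphology features computed from the mask alone (intensity- and
#' bin-width-independent). Mesh volume and surface area come from an
#' iso-surface of the mask indicator extracted at 0.5 after light Gaussian
#' anti-aliasing (`smooth_sigma_vox` voxels; raw binary iso-surfaces
#' overestimate the area of smooth objects by ~9% through staircasing).
#' Axis lengths derive from the eigenvalues of the physical voxel-coordinate
#' covariance (length = 4 sqrt(lambda)); maximum diameters are the largest
#' pairwise surface-vertex distances in 3D and in each plane projection.
#'
#' Degenerate masks whose anti-aliased indicator never exceeds 0.5 (e.g. a
#' single voxel) fall back to the voxel rectangular hull for area, volume and
#' diameters. Zero-variance axes give elongation/flatness 1 by convention.
#'
#' @param mask a [roi_mask] on the analysis (resampled) grid.
#' @param smooth_sigma_vox anti-aliasing sigma in voxels.
#' @return Named numeric vector of the 14 `shape_*` features.
#' @export
shape_features <- function(mask, smooth_sigma_vox = 0.8) {
  stopifnot(inherits(mask, "roi_mask"))
  sp <- mask$spacing
  nvox <- sum(mask$values)
  if (nvox < 1L) stop("degenerate-ROI error: empty mask", call. = FALSE)

  mesh <- mask_mesh(mask, smooth_sigma_vox)
  A <- mesh$area
  V <- mesh$volume

  idx <- which(mask$values == 1L, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, sp, "*")
  if (nvox > 1L) {
    cc <- sweep(coords, 2, colMeans(coords))
    lambda <- sort(pmax(eigen(crossprod(cc) / nvox, symmetric = TRUE,
                              only.values = TRUE)$values, 0),
                   decreasing = TRUE)
  } else lambda <- c(0, 0, 0)
  axis_len <- 4 * sqrt(lambda)
  elongation <- if (lambda[1] > 0) sqrt(lambda[2] / lambda[1]) else 1
  flatness <- if (lambda[1] > 0) sqrt(lambda[3] / lambda[1]) else 1

  c(shape_elongation = elongation,
    shape_flatness = flatness,
    shape_least_axis_length = axis_len[3],
    shape_major_axis_length = axis_len[1],
    shape_maximum_2d_diameter_column = mesh$diameter_ignore_x,
    shape_maximum_2d_diameter_row = mesh$diameter_ignore_y,
    shape_maximum_2d_diameter_slice = mesh$diameter_ignore_z,
    shape_maximum_3d_diameter = mesh$diameter_3d,
    shape_mesh_volume = V,
    shape_minor_axis_length = axis_len[2],
    shape_sphericity = (36 * pi * V^2)^(1 / 3) / A,
    shape_surface_area = A,
    shape_surface_volume_ratio = A / V,
    shape_voxel_volume = nvox * prod(sp))
}

# anti-aliased iso-surface of the mask; voxel rectangular hull fallback when
# the smoothed indicator stays below the 0.5 level everywhere
mask_mesh <- function(mask, smooth_sigma_vox) {
  nd <- dim(mask$values)
  pad <- 4L
  field <- array(0, nd + 2L * pad)
  field[pad + seq_len(nd[1]), pad + seq_len(nd[2]), pad + seq_len(nd[3])] <-
    mask$values
  if (smooth_sigma_vox > 0)
    field <- smooth_gaussian_cpp(field, dim(field), rep(smooth_sigma_vox, 3))
  m <- mesh_tetra_cpp(field, dim(field), mask$spacing, 0.5)
  if (m$n_triangles > 0) return(m)
  voxel_hull_mesh(mask)
}

voxel_hull_mesh <- function(mask) {
  v <- mask$values
  sp <- mask$spacing
  nd <- dim(v)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  for (ax in 1:3) {
    pd <- nd
    pd[ax] <- nd[ax] + 1L
    padded <- array(0L, pd)
    ix <- lapply(nd, seq_len)
    do.call(`[<-`, c(list(padded), ix, list(v)))
    shifted <- array(0L, pd)
    ix2 <- ix
    ix2[[ax]] <- ix2[[ax]] + 1L
    do.call(`[<-`, c(list(shifted), ix2, list(v)))
    area <- area + sum(padded != shifted) * face_area[ax]
  }
  idx <- which(v == 1L, arr.ind = TRUE)
  corners <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  pts <- do.call(rbind, lapply(seq_len(nrow(corners)), function(k)
    sweep(sweep(idx - 1, 2, corners[k, ], "+"), 2, sp, "*")))
  d2 <- function(cols) {
    p <- pts[, cols, drop = FALSE]
    max(dist(p))
  }
  list(area = area, volume = sum(v) * prod(sp), n_triangles = 0,
       n_vertices = nrow(pts),
       diameter_3d = d2(1:3), diameter_ignore_x = d2(2:3),
       diameter_ignore_y = d2(c(1, 3)), diameter_ignore_z = d2(1:2))
}
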