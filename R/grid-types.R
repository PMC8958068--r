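#' 3D scalar volume on a regular grid
#'
#' Container for a CT-like image: a 3D array of Hounsfield units plus grid
#' geometry. Axis convention: the first array dimension (x) is the fastest
#' varying in-plane axis, the second (y) the other in-plane axis, the third
#' (z) the slice axis. `origin` is the physical position (mm) of the center
#' of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array of intensities (finite).
#' @param spacing length-3 positive numeric, voxel spacing in mm (dx, dy, dz).
#' @param origin length-3 numeric, physical position of the first voxel
#'   center in mm.
#' @return An object of class `volume_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("volume_grid: `values` must be a 3D array", call. = FALSE)
  values <- array(as.double(values), dim(values)) # drop foreign attributes
  if (!all(is.finite(values)))
    stop("volume_grid: all values must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("volume_grid: spacing must be 3 strictly positive numbers", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("volume_grid: origin must have length 3", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Binary region-of-interest mask on a regular grid
#'
#' Same geometry contract as [volume_grid()]; any nonzero voxel is treated as
#' foreground and stored as 1.
#'
#' @inheritParams volume_grid
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("roi_mask: `values` must be a 3D array", call. = FALSE)
  values <- array(as.integer(values != 0), dim(values)) # drop foreign attributes
  if (sum(values) < 1L)
    stop("roi_mask: mask must contain at least one foreground voxel", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("roi_mask: spacing must be 3 strictly positive numbers", call. = FALSE)
  origin <- as.numeric(origin)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "roi_mask")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"), " mm\n",
      "  HU range [", signif(min(x$values), 5), ", ", signif(max(x$values), 5), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, ", sum(x$values), " foreground voxels\n", sep = "")
  invisible(x)
}

# geometry agreement between an image and its mask
check_same_grid <- function(image, mask, tol = 1e-4) {
  if (!identical(dim(image$values), dim(mask$values)))
    stop("geometry error: image and mask shapes differ", call. = FALSE)
  if (any(abs(image$spacing - mask$spacing) > tol) ||
      any(abs(image$origin - mask$origin) > tol))
    stop("geometry error: image and mask grids differ beyond tolerance", call. = FALSE)
  invisible(TRUE)
}

# physical voxel volume in mm^3
voxel_volume_mm3 <- function(grid) prod(grid$spacing)
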