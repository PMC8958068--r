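#' The ten named interpolation algorithms
#'
#' Closed vocabulary of image interpolators for isotropic resampling:
#' `BS` cubic B-spline (order 3, recursive prefilter), `BL`/`CWS`/`HWS`/
#' `LWS`/`WWS` sinc kernels windowed by Blackman/cosine/Hamming/Lanczos/Welch
#' (window radius 3 voxels), `G` Gaussian with sigma = 0.5 x output spacing,
#' `LG` Gaussian-weighted label voting (same sigma), `L` trilinear, `NN`
#' nearest neighbor.
#'
#' @return Character vector of the ten interpolator names.
#' @export
interpolators <- function() {
  c("BS", "BL", "CWS", "G", "HWS", "LG", "LWS", "L", "NN", "WWS")
}

#' One point of the preprocessing grid
#'
#' @param voxel_size_mm isotropic resampling voxel size in mm (> 0).
#' @param interpolator one of [interpolators()].
#' @param bin_width_hu intensity bin width in HU (> 0).
#' @param hu_floor resegmentation threshold: ROI voxels strictly below this
#'   HU value are removed (accounts for partial-volume air).
#' @param gaussian_sigma_factor sigma of the `G`/`LG` kernels as a fraction
#'   of the output spacing.
#' @return An object of class `preproc_setting`.
#' @export
preproc_setting <- function(voxel_size_mm, interpolator = "BS",
                            bin_width_hu = 5, hu_floor = -500,
                            gaussian_sigma_factor = 0.5) {
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("config error: voxel_size_mm must be positive", call. = FALSE)
  if (!interpolator %in% interpolators())
    stop(sprintf("config error: unknown interpolator '%s'", interpolator),
         call. = FALSE)
  if (!is.numeric(bin_width_hu) || bin_width_hu <= 0)
    stop("config error: bin_width_hu must be positive", call. = FALSE)
  structure(list(voxel_size_mm = as.numeric(voxel_size_mm),
                 interpolator = interpolator,
                 bin_width_hu = as.numeric(bin_width_hu),
                 hu_floor = as.numeric(hu_floor),
                 gaussian_sigma_factor = as.numeric(gaussian_sigma_factor)),
            class = "preproc_setting")
}

# output grid for isotropic resampling: covers the input physical extent,
# grid centers aligned to the input volume center
iso_output_grid <- function(grid, voxel_size_mm) {
  nd <- dim(grid$values)
  extent <- (nd - 1) * grid$spacing
  n_out <- pmax(1L, as.integer(floor(extent / voxel_size_mm)) + 1L)
  center <- grid$origin + extent / 2
  out_spacing <- rep(voxel_size_mm, 3)
  out_origin <- center - (n_out - 1) * out_spacing / 2
  list(dim = n_out, spacing = out_spacing, origin = out_origin)
}

#' Resample an image/mask pair to an isotropic grid
#'
#' The image is interpolated with the kernel named in `setting`; the mask is
#' always resampled with nearest neighbor (and re-binarized), so at a fixed
#' voxel size the ROI geometry is identical across all ten image
#' interpolators and across bin widths.
#'
#' @param image a [volume_grid].
#' @param mask the companion [roi_mask].
#' @param setting a [preproc_setting].
#' @return A list with resampled `image` and `mask`.
#' @export
resample_pair <- function(image, mask, setting) {
  stopifnot(inherits(setting, "preproc_setting"))
  check_same_grid(image, mask)
  out <- iso_output_grid(image, setting$voxel_size_mm)
  sigma_mm <- setting$gaussian_sigma_factor * setting$voxel_size_mm
  vi <- resample_grid_cpp(image$values, dim(image$values),
                          image$spacing, image$origin,
                          out$dim, out$spacing, out$origin,
                          setting$interpolator, sigma_mm)
  vm <- resample_grid_cpp(mask$values + 0, dim(mask$values),
                          mask$spacing, mask$origin,
                          out$dim, out$spacing, out$origin,
                          "NN", sigma_mm)
  vm <- array(as.integer(vm > 0.5), out$dim)
  if (sum(vm) < 1L)
    stop("degenerate-ROI error: resampled mask is empty", call. = FALSE)
  list(image = volume_grid(vi, out$spacing, out$origin),
       mask = roi_mask(vm, out$spacing, out$origin))
}

#' Remove sub-threshold voxels from the ROI
#'
#' Drops mask voxels whose image intensity is strictly below `hu_floor`
#' (partial-volume air exclusion); boundary-value voxels are kept.
#'
#' @inheritParams resample_pair
#' @param hu_floor threshold in HU.
#' @return The resegmented [roi_mask].
#' @export
resegment <- function(image, mask, hu_floor = -500) {
  check_same_grid(image, mask)
  m <- mask$values
  m[image$values < hu_floor] <- 0L
  if (sum(m) < 1L)
    stop("degenerate-ROI error: resegmentation removed all ROI voxels",
         call. = FALSE)
  roi_mask(m, mask$spacing, mask$origin)
}

#' Fixed-bin-width gray-level discretization of the ROI
#'
#' Assigns level `floor((x - x_min)/W) + 1` to each ROI voxel, with `x_min`
#' the ROI minimum (bins anchored at the ROI minimum, fixed-bin-size
#' convention). The number of levels is `Ng = floor((max - min)/W) + 1`.
#'
#' @inheritParams resample_pair
#' @param bin_width bin width W in HU (> 0).
#' @return An object of class `discretized_roi`: `levels` (3D integer array,
#'   0 outside the ROI), `n_levels`, `bin_width`, `anchor` (the ROI minimum),
#'   `voxel_volume` (mm^3) and `spacing`.
#' @export
discretize <- function(image, mask, bin_width) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("config error: bin_width must be positive", call. = FALSE)
  check_same_grid(image, mask)
  roi <- mask$values == 1L
  if (!any(roi))
    stop("degenerate-ROI error: empty mask", call. = FALSE)
  x <- image$values[roi]
  anchor <- min(x)
  lev <- as.integer(floor((x - anchor) / bin_width) + 1)
  ng <- as.integer(floor((max(x) - anchor) / bin_width) + 1)
  lev[lev > ng] <- ng # guard against floating-point edge at the maximum
  levels <- array(0L, dim(mask$values))
  levels[roi] <- lev
  structure(list(levels = levels, n_levels = ng, bin_width = bin_width,
                 anchor = anchor, voxel_volume = prod(image$spacing),
                 spacing = image$spacing),
            class = "discretized_roi")
}

#' Check the quantization-level budget
#'
#' Flags whether the number of gray levels falls in the suggested band
#' (30-130 by default). The pipeline logs a warning outside the band but
#' never aborts.
#'
#' @param d a [discretize()] result.
#' @param lo,hi band limits.
#' @return `"within"`, `"below"` or `"above"`.
#' @export
check_level_budget <- function(d, lo = 30, hi = 130) {
  stopifnot(inherits(d, "discretized_roi"))
  if (d$n_levels < lo) "below" else if (d$n_levels > hi) "above" else "within"
}
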