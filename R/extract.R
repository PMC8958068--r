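#' Extract all 105 features from a raw image/mask pair
#'
#' Runs the full preprocessing chain — isotropic resampling (mask with
#' nearest neighbor), HU-floor resegmentation, fixed-bin-width discretization
#' — and all seven feature-class extractors. Shape features are computed on
#' the resampled (not resegmented) mask, so they depend only on the voxel
#' size; intensity first-order features are computed from undiscretized HU,
#' so they do not vary with bin width.
#'
#' @param image a [volume_grid] in HU.
#' @param mask the companion [roi_mask].
#' @param setting a [preproc_setting].
#' @return Named numeric vector of exactly 105 finite values, ordered as in
#'   [feature_registry()].
#' @export
extract_all <- function(image, mask, setting) {
  rp <- resample_pair(image, mask, setting)
  shape <- shape_features(rp$mask)
  extract_after_resample(rp, shape, setting)
}

# feature extraction downstream of resampling; `shape` precomputed because it
# is invariant to interpolator and bin width at fixed voxel size
extract_after_resample <- function(rp, shape, setting) {
  reseg <- resegment(rp$image, rp$mask, setting$hu_floor)
  d <- discretize(rp$image, reseg, setting$bin_width_hu)
  out <- c(shape,
           firstorder_features(rp$image, reseg, d),
           glcm_features(d),
           glrlm_features(d),
           glszm_features(d),
           gldm_features(d),
           ngtdm_features(d))
  reg <- feature_registry()
  out <- out[reg$name]
  stopifnot(length(out) == 105L, all(is.finite(out)))
  attr(out, "n_levels") <- d$n_levels
  attr(out, "level_flag") <- check_level_budget(d)
  out
}

#' Extract the full preprocessing grid over a cohort
#'
#' Computes the feature table over the two setting families the analysis
#' needs: all `(voxel size, interpolator)` pairs at the fixed bin width, and
#' all `(voxel size, bin width)` pairs at the fixed interpolator. Each
#' resampling is performed once per `(subject, voxel size, interpolator)` and
#' shape features once per `(subject, voxel size)`.
#'
#' @param cohort a list of subjects (as from [make_cohort()]), each with
#'   `image` and `mask` elements.
#' @param voxel_sizes isotropic resampling voxel sizes in mm.
#' @param interps interpolator names varied at `fixed_bin`.
#' @param bin_widths bin widths (HU) varied under `fixed_interp`.
#' @param fixed_interp interpolator used when varying bin width.
#' @param fixed_bin bin width (HU) used when varying the interpolator.
#' @param hu_floor resegmentation threshold in HU.
#' @param verbose print progress to stderr.
#' @return Long-format data frame: `subject`, `voxel_size`, `interpolator`,
#'   `bin_width`, `feature_class`, `feature_name`, `value`.
#' @export
extract_grid <- function(cohort, voxel_sizes = c(1, 1.3, 1.6, 1.9, 2.2, 2.5),
                         interps = interpolators(), bin_widths = 3:8,
                         fixed_interp = "BS", fixed_bin = 5,
                         hu_floor = -500, verbose = FALSE) {
  reg <- feature_registry()
  rows <- list()
  for (si in seq_along(cohort)) {
    subj <- cohort[[si]]
    sid <- if (!is.null(subj$params$subject)) subj$params$subject else si - 1L
    for (vs in voxel_sizes) {
      if (verbose)
        message(sprintf("subject %s, voxel size %.1f mm", sid, vs))
      # (interpolator, bin width) combinations needed at this voxel size
      combos <- unique(rbind(
        data.frame(interpolator = interps, bin_width = fixed_bin,
                   stringsAsFactors = FALSE),
        data.frame(interpolator = fixed_interp, bin_width = bin_widths,
                   stringsAsFactors = FALSE)))
      shape_vals <- NULL
      for (ip in unique(combos$interpolator)) {
        setting <- preproc_setting(vs, ip, fixed_bin, hu_floor)
        rp <- resample_pair(subj$image, subj$mask, setting)
        if (is.null(shape_vals)) shape_vals <- shape_features(rp$mask)
        for (bw in combos$bin_width[combos$interpolator == ip]) {
          st <- preproc_setting(vs, ip, bw, hu_floor)
          fv <- extract_after_resample(rp, shape_vals, st)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sid, voxel_size = vs, interpolator = ip, bin_width = bw,
            feature_class = reg$class, feature_name = reg$name,
            value = as.numeric(fv), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table as CSV
#'
#' Deterministic long-format CSV (stable row order and full-precision
#' values), suitable for byte-identical reruns at a fixed seed.
#'
#' @param features data frame from [extract_grid()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  features$value <- sprintf("%.17g", features$value)
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
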