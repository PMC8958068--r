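#' Specification of a synthetic CT lesion cohort
#'
#' Describes the statistical structure of a cohort of CT-like lesion volumes:
#' between-subject heterogeneity (each subject draws its own texture
#' parameters from the stated ranges), intra-lesion texture (a correlated
#' Gaussian random field plus a smooth core-to-rim intensity gradient),
#' occasional sub-(-500 HU) air pockets inside the delineation, and an
#' anisotropic acquisition grid (in-plane pixel 0.82-1.27 mm, 5 mm slices).
#'
#' Defaults are chosen so that, at a fixed bin width of 5 HU, the resegmented
#' ROI of every subject discretizes to roughly 30-130 gray levels.
#'
#' @param n_subjects number of subjects (>= 2; the intraclass correlation
#'   needs between-subject variance).
#' @param seed integer seed; subject `i` uses `seed + i` so the cohort is a
#'   pure function of `(spec, seed)`.
#' @param lesion_diameter_mm range of lesion diameters (mm).
#' @param hu_mean range of subject-level mean ROI intensity (HU).
#' @param hu_sd range of subject-level ROI intensity SD (HU).
#' @param correlation_length_mm range of texture correlation lengths (mm);
#'   larger values give smoother, coarser texture.
#' @param gradient_amplitude_hu range of the core-to-rim intensity gradient
#'   amplitude (HU), part of the intra-lesion texture budget.
#' @param air_fraction range of the proportion of ROI voxels forced below
#'   -500 HU (small connected pockets imitating partial-volume air).
#' @param inplane_pixel_mm range of in-plane pixel sizes (mm).
#' @param slice_thickness_mm slice thickness (mm).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L,
                        seed = 1L,
                        lesion_diameter_mm = c(25, 55),
                        hu_mean = c(10, 60),
                        hu_sd = c(28, 45),
                        correlation_length_mm = c(3, 8),
                        gradient_amplitude_hu = c(60, 90),
                        air_fraction = c(0, 0.02),
                        inplane_pixel_mm = c(0.82, 1.27),
                        slice_thickness_mm = 5) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L)
    stop("cohort_spec: n_subjects must be >= 2", call. = FALSE)
  rng2 <- function(r, what, lo = -Inf, hi = Inf) {
    r <- as.numeric(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || r[1] > r[2] || r[1] < lo || r[2] > hi)
      stop(sprintf("cohort_spec: invalid range for %s", what), call. = FALSE)
    r
  }
  spec <- list(
    n_subjects = n_subjects,
    seed = as.integer(seed),
    lesion_diameter_mm = rng2(lesion_diameter_mm, "lesion_diameter_mm", lo = 1),
    hu_mean = rng2(hu_mean, "hu_mean"),
    hu_sd = rng2(hu_sd, "hu_sd", lo = 0),
    correlation_length_mm = rng2(correlation_length_mm, "correlation_length_mm", lo = 0.1),
    gradient_amplitude_hu = rng2(gradient_amplitude_hu, "gradient_amplitude_hu", lo = 0),
    air_fraction = rng2(air_fraction, "air_fraction", lo = 0, hi = 0.2),
    inplane_pixel_mm = rng2(inplane_pixel_mm, "inplane_pixel_mm", lo = 0.05),
    slice_thickness_mm = as.numeric(slice_thickness_mm)
  )
  if (spec$slice_thickness_mm <= 0)
    stop("cohort_spec: slice_thickness_mm must be positive", call. = FALSE)
  structure(spec, class = "cohort_spec")
}

# run expr under a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic subject
#'
#' Builds an ellipsoid-like lesion with mild boundary perturbation, filled
#' with a correlated Gaussian random field rescaled to the subject's drawn
#' mean/SD, superimposed on a smooth core-to-rim gradient; the background is
#' soft-tissue noise in about -100..100 HU, and a drawn fraction of ROI
#' voxels is replaced by small connected air pockets below -500 HU. The
#' result is fully determined by `(spec, subject_index, seed)`.
#'
#' @param spec a [cohort_spec].
#' @param subject_index 0-based subject index, `< spec$n_subjects`.
#' @param seed base seed; defaults to `spec$seed`.
#' @return A list with `image` ([volume_grid]), `mask` ([roi_mask]) and
#'   `params` (the drawn subject-level parameters).
#' @export
make_subject <- function(spec, subject_index, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 0L || subject_index >= spec$n_subjects)
    stop("make_subject: subject_index out of range", call. = FALSE)
  with_seed(seed + subject_index, make_subject_impl(spec, subject_index))
}

make_subject_impl <- function(spec, subject_index) {
  draw <- function(r) runif(1, r[1], r[2])
  diam <- draw(spec$lesion_diameter_mm)
  mu <- draw(spec$hu_mean)
  sdev <- draw(spec$hu_sd)
  clen <- draw(spec$correlation_length_mm)
  grad_amp <- draw(spec$gradient_amplitude_hu)
  airf <- draw(spec$air_fraction)
  pix <- draw(spec$inplane_pixel_mm)
  thk <- spec$slice_thickness_mm

  spacing <- c(pix, pix, thk)
  # grid extent: lesion plus margin on each side
  margin_xy <- 14; margin_z <- 8
  nd <- c(ceiling((diam + 2 * margin_xy) / pix),
          ceiling((diam + 2 * margin_xy) / pix),
          ceiling((diam + 2 * margin_z) / thk))
  extent <- (nd - 1) * spacing
  if (diam > min(extent))
    stop("sizing error: lesion diameter exceeds volume extent", call. = FALSE)
  ctr <- extent / 2

  # physical voxel-center coordinates relative to the lesion center
  xs <- (seq_len(nd[1]) - 1) * spacing[1] - ctr[1]
  ys <- (seq_len(nd[2]) - 1) * spacing[2] - ctr[2]
  zs <- (seq_len(nd[3]) - 1) * spacing[3] - ctr[3]

  # random-orientation ellipsoid with semi-axes a >= b >= c
  ax <- (diam / 2) * c(1, runif(1, 0.75, 1), runif(1, 0.75, 1))
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  # squared ellipsoidal radius for all voxels
  X <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  Xr <- X %*% rot
  q2 <- (Xr[, 1] / ax[1])^2 + (Xr[, 2] / ax[2])^2 + (Xr[, 3] / ax[3])^2

  # mild boundary perturbation from a coarse smoothed noise field
  pert <- array(rnorm(prod(nd)), nd)
  pert <- smooth_gaussian_cpp(pert, dim(pert), (diam / 4) / spacing)
  pert <- (pert - mean(pert)) / max(sd(pert), 1e-12)
  inside <- q2 <= (1 + 0.08 * as.vector(pert))^2
  mask_arr <- array(as.integer(inside), nd)
  # keep the largest 26-connected component so the ROI is connected
  lab <- label_components_cpp(mask_arr, dim(mask_arr))
  if (max(lab) > 1L) {
    keep <- which.max(tabulate(lab[lab > 0L]))
    mask_arr <- array(as.integer(lab == keep), nd)
  }
  nroi <- sum(mask_arr)
  if (nroi < 1L) stop("sizing error: empty lesion mask", call. = FALSE)
  roi_idx <- which(mask_arr == 1L)

  # intra-lesion texture: correlated field + core-to-rim gradient, scaled to
  # the subject's mean/SD over the ROI
  field <- array(rnorm(prod(nd)), nd)
  field <- smooth_gaussian_cpp(field, dim(field), clen / spacing)
  g <- as.vector(field)[roi_idx]
  g <- (g - mean(g)) / max(sd(g), 1e-12)
  radial <- sqrt(q2[roi_idx]) # 0 at core, ~1 at rim
  radial <- radial - mean(radial)
  w_rad <- grad_amp / max(sdev, 1e-12) # gradient amplitude in SD units
  tex <- w_rad * radial + g
  tex_sd <- sd(tex)
  tex <- if (tex_sd > 1e-12) (tex - mean(tex)) / tex_sd else tex * 0
  roi_vals <- mu + sdev * tex

  # background: soft-tissue noise within about -100..100 HU
  vals <- pmin(pmax(rnorm(prod(nd), 0, 35), -100), 100)
  vals[roi_idx] <- roi_vals
  vals <- array(vals, nd)

  # air pockets: small connected blobs strictly below -500 HU
  n_air <- round(airf * nroi)
  if (n_air > 0) {
    placed <- integer(0)
    guard <- 0L
    while (length(placed) < n_air && guard < 1000L) {
      guard <- guard + 1L
      seed_vox <- roi_idx[sample.int(nroi, 1)]
      sv <- arrayInd(seed_vox, nd)
      nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
      cand <- sweep(nb, 2, as.integer(sv), "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= nd[1] &
            cand[, 2] >= 1 & cand[, 2] <= nd[2] &
            cand[, 3] >= 1 & cand[, 3] <= nd[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + nd[1] * (cand[, 2] - 1 + nd[2] * (cand[, 3] - 1))
      lin <- lin[mask_arr[lin] == 1L]
      placed <- unique(c(placed, lin))
    }
    placed <- placed[seq_len(min(length(placed), n_air))]
    vals[placed] <- runif(length(placed), -1000, -600)
  }

  params <- list(subject = subject_index, lesion_diameter_mm = diam,
                 hu_mean = mu, hu_sd = sdev, correlation_length_mm = clen,
                 gradient_amplitude_hu = grad_amp, air_fraction = airf,
                 inplane_pixel_mm = pix, slice_thickness_mm = thk,
                 n_roi_voxels = nroi)
  list(image = volume_grid(vals, spacing),
       mask = roi_mask(mask_arr, spacing),
       params = params)
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec].
#' @return A list of subjects (each as returned by [make_subject()]) with a
#'   `manifest` attribute: a data frame of the drawn per-subject parameters.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- lapply(seq_len(spec$n_subjects) - 1L,
                     function(i) make_subject(spec, i))
  manifest <- do.call(rbind, lapply(subjects, function(s)
    as.data.frame(s$params)))
  attr(subjects, "manifest") <- manifest
  class(subjects) <- "radcohort"
  subjects
}

#' Write a cohort to disk as NIfTI pairs plus a JSON manifest
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame augmented with file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- attr(cohort, "manifest")
  manifest$image_path <- file.path(dir, sprintf("subject%03d_image.nii.gz",
                                                manifest$subject))
  manifest$mask_path <- file.path(dir, sprintf("subject%03d_mask.nii.gz",
                                               manifest$subject))
  for (i in seq_along(cohort))
    write_pair(cohort[[i]]$image, cohort[[i]]$mask,
               manifest$image_path[i], manifest$mask_path[i])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
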