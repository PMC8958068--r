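#' Read an image/mask pair from NIfTI files
#'
#' Loads a 3D volume and its companion binary mask, checks that their grids
#' agree (spacing and origin within `tol` mm, identical shape), and binarizes
#' the mask (any nonzero voxel becomes foreground).
#'
#' @param image_path,mask_path paths to NIfTI files (`.nii` or `.nii.gz`).
#' @param tol geometry agreement tolerance in mm.
#' @return A list with elements `image` ([volume_grid]) and `mask`
#'   ([roi_mask]).
#' @export
read_pair <- function(image_path, mask_path, tol = 1e-4) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  gi <- nifti_geometry(img)
  gm <- nifti_geometry(msk)
  ai <- as.array(img)
  am <- as.array(msk)
  if (length(dim(ai)) != 3L || length(dim(am)) != 3L)
    stop("format error: inputs must be 3D volumes", call. = FALSE)
  image <- volume_grid(ai, gi$spacing, gi$origin)
  mask <- roi_mask(am, gm$spacing, gm$origin)
  check_same_grid(image, mask, tol = tol)
  list(image = image, mask = mask)
}

#' Write an image/mask pair as NIfTI files
#'
#' @param image a [volume_grid].
#' @param mask the companion [roi_mask].
#' @param image_path,mask_path output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_pair <- function(image, mask, image_path, mask_path) {
  check_same_grid(image, mask)
  write_nifti_grid(image$values, image$spacing, image$origin, image_path)
  write_nifti_grid(mask$values, mask$spacing, mask$origin, mask_path)
  invisible(c(image_path, mask_path))
}

nifti_geometry <- function(im) {
  sp <- RNifti::pixdim(im)[1:3]
  xf <- RNifti::xform(im)
  list(spacing = as.numeric(sp), origin = as.numeric(xf[1:3, 4]))
}

write_nifti_grid <- function(values, spacing, origin, path) {
  im <- RNifti::asNifti(values)
  RNifti::pixdim(im) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::`qform<-`(im, structure(m, code = 2L)) -> im
  RNifti::writeNifti(im, path)
  invisible(path)
}
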