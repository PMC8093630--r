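#' Image volume with physical voxel spacing
#'
#' A minimal container for a 3D scalar image: a numeric array plus the
#' physical voxel spacing (mm) and origin (mm) of the first voxel centre.
#' Masks are plain logical arrays aligned to the volume grid.
#'
#' @param values numeric 3D array of voxel intensities; all finite.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm,
#'   strictly positive.
#' @param origin numeric length-3 vector, physical position (mm) of the
#'   centre of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(rnorm(27), c(3, 3, 3)), spacing = c(1, 1, 1.2))
#' dim(vol$values)
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

check_mask <- function(vol, mask, require_nonempty = TRUE) {
  if (!is.array(mask) || !identical(dim(mask), dim(vol$values)))
    stop("mask grid does not match the volume grid", call. = FALSE)
  mask <- mask > 0
  if (require_nonempty && !any(mask))
    stop("mask has no foreground voxel", call. = FALSE)
  mask
}

#' Voxelwise image subtraction
#'
#' Computes the subtracted (contrast-enhancement) image: the pre-contrast
#' acquisition removed voxelwise from a post-contrast dynamic acquisition.
#'
#' @param pre,post `image_volume` objects on identical grids with identical
#'   spacing.
#' @return An `image_volume` holding `post - pre`.
#' @export
subtract_images <- function(pre, post) {
  stopifnot(is_image_volume(pre), is_image_volume(post))
  if (!identical(dim(pre$values), dim(post$values)))
    stop("pre and post volumes have different grid shapes", call. = FALSE)
  if (max(abs(pre$spacing - post$spacing)) > 1e-9)
    stop("pre and post volumes have different voxel spacings", call. = FALSE)
  image_volume(post$values - pre$values, post$spacing, post$origin)
}

#' Intensity normalization to fixed mean and scale
#'
#' Linearly rescales the whole volume so the voxel mean is 0 and the voxel
#' standard deviation equals `scale` (default 100), the convention used for
#' MR intensity normalization before texture feature extraction. The
#' standard deviation uses the population (n-denominator) convention. By
#' default statistics are computed over the whole volume; supply `mask` with
#' `roi_only = TRUE` to normalize using ROI statistics instead.
#'
#' @param vol an `image_volume`.
#' @param scale target standard deviation after normalization.
#' @param mask optional logical array; required when `roi_only = TRUE`.
#' @param roi_only logical; compute mean/sd over the masked voxels only.
#' @return The normalized `image_volume`.
#' @export
normalize_intensity <- function(vol, scale = 100, mask = NULL,
                                roi_only = FALSE) {
  stopifnot(is_image_volume(vol))
  x <- vol$values
  sel <- if (roi_only) {
    if (is.null(mask)) stop("`roi_only = TRUE` needs a mask", call. = FALSE)
    x[check_mask(vol, mask)]
  } else as.vector(x)
  mu <- mean(sel)
  sig <- sqrt(mean((sel - mu)^2))
  if (sig <= 0 || !is.finite(sig))
    stop("constant volume: normalization undefined", call. = FALSE)
  image_volume((x - mu) / sig * scale, vol$spacing, vol$origin)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} that carry the voxel spacing in and out
#' of the `image_volume` container. Masks are written as 0/1 volumes.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns an `image_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[seq_len(3)]
  arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  image_volume(arr, spacing = spacing)
}

#' @rdname read_volume
#' @param vol an `image_volume` (or logical mask array with `spacing`).
#' @param spacing spacing used when `vol` is a bare array.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (is_image_volume(vol)) {
    arr <- vol$values
    spacing <- vol$spacing
  } else {
    arr <- vol + 0
    if (is.null(spacing)) stop("spacing required for a bare array")
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
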