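#' Fixed-bin-count gray-level discretization of a masked ROI
#'
#' Maps masked intensities to integer gray levels 1..`n_bins` with
#' equal-width bins spanning the ROI intensity range, the fixed-bin-count
#' convention of standard radiomics pipelines. The maximum intensity is
#' assigned the top level. A constant ROI is flagged degenerate and all
#' voxels receive level 1.
#'
#' @param vol an `image_volume`.
#' @param mask logical array aligned with `vol`; non-empty.
#' @param n_bins number of gray levels (default 8).
#' @return An object of class `discretized_roi`: integer `levels` per masked
#'   voxel, the voxel index `coords` (n x 3), the grid `dim`, `n_bins`, and
#'   a `degenerate` flag.
#' @export
discretize_fixed_bin_count <- function(vol, mask, n_bins = 8) {
  stopifnot(is_image_volume(vol))
  mask <- check_mask(vol, mask)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)
  x <- vol$values[mask]
  rng <- range(x)
  degenerate <- rng[1] == rng[2]
  if (degenerate) {
    warning("constant ROI: all voxels assigned gray level 1")
    levels <- rep(1L, length(x))
  } else {
    width <- (rng[2] - rng[1]) / n_bins
    levels <- pmin(as.integer(floor((x - rng[1]) / width)) + 1L, n_bins)
  }
  structure(list(levels = levels,
                 coords = which(mask, arr.ind = TRUE),
                 dim = dim(mask),
                 n_bins = n_bins,
                 degenerate = degenerate),
            class = "discretized_roi")
}

is_discretized_roi <- function(x) inherits(x, "discretized_roi")

#' @export
print.discretized_roi <- function(x, ...) {
  cat("discretized_roi:", length(x$levels), "voxels,", x$n_bins,
      "gray levels", if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

# Level array of the ROI: NA outside the mask. The workhorse layout for the
# texture matrices.
roi_level_array <- function(roi) {
  arr <- array(NA_integer_, roi$dim)
  arr[roi$coords] <- roi$levels
  arr
}
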