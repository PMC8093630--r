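#' Extract the five-feature radiomic vector from a lesion
#'
#' Runs the full preprocessing chain (intensity normalization to mean 0 /
#' sd `norm_scale`, isotropic cubic B-spline resampling to `target` mm
#' cubes with nearest-neighbour mask resampling, fixed-bin-count
#' discretization to `n_bins` gray levels) on both input channels, then
#' computes the five retained radiomic features:
#'
#' * F1 `sphericity` and F3 `gldm_dependence_variance` on the subtracted
#'   (contrast-enhancement) channel;
#' * F2 `intensity_kurtosis`, F4 `glrlm_lrhgle` and F5 `glszm_hglze` on the
#'   dynamic channel.
#'
#' First-order kurtosis is computed on the continuous (normalized,
#' resampled) intensities; the texture features on the discretized ROI.
#'
#' @param dynamic `image_volume`, the dynamic post-contrast acquisition.
#' @param subtracted `image_volume`, the subtracted image; same grid.
#' @param mask logical array aligned with both volumes.
#' @param target isotropic voxel edge in mm (default 0.90).
#' @param n_bins gray-level count for discretization (default 8).
#' @param norm_scale standard deviation after normalization (default 100).
#' @param resample apply the isotropic resampling stage (default `TRUE`).
#' @return A named numeric vector `c(F1, F2, F3, F4, F5)` with attributes
#'   recording the preprocessing parameters and channel of each feature.
#' @export
extract_features <- function(dynamic, subtracted, mask, target = 0.9,
                             n_bins = 8, norm_scale = 100, resample = TRUE) {
  stopifnot(is_image_volume(dynamic), is_image_volume(subtracted))
  if (!identical(dim(dynamic$values), dim(subtracted$values)))
    stop("dynamic and subtracted volumes must share one grid", call. = FALSE)
  mask <- check_mask(dynamic, mask)

  prep <- function(vol) {
    vol <- normalize_intensity(vol, scale = norm_scale)
    if (resample) resample_isotropic(vol, mask, target = target)
    else list(volume = vol, mask = mask)
  }
  dyn <- prep(dynamic)
  sub <- prep(subtracted)

  roi_dyn <- discretize_fixed_bin_count(dyn$volume, dyn$mask, n_bins)
  roi_sub <- discretize_fixed_bin_count(sub$volume, sub$mask, n_bins)

  out <- c(F1 = sphericity(sub$mask, sub$volume$spacing),
           F2 = intensity_kurtosis(dyn$volume, dyn$mask),
           F3 = gldm_dependence_variance(roi_sub),
           F4 = glrlm_lrhgle(roi_dyn),
           F5 = glszm_hglze(roi_dyn))
  attr(out, "channel") <- c(F1 = "subtracted", F2 = "dynamic",
                            F3 = "subtracted", F4 = "dynamic",
                            F5 = "dynamic")
  attr(out, "preprocessing") <- list(target = if (resample) target else NA,
                                     n_bins = n_bins,
                                     norm_scale = norm_scale)
  out
}

#' Write a per-subject radiomic feature table
#'
#' @param features matrix or data.frame with columns F1..F5 (rows =
#'   subjects) or a single feature vector from [extract_features()].
#' @param path output file; tab-delimited with a header row.
#' @param ids optional subject identifiers.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, ids = NULL) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  df <- as.data.frame(features)
  df <- cbind(subject = ids %||% seq_len(nrow(df)), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
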