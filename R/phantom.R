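# Textured ellipsoidal lesion phantoms: paired "dynamic" and "subtracted"
# volumes plus the ellipsoid mask, for exercising the feature-extraction
# chain without patient images.

#' Phantom specification
#'
#' @param shape grid size in voxels (length 3).
#' @param spacing voxel spacing in mm (length 3, positive).
#' @param semi_axes ellipsoid semi-axes in mm (length 3); must fit inside
#'   the grid.
#' @param texture one of `"constant"`, `"gradient"` (smooth linear ramp) or
#'   `"correlated"` (Gaussian-correlated noise field).
#' @param corr_length correlation length in mm for the correlated texture.
#' @param texture_sd intensity standard deviation of the texture field.
#' @param noise_sd standard deviation of i.i.d. voxel noise added to each
#'   channel.
#' @param baseline constant offset separating the dynamic from the
#'   subtracted channel.
#' @param lesion_contrast intensity added inside the lesion.
#' @param seed integer seed.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), spacing = c(1, 1, 1.2),
                         semi_axes = c(10, 8, 7),
                         texture = c("constant", "gradient", "correlated"),
                         corr_length = 4, texture_sd = 20, noise_sd = 5,
                         baseline = 50, lesion_contrast = 100, seed = 1) {
  texture <- match.arg(texture)
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               semi_axes = as.numeric(semi_axes), texture = texture,
               corr_length = corr_length, texture_sd = texture_sd,
               noise_sd = noise_sd, baseline = baseline,
               lesion_contrast = lesion_contrast, seed = as.integer(seed))
  if (length(spec$shape) != 3L || any(spec$shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (any(spec$spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  if (any(spec$semi_axes <= 0)) stop("`semi_axes` must be positive", call. = FALSE)
  if (any(2 * spec$semi_axes > (spec$shape - 1) * spec$spacing))
    stop("ellipsoid does not fit inside the grid", call. = FALSE)
  if (all(spec$semi_axes < spec$spacing / 2))
    stop("ellipsoid smaller than half a voxel: empty mask", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

# Separable Gaussian smoothing of a 3D array, kernel truncated at 3 sd,
# replicate padding. sigma per axis in voxel units.
gaussian_smooth3 <- function(arr, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2)); k <- k / sum(k)
    d <- dim(arr)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = d[ax])
    idx <- pmin(pmax(outer(seq_len(d[ax]), seq(-r, r), `+`), 1L), d[ax])
    sm <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) sm <- sm + k[t] * m[idx[, t], , drop = FALSE]
    arr <- aperm(array(sm, d[perm]), order(perm))
  }
  arr
}

#' Generate a textured ellipsoidal lesion phantom
#'
#' Builds a "dynamic" volume, a "subtracted" volume (the dynamic minus the
#' constant baseline, plus independent noise) and the binary ellipsoid
#' lesion mask (centre-of-voxel inclusion test). The chosen texture is
#' applied over the whole grid; the lesion adds a constant contrast inside
#' the mask.
#'
#' @param spec a [phantom_spec()].
#' @return A list `list(dynamic, subtracted, mask)`: two `image_volume`s
#'   and a logical array.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ctr <- (d + 1) / 2
  ax <- lapply(1:3, function(i) ((seq_len(d[i]) - ctr[i]) * spec$spacing[i]) /
                                  spec$semi_axes[i])
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mask <- q <= 1
  if (!any(mask)) stop("empty phantom mask", call. = FALSE)

  with_seed(derive_seed(spec$seed, "phantom"), {
    tex <- switch(spec$texture,
      constant = array(0, d),
      gradient = {
        ramp <- outer(outer(seq_len(d[1]) * spec$spacing[1],
                            0.5 * seq_len(d[2]) * spec$spacing[2], `+`),
                      0.25 * seq_len(d[3]) * spec$spacing[3], `+`)
        (ramp - mean(ramp)) / sd(ramp) * spec$texture_sd
      },
      correlated = {
        w <- array(rnorm(prod(d)), d)
        sm <- gaussian_smooth3(w, spec$corr_length / spec$spacing)
        (sm - mean(sm)) / sd(sm) * spec$texture_sd
      })
    dynamic <- spec$baseline + spec$lesion_contrast * (mask + 0) + tex +
      array(rnorm(prod(d), sd = spec$noise_sd), d)
    subtracted <- dynamic - spec$baseline +
      array(rnorm(prod(d), sd = spec$noise_sd), d)
    list(dynamic = image_volume(dynamic, spec$spacing),
         subtracted = image_volume(subtracted, spec$spacing),
         mask = mask)
  })
}

#' Write a phantom to NIfTI files
#'
#' Writes `<prefix>_dynamic.nii.gz`, `<prefix>_subtracted.nii.gz` and
#' `<prefix>_mask.nii.gz`, with the voxel spacing recorded in the headers.
#'
#' @param phantom result of [generate_phantom()].
#' @param prefix output path prefix.
#' @return The three paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  paths <- paste0(prefix, c("_dynamic.nii.gz", "_subtracted.nii.gz",
                            "_mask.nii.gz"))
  write_volume(phantom$dynamic, paths[1])
  write_volume(phantom$subtracted, paths[2])
  write_volume(phantom$mask, paths[3], spacing = phantom$dynamic$spacing)
  invisible(paths)
}
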