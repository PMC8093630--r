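# Isotropic resampling with cubic B-spline interpolation.
#
# The interpolation is the classical two-step scheme: a prefilter turns the
# samples into B-spline coefficients (mirror boundary), then the resampled
# values are separable weighted sums of 4 coefficients per axis with the
# cubic B-spline kernel. The coefficients are obtained by solving the
# banded interpolation system directly (the collocation matrix folds the
# mirror boundary), so the interpolant passes exactly through the original
# samples and reproduces polynomials up to degree 3: constants and linear
# ramps survive resampling unchanged up to floating point.

# Prefilter the columns-as-signals matrix: signals run along rows
# (dimension 1). Solves B %*% coef = s where B holds the cubic B-spline
# values at the sample positions under the mirror boundary.
bspline_prefilter_mat <- function(s) {
  n <- nrow(s)
  if (n == 1L) return(s)
  B <- bspline_eval_matrix(0:(n - 1L), n)
  solve(B, s)
}

# Cubic B-spline kernel.
bspline3 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, 2 / 3 - ax^2 + ax^3 / 2,
         ifelse(ax < 2, (2 - ax)^3 / 6, 0))
}

# Evaluation matrix W (n_new x n_old): row j holds the 4 kernel weights for
# continuous position t[j] (0-based index units), with mirror boundary.
bspline_eval_matrix <- function(t, n_old) {
  mirror <- function(i) {
    if (n_old == 1L) return(rep(1L, length(i)))
    p <- 2L * (n_old - 1L)
    i <- ((i %% p) + p) %% p
    ifelse(i >= n_old, p - i, i)
  }
  W <- matrix(0, length(t), n_old)
  i0 <- floor(t)
  for (off in -1:2) {
    idx <- mirror(i0 + off) + 1L
    w <- bspline3(t - (i0 + off))
    W[cbind(seq_along(t), idx)] <- W[cbind(seq_along(t), idx)] + w
  }
  W
}

# Apply 1D cubic-spline resampling along dimension `axis` of a 3D array.
resample_axis_bspline <- function(arr, axis, t_new) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  cf <- bspline_prefilter_mat(m)
  W <- bspline_eval_matrix(t_new, d[axis])
  res <- W %*% cf
  newd <- c(length(t_new), d[perm[2]], d[perm[3]])
  out <- array(res, dim = newd)
  aperm(out, order(perm))
}

resample_axis_nn <- function(arr, axis, t_new) {
  d <- dim(arr)
  idx <- pmin(pmax(round(t_new) + 1L, 1L), d[axis])
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

#' Resample a volume and mask to an isotropic grid
#'
#' Interpolates the image to cubic voxels of edge `target` mm with cubic
#' B-spline interpolation (exact interpolation via the recursive prefilter)
#' and the mask with nearest-neighbour interpolation, the standard
#' radiomics preprocessing pair. The new grid shares the origin of the old
#' one and covers the same physical extent (no extrapolation).
#'
#' @param vol an `image_volume`.
#' @param mask logical array aligned with `vol` (or `NULL` to resample the
#'   image alone).
#' @param target isotropic voxel edge length in mm (default 0.90).
#' @return A list with elements `volume` (resampled `image_volume`) and
#'   `mask` (resampled logical array, or `NULL`).
#' @export
resample_isotropic <- function(vol, mask = NULL, target = 0.9) {
  stopifnot(is_image_volume(vol), is.numeric(target), target > 0)
  if (!is.null(mask)) mask <- check_mask(vol, mask)
  d <- dim(vol$values)
  t_new <- vector("list", 3L)
  for (ax in 1:3) {
    extent <- (d[ax] - 1L) * vol$spacing[ax]
    n_new <- max(1L, floor(extent / target) + 1L)
    t_new[[ax]] <- (seq_len(n_new) - 1) * target / vol$spacing[ax]
  }
  img <- vol$values
  msk <- if (!is.null(mask)) mask + 0L else NULL
  for (ax in 1:3) {
    img <- resample_axis_bspline(img, ax, t_new[[ax]])
    if (!is.null(msk)) msk <- resample_axis_nn(msk, ax, t_new[[ax]])
  }
  if (!is.null(msk)) {
    msk <- msk > 0
    if (!any(msk)) stop("resampled mask is empty", call. = FALSE)
  }
  list(volume = image_volume(img, rep(target, 3), vol$origin),
       mask = msk)
}
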