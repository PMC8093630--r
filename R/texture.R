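# Gray-level texture matrices over a discretized ROI: dependence (GLDM),
# run length (GLRLM) and size zone (GLSZM), each with the single feature
# retained by the reduction step. All three use the 26-connected (Chebyshev
# distance 1) 3D neighbourhood.

# The 26 neighbour offsets, and the 13 unique direction representatives
# (one per +/- pair) used for runs and zone adjacency.
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

unique_directions_13 <- function() {
  g <- neighbor_offsets_26()
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[keep, , drop = FALSE]
}

# Aligned views of an array under an integer offset: returns the two index
# lists (base and shifted) covering the overlap region.
offset_ranges <- function(d, off) {
  base <- shifted <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      base[[ax]] <- seq_len(d[ax] - o)
      shifted[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      base[[ax]] <- seq_len(d[ax] + o) - o
      shifted[[ax]] <- seq_len(d[ax] + o)
    }
    if (d[ax] + abs(o) <= abs(o)) return(NULL)
  }
  list(base = base, shifted = shifted)
}

#' Gray level dependence matrix and dependence variance
#'
#' For every masked voxel the dependence is the number of 26-neighbourhood
#' voxels (inside the mask) whose gray level differs from the centre level
#' by at most `alpha`, plus one for the centre voxel itself (set
#' `include_center = FALSE` for the neighbours-only convention). The GLDM
#' entry P(i, j) counts voxels of level i with dependence j; the dependence
#' variance is the variance of j under the normalized matrix.
#'
#' @param roi a `discretized_roi`.
#' @param alpha gray-level difference tolerance (default 0).
#' @param include_center count the centre voxel in the dependence (default
#'   `TRUE`, the reference-extractor convention).
#' @return `gldm_matrix` returns the P(i, j) count matrix;
#'   `gldm_dependence_variance` the scalar feature.
#' @export
gldm_matrix <- function(roi, alpha = 0, include_center = TRUE) {
  stopifnot(is_discretized_roi(roi), alpha >= 0)
  lev <- roi_level_array(roi)
  d <- dim(lev)
  dep <- array(0L, d)
  offs <- neighbor_offsets_26()
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    rg <- offset_ranges(d, off)
    if (is.null(rg)) next
    a <- lev[rg$base[[1]], rg$base[[2]], rg$base[[3]], drop = FALSE]
    b <- lev[rg$shifted[[1]], rg$shifted[[2]], rg$shifted[[3]], drop = FALSE]
    hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    dep[rg$base[[1]], rg$base[[2]], rg$base[[3]]] <-
      dep[rg$base[[1]], rg$base[[2]], rg$base[[3]]] + as.integer(hit)
  }
  j <- dep[roi$coords] + as.integer(include_center)
  i <- roi$levels
  jmin <- if (include_center) 1L else 0L     # isolated voxels: 0 neighbours
  tab <- table(factor(i, levels = seq_len(roi$n_bins)),
               factor(j, levels = jmin:max(j)))
  unclass(as.matrix(tab))
}

#' @rdname gldm_matrix
#' @export
gldm_dependence_variance <- function(roi, alpha = 0, include_center = TRUE) {
  P <- gldm_matrix(roi, alpha, include_center)
  p <- P / sum(P)
  j <- as.numeric(colnames(p) %||% seq_len(ncol(p)))
  pj <- colSums(p)
  mu <- sum(pj * j)
  sum(pj * (j - mu)^2)
}

# Maximal runs of equal gray level along one direction. Returns a data.frame
# with columns level and length. Lines are enumerated over the full grid so
# out-of-mask voxels (NA level) break runs.
runs_along_direction <- function(lev, dir) {
  d <- dim(lev)
  ii <- slice.index(lev, 1); jj <- slice.index(lev, 2); kk <- slice.index(lev, 3)
  ax <- which(dir != 0)[1]
  s <- switch(ax, ii, jj, kk) * dir[ax]     # step parameter: +1 per voxel step
  lx <- ii - s * dir[1]; ly <- jj - s * dir[2]; lz <- kk - s * dir[3]
  # encode line id; start coordinates lie in [1 - max(d), 2 max(d)]
  o <- max(d); B <- 3 * max(d) + 2
  line <- ((lx + o) * B + (ly + o)) * B + (lz + o)
  ord <- order(line, s)
  lv <- as.vector(lev)[ord]
  ln <- as.vector(line)[ord]
  n <- length(lv)
  same <- c(FALSE, ln[-1] == ln[-n] &
                   !is.na(lv[-1]) & !is.na(lv[-n]) & lv[-1] == lv[-n])
  starts <- which(!same)
  lens <- diff(c(starts, n + 1L))
  keep <- !is.na(lv[starts])
  data.frame(level = lv[starts][keep], length = lens[keep])
}

#' Gray level run length matrices and long-run high-gray-level emphasis
#'
#' Builds one run-length matrix P(i, j) per unique 3D direction (13 in
#' total): counts of maximal runs of consecutive voxels with equal gray
#' level i and run length j inside the mask. The feature is
#' `sum(P * i^2 * j^2) / Nr` per direction (Nr = total run count), averaged
#' without weighting over the 13 directions.
#'
#' @param roi a `discretized_roi`.
#' @return `glrlm_matrices` returns a list of 13 count matrices;
#'   `glrlm_lrhgle` the scalar feature.
#' @export
glrlm_matrices <- function(roi) {
  stopifnot(is_discretized_roi(roi))
  lev <- roi_level_array(roi)
  dirs <- unique_directions_13()
  out <- vector("list", nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    runs <- runs_along_direction(lev, dirs[r, ])
    tab <- table(factor(runs$level, levels = seq_len(roi$n_bins)),
                 factor(runs$length, levels = seq_len(max(runs$length))))
    out[[r]] <- unclass(as.matrix(tab))
  }
  out
}

#' @rdname glrlm_matrices
#' @export
glrlm_lrhgle <- function(roi) {
  mats <- glrlm_matrices(roi)
  vals <- vapply(mats, function(P) {
    i2 <- as.numeric(rownames(P))^2
    j2 <- as.numeric(colnames(P))^2
    sum(P * outer(i2, j2)) / sum(P)
  }, numeric(1))
  mean(vals)
}

#' Gray level size zone matrix and high-gray-level zone emphasis
#'
#' Zones are 26-connected components of equal gray level inside the mask;
#' P(i, s) counts zones of level i and size s voxels. The feature is
#' `sum(P * i^2) / Nz` with Nz the total zone count.
#'
#' @param roi a `discretized_roi`.
#' @return `glszm_zones` returns a data.frame of zones (level, size);
#'   `glszm_hglze` the scalar feature.
#' @export
glszm_zones <- function(roi) {
  stopifnot(is_discretized_roi(roi))
  lev <- roi_level_array(roi)
  d <- dim(lev)
  lin <- array(seq_len(prod(d)), d)
  dirs <- unique_directions_13()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    rg <- offset_ranges(d, dirs[r, ])
    if (is.null(rg)) next
    a <- lev[rg$base[[1]], rg$base[[2]], rg$base[[3]], drop = FALSE]
    b <- lev[rg$shifted[[1]], rg$shifted[[2]], rg$shifted[[3]], drop = FALSE]
    hit <- which(!is.na(a) & !is.na(b) & a == b)
    if (!length(hit)) next
    la <- lin[rg$base[[1]], rg$base[[2]], rg$base[[3]], drop = FALSE]
    lb <- lin[rg$shifted[[1]], rg$shifted[[2]], rg$shifted[[3]], drop = FALSE]
    from <- c(from, la[hit]); to <- c(to, lb[hit])
  }
  vox <- lin[roi$coords]
  vid <- match(seq_len(prod(d)), vox)        # linear index -> roi voxel id
  g <- igraph::graph_from_edgelist(cbind(vid[from], vid[to]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(vox) - igraph::vcount(g)))
  comp <- igraph::components(g)
  data.frame(level = vapply(split(roi$levels, comp$membership),
                            function(z) z[1], integer(1)),
             size = as.integer(comp$csize))
}

#' @rdname glszm_zones
#' @export
glszm_hglze <- function(roi) {
  z <- glszm_zones(roi)
  sum(z$level^2) / nrow(z)
}

#' Pearson kurtosis of masked intensities
#'
#' Fourth central moment over the squared second central moment, computed
#' with population (n-denominator) moments on continuous intensities
#' (non-excess convention: a Gaussian gives 3).
#'
#' @param vol an `image_volume`.
#' @param mask logical array aligned with `vol`; at least 4 masked voxels.
#' @return The scalar kurtosis.
#' @export
intensity_kurtosis <- function(vol, mask) {
  stopifnot(is_image_volume(vol))
  mask <- check_mask(vol, mask)
  x <- vol$values[mask]
  if (length(x) < 4L) stop("kurtosis needs at least 4 masked voxels", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("zero intensity variance in the ROI", call. = FALSE)
  mean((x - m)^4) / m2^2
}
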