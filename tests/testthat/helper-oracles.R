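# Independent brute-force oracles for the texture/shape statistics and
# small fixture builders. These deliberately use naive triple loops and
# breadth-first search so they share no code with the implementation.

# random small discretized ROI: random grid dims (each 2..max_dim), random
# mask (every voxel kept with prob p_mask, at least one kept), random levels
random_roi <- function(seed, max_dim = 5, n_levels = 4, p_mask = 0.8) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  vol <- image_volume(array(runif(prod(d)), d))
  mask <- array(runif(prod(d)) < p_mask, d)
  if (!any(mask)) mask[sample(prod(d), 1)] <- TRUE
  roi <- discretize_fixed_bin_count(vol, mask, n_levels)
  roi
}

all_offsets_26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
all_offsets_26 <- all_offsets_26[rowSums(abs(all_offsets_26)) > 0, ]

oracle_level_array <- function(roi) {
  arr <- array(NA_integer_, roi$dim)
  arr[roi$coords] <- roi$levels
  arr
}

# GLDM dependence variance: per-voxel neighbour loop.
oracle_gldm_dv <- function(roi, alpha = 0, include_center = TRUE) {
  lev <- oracle_level_array(roi)
  d <- dim(lev)
  deps <- numeric(0)
  for (r in seq_len(nrow(roi$coords))) {
    v <- roi$coords[r, ]
    li <- lev[v[1], v[2], v[3]]
    cnt <- 0L
    for (o in seq_len(nrow(all_offsets_26))) {
      w <- v + all_offsets_26[o, ]
      if (any(w < 1) || any(w > d)) next
      lw <- lev[w[1], w[2], w[3]]
      if (!is.na(lw) && abs(lw - li) <= alpha) cnt <- cnt + 1L
    }
    deps <- c(deps, cnt + as.integer(include_center))
  }
  mean((deps - mean(deps))^2)
}

# 13 scan directions as used for run/zone statistics.
oracle_directions <- function() {
  g <- all_offsets_26
  g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))), ,
    drop = FALSE]
}

# GLRLM long-run high-gray-level emphasis: explicit run scanner. A run
# starts at any voxel whose predecessor along the direction is absent or
# has a different level, and extends while the level repeats.
oracle_glrlm_lrhgle <- function(roi) {
  lev <- oracle_level_array(roi)
  d <- dim(lev)
  at <- function(v) {
    if (any(v < 1) || any(v > d)) return(NA_integer_)
    lev[v[1], v[2], v[3]]
  }
  dirs <- oracle_directions()
  per_dir <- numeric(nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    dir <- dirs[k, ]
    tot <- 0; nr <- 0
    for (r in seq_len(nrow(roi$coords))) {
      v <- roi$coords[r, ]
      li <- at(v)
      prev <- at(v - dir)
      if (!is.na(prev) && prev == li) next      # not a run start
      len <- 1L
      w <- v + dir
      while (!is.na(at(w)) && at(w) == li) {
        len <- len + 1L
        w <- w + dir
      }
      tot <- tot + li^2 * len^2
      nr <- nr + 1
    }
    per_dir[k] <- tot / nr
  }
  mean(per_dir)
}

# GLSZM high-gray-level zone emphasis: flood fill over 26-connected
# same-level components.
oracle_glszm_hglze <- function(roi) {
  lev <- oracle_level_array(roi)
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (r in seq_len(nrow(roi$coords))) {
    v <- roi$coords[r, ]
    if (seen[v[1], v[2], v[3]]) next
    li <- lev[v[1], v[2], v[3]]
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (o in seq_len(nrow(all_offsets_26))) {
        w <- u + all_offsets_26[o, ]
        if (any(w < 1) || any(w > d)) next
        if (seen[w[1], w[2], w[3]]) next
        lw <- lev[w[1], w[2], w[3]]
        if (!is.na(lw) && lw == li) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue <- c(queue, list(w))
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(level = li, size = size)
  }
  z <- do.call(rbind, zones)
  sum(z[, "level"]^2) / nrow(z)
}

# Voxel-face surface area: count exposed faces of foreground voxels.
oracle_voxel_face_area <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- mask
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  area <- 0
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[ax] <- sgn
      sh <- pad[1L + off[1] + seq_len(d[1]), 1L + off[2] + seq_len(d[2]),
                1L + off[3] + seq_len(d[3])]
      area <- area + face[ax] * sum(mask & !sh)
    }
  }
  area
}

# digital ball mask
ball_mask <- function(radius, n = 2 * radius + 5) {
  ctr <- (n + 1) / 2
  idx <- seq_len(n)
  q <- outer(outer((idx - ctr)^2, (idx - ctr)^2, `+`), (idx - ctr)^2, `+`)
  array(q <= radius^2, c(n, n, n))
}

# two-sided Fisher p by direct multivariate hypergeometric enumeration
# (tables with the observed margins, probability <= observed summed)
oracle_fisher_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  logp_table <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(m + 1))
  }
  obs <- logp_table(tab)
  total <- 0
  # enumerate all tables with the given margins, row by row
  recurse <- function(filled, row) {
    if (row == nrow(tab)) {
      last <- cs - colSums(filled)
      if (any(last < 0)) return()
      m <- rbind(filled, last)
      lp <- logp_table(m)
      if (lp <= obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    free <- cs - if (nrow(filled)) colSums(filled) else rep(0, length(cs))
    cells <- vector("list", ncol(tab) - 1L)
    enum_row <- function(partial, col) {
      left <- rs[row] - sum(partial)
      if (col == ncol(tab)) {
        if (left >= 0 && left <= free[col])
          recurse(rbind(filled, c(partial, left)), row + 1L)
        return()
      }
      for (v in 0:min(left, free[col])) enum_row(c(partial, v), col + 1L)
    }
    enum_row(integer(0), 1L)
  }
  recurse(tab[integer(0), , drop = FALSE], 1L)
  min(1, total)
}
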