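# Preprocessing chain: subtraction, normalization, isotropic resampling,
# fixed-bin-count discretization.

make_vol <- function(values, spacing = c(1, 1, 1)) {
  image_volume(values, spacing)
}

test_that("image subtraction is exact voxelwise and validates grids", {
  set.seed(1)
  a <- make_vol(array(rnorm(60), c(5, 4, 3)))
  b <- make_vol(array(rnorm(60), c(5, 4, 3)))
  s <- subtract_images(a, b)
  # elementwise loop oracle
  expected <- array(0, dim(a$values))
  for (i in seq_along(expected)) expected[i] <- b$values[i] - a$values[i]
  expect_identical(s$values, expected)
  expect_true(all(subtract_images(a, a)$values == 0))
  cc <- make_vol(array(2, c(5, 4, 3)))
  expect_equal(subtract_images(cc, b)$values, b$values - 2)
  expect_error(subtract_images(a, make_vol(array(0, c(4, 4, 3)))), "shapes")
  expect_error(subtract_images(a, make_vol(array(0, c(5, 4, 3)), c(2, 1, 1))),
               "spacings")
})

test_that("normalization hits mean 0 / sd 100 with the population convention", {
  v <- make_vol(array(c(0, 2), c(2, 1, 1)))
  out <- normalize_intensity(v)
  expect_equal(as.numeric(out$values), c(-100, 100))
  set.seed(2)
  x <- make_vol(array(rexp(1000), c(10, 10, 10)))
  n1 <- normalize_intensity(x)
  expect_lt(abs(mean(n1$values)), 1e-6)
  expect_lt(abs(sqrt(mean((n1$values - mean(n1$values))^2)) - 100), 1e-6)
  n2 <- normalize_intensity(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-10)
  expect_error(normalize_intensity(make_vol(array(5, c(3, 3, 3)))), "constant")
})

test_that("ROI-only normalization uses mask statistics", {
  set.seed(3)
  v <- make_vol(array(rnorm(125, 10, 3), c(5, 5, 5)))
  m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
  out <- normalize_intensity(v, mask = m, roi_only = TRUE)
  inside <- out$values[m]
  expect_lt(abs(mean(inside)), 1e-9)
  expect_lt(abs(sqrt(mean((inside - mean(inside))^2)) - 100), 1e-6)
})

test_that("b-spline resampling reproduces constants and interior linear ramps", {
  cv <- make_vol(array(7, c(8, 8, 8)))
  rc <- resample_isotropic(cv, NULL, 0.7)
  expect_lt(max(abs(rc$volume$values - 7)), 1e-5)
  expect_equal(rc$volume$spacing, rep(0.7, 3))

  d <- c(40, 40, 40)
  ramp <- array(0, d)
  for (k in 1:d[3]) ramp[, , k] <- outer(2 * seq_len(d[1]), 3 * seq_len(d[2]), `+`) - k
  v <- make_vol(ramp, c(1, 1.2, 0.8))
  rs <- resample_isotropic(v, NULL, 0.9)
  nd <- dim(rs$volume$values)
  ti <- (seq_len(nd[1]) - 1) * 0.9 / 1 + 1
  tj <- (seq_len(nd[2]) - 1) * 0.9 / 1.2 + 1
  tk <- (seq_len(nd[3]) - 1) * 0.9 / 0.8 + 1
  expected <- outer(outer(2 * ti, 3 * tj, `+`), -tk, `+`)
  # away from the mirror boundary (whose influence decays geometrically)
  # the cubic spline reproduces linear polynomials to floating precision
  core <- function(a) {
    m <- 14
    a[(m + 1):(dim(a)[1] - m), (m + 1):(dim(a)[2] - m), (m + 1):(dim(a)[3] - m)]
  }
  expect_lt(max(abs(core(rs$volume$values) - core(expected))), 1e-6)
  expect_lt(max(abs(rs$volume$values - expected)), 0.6)
})

test_that("resampling at the native spacing is an identity and masks stay binary", {
  set.seed(4)
  v <- make_vol(array(rnorm(11^3), c(11, 11, 11)), c(0.9, 0.9, 0.9))
  m <- array(FALSE, c(11, 11, 11)); m[4:8, 4:8, 4:8] <- TRUE
  rs <- resample_isotropic(v, m, 0.9)
  expect_equal(rs$volume$values, v$values, tolerance = 1e-8)
  expect_identical(rs$mask, m)
  expect_error(resample_isotropic(v, m, -1))
})

test_that("fixed-bin-count discretization matches a per-value binning loop", {
  v <- make_vol(array(0:7, c(8, 1, 1)))
  roi <- discretize_fixed_bin_count(v, array(TRUE, c(8, 1, 1)), 8)
  expect_identical(roi$levels, 1:8)

  set.seed(5)
  x <- runif(1000)
  v2 <- make_vol(array(x, c(10, 10, 10)))
  roi2 <- discretize_fixed_bin_count(v2, array(TRUE, c(10, 10, 10)), 8)
  w <- (max(x) - min(x)) / 8
  oracle <- pmin(floor((x - min(x)) / w) + 1, 8)
  expect_identical(roi2$levels, as.integer(oracle))
  expect_equal(length(roi2$levels), 1000L)
  expect_gte(min(roi2$levels), 1L)
  expect_lte(max(roi2$levels), 8L)

  const <- make_vol(array(1, c(3, 3, 3)))
  expect_warning(roi3 <- discretize_fixed_bin_count(const, array(TRUE, c(3, 3, 3)), 8),
                 "constant ROI")
  expect_true(roi3$degenerate)
  expect_true(all(roi3$levels == 1L))
  expect_error(discretize_fixed_bin_count(v, array(TRUE, c(8, 1, 1)), 1),
               "at least 2")
})
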