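# The five radiomic features against analytic limits and independent
# brute-force oracles.

test_that("sphericity approaches 1 for a digital ball and orders shapes", {
  ball <- ball_mask(20)
  s_ball <- sphericity(ball)
  expect_gte(s_ball, 0.97)
  expect_lte(s_ball, 1.001)
  expect_equal(sphericity(ball, c(2, 2, 2)), s_ball)   # dimensionless
  rod <- array(FALSE, c(5, 5, 24)); rod[3, 3, 3:22] <- TRUE
  expect_lt(sphericity(rod), s_ball)
  # mesh area below the voxel-face staircase bound, above the true sphere
  m <- mask_mesh_measures(ball)
  expect_lt(m$area, oracle_voxel_face_area(ball))
  expect_gt(m$area, 4 * pi * 20^2 * 0.95)
  expect_lt(abs(m$volume - 4 / 3 * pi * 20^3), 4 * pi * 20^2)
  # a single voxel still yields a valid mesh
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  s1 <- sphericity(one)
  expect_true(is.finite(s1) && s1 > 0 && s1 <= 1.001)
  expect_error(sphericity(array(FALSE, c(3, 3, 3))), "foreground")
})

test_that("kurtosis uses population central moments (Pearson convention)", {
  v <- image_volume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  m <- array(TRUE, c(4, 1, 1))
  expect_equal(intensity_kurtosis(v, m), 1.64)   # m2 = 1.25, m4 = 2.5625
  set.seed(6)
  g <- image_volume(array(rnorm(1e6), c(100, 100, 100)))
  expect_lt(abs(intensity_kurtosis(g, array(TRUE, c(100, 100, 100))) - 3), 0.02)
  # affine invariance
  v2 <- image_volume(3.7 * v$values + 11)
  expect_equal(intensity_kurtosis(v2, m), 1.64)
  expect_error(intensity_kurtosis(image_volume(array(1, c(4, 1, 1))), m), "variance")
  expect_error(intensity_kurtosis(v, array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))),
               "4 masked")
})

test_that("GLDM dependence variance matches the neighbour-loop oracle", {
  # singleton
  v <- image_volume(array(1:2, c(2, 1, 1)))
  m <- array(c(TRUE, FALSE), c(2, 1, 1))
  roi1 <- suppressWarnings(discretize_fixed_bin_count(v, m, 2))  # single voxel
  expect_equal(gldm_dependence_variance(roi1), 0)
  # constant 3x3x3 cube: dependence = 1 + neighbour count
  const <- image_volume(array(0, c(3, 3, 3)) + 5)
  roic <- suppressWarnings(discretize_fixed_bin_count(const, array(TRUE, c(3, 3, 3)), 8))
  expect_equal(gldm_dependence_variance(roic), oracle_gldm_dv(roic))
  # random ROIs, both centre conventions and alpha values
  for (seed in 1:25) {
    roi <- random_roi(seed)
    expect_equal(gldm_dependence_variance(roi), oracle_gldm_dv(roi),
                 info = paste("seed", seed))
  }
  roi <- random_roi(101)
  expect_equal(gldm_dependence_variance(roi, alpha = 1),
               oracle_gldm_dv(roi, alpha = 1))
  expect_equal(gldm_dependence_variance(roi, include_center = FALSE),
               oracle_gldm_dv(roi, include_center = FALSE))
})

test_that("GLRLM long-run emphasis matches the run-scanner oracle", {
  # [1,1,2] along one line: runs (1, len 2), (2, len 1) -> (1*4 + 4*1)/2 = 4
  v <- image_volume(array(c(0, 0, 1), c(3, 1, 1)))
  roi <- discretize_fixed_bin_count(v, array(TRUE, c(3, 1, 1)), 2)
  mats <- glrlm_matrices(roi)
  stat1 <- vapply(mats, function(P) {
    sum(P * outer(as.numeric(rownames(P))^2, as.numeric(colnames(P))^2)) / sum(P)
  }, numeric(1))
  expect_true(4 %in% round(stat1, 10))           # the x-direction
  expect_equal(glrlm_lrhgle(roi), oracle_glrlm_lrhgle(roi))
  # all-distinct levels: every run has length 1
  v2 <- image_volume(array(seq_len(8), c(2, 2, 2)))
  roi2 <- discretize_fixed_bin_count(v2, array(TRUE, c(2, 2, 2)), 8)
  mats2 <- glrlm_matrices(roi2)
  expect_true(all(vapply(mats2, function(P) all(P[, -1] == 0), logical(1))))
  for (seed in 1:25) {
    roi <- random_roi(seed + 300)
    expect_equal(glrlm_lrhgle(roi), oracle_glrlm_lrhgle(roi),
                 info = paste("seed", seed))
  }
})

test_that("GLSZM zone emphasis matches the flood-fill oracle", {
  const <- image_volume(array(1, c(3, 3, 3)))
  roic <- suppressWarnings(discretize_fixed_bin_count(const, array(TRUE, c(3, 3, 3)), 8))
  expect_equal(glszm_hglze(roic), 1)             # one zone at level 1
  # alternating slabs of levels 1/2: zones are the slabs
  slab <- array(rep(c(0, 1), each = 9, times = 2), c(3, 3, 4))
  v <- image_volume(slab)
  roi <- discretize_fixed_bin_count(v, array(TRUE, c(3, 3, 4)), 2)
  z <- glszm_zones(roi)
  expect_equal(nrow(z), 4L)
  expect_equal(sort(z$size), rep(9L, 4))
  expect_equal(glszm_hglze(roi), mean(c(1, 4, 1, 4)))
  for (seed in 1:25) {
    roi <- random_roi(seed + 600)
    expect_equal(glszm_hglze(roi), oracle_glszm_hglze(roi),
                 info = paste("seed", seed))
  }
})

test_that("texture matrices conserve voxel mass", {
  for (seed in c(2, 17, 44)) {
    roi <- random_roi(seed + 900)
    nv <- length(roi$levels)
    expect_equal(sum(gldm_matrix(roi)), nv)
    for (P in glrlm_matrices(roi)) {
      j <- as.numeric(colnames(P))
      expect_equal(sum(sweep(P, 2, j, `*`)), nv)
    }
    z <- glszm_zones(roi)
    expect_equal(sum(z$size), nv)
  }
})

test_that("extract_features composes the chain consistently", {
  spec <- phantom_spec(shape = c(24, 24, 20), spacing = c(1, 1, 1.1),
                       semi_axes = c(8, 7, 6), texture = "correlated",
                       corr_length = 3, seed = 21)
  ph <- generate_phantom(spec)
  f <- extract_features(ph$dynamic, ph$subtracted, ph$mask)
  expect_named(f, paste0("F", 1:5))
  expect_true(all(is.finite(f)))
  expect_true(f["F1"] > 0 && f["F1"] <= 1.001)
  expect_gte(f["F2"], 1)
  expect_true(all(f[c("F3", "F4", "F5")] >= 0))
  # identical channels give values consistent with single-channel calls
  f2 <- extract_features(ph$dynamic, ph$dynamic, ph$mask)
  dyn <- normalize_intensity(ph$dynamic)
  rs <- resample_isotropic(dyn, ph$mask, 0.9)
  expect_equal(unname(f2["F2"]), intensity_kurtosis(rs$volume, rs$mask))
  roi <- discretize_fixed_bin_count(rs$volume, rs$mask, 8)
  expect_equal(unname(f2["F3"]), gldm_dependence_variance(roi))
  expect_equal(unname(f2["F4"]), glrlm_lrhgle(roi))
})

test_that("features are invariant to a constant intensity shift", {
  spec <- phantom_spec(shape = c(20, 20, 18), semi_axes = c(6, 5, 5),
                       texture = "correlated", corr_length = 2, seed = 8)
  ph <- generate_phantom(spec)
  shifted <- image_volume(ph$dynamic$values + 500, ph$dynamic$spacing)
  f0 <- extract_features(ph$dynamic, ph$subtracted, ph$mask)
  f1 <- extract_features(shifted, ph$subtracted, ph$mask)
  expect_equal(f1, f0, tolerance = 1e-8)
})

test_that("long correlation length raises run emphasis; sphere beats rod on F1", {
  base <- function(len, seed) {
    spec <- phantom_spec(shape = c(24, 24, 24), spacing = c(1, 1, 1),
                         semi_axes = c(9, 9, 9), texture = "correlated",
                         corr_length = len, noise_sd = 0, seed = seed)
    ph <- generate_phantom(spec)
    extract_features(ph$dynamic, ph$subtracted, ph$mask)
  }
  f_long <- base(5, 31)
  f_short <- base(0.5, 31)
  expect_gt(f_long["F4"], f_short["F4"])

  sph_spec <- phantom_spec(shape = c(24, 24, 24), spacing = c(1, 1, 1),
                           semi_axes = c(9, 9, 9), texture = "constant", seed = 4)
  rod_spec <- phantom_spec(shape = c(10, 10, 40), spacing = c(1, 1, 1),
                           semi_axes = c(1.4, 1.4, 18), texture = "constant",
                           seed = 4)
  ps <- generate_phantom(sph_spec); pr <- generate_phantom(rod_spec)
  fs <- extract_features(ps$dynamic, ps$subtracted, ps$mask)
  fr <- extract_features(pr$dynamic, pr$subtracted, pr$mask)
  expect_gt(fs["F1"], fr["F1"])
})
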