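test_that("config validation rejects bad correlation structures", {
  r <- list(region_spec("a", c(-10, 0, 0)), region_spec("b", c(-20, 0, 0)))
  bad <- matrix(c(1, 2, 2, 1), 2)   # |r| > 1, not PSD
  expect_error(cohort_config(regions = r, laterality_corr = bad),
               "positive semi-definite")
  asym <- matrix(c(1, .2, .4, 1), 2)
  expect_error(cohort_config(regions = r, laterality_corr = asym),
               "symmetric")
  expect_error(region_spec("x", c(10, 0, 0)), "left hemisphere")
})

test_that("sampled LI values match the requested moments and correlation", {
  r <- list(region_spec("a", c(-10, 0, 0)), region_spec("b", c(-20, 0, 0)),
            region_spec("c", c(-30, 0, 0)))
  cfg <- cohort_config(n_subjects = 10000, regions = r,
                       laterality_mean = 1, laterality_sd = 0.5,
                       atypical_fraction = 0, rng_seed = 9)
  gt <- sample_laterality(cfg)
  # identity correlation: sample cross-correlations within +/- 0.03 of 0
  off <- gt$realized_corr[upper.tri(gt$realized_corr)]
  expect_true(all(abs(off) < 0.03))
  expect_true(all(abs(colMeans(gt$li) - 1) < 0.02))
  expect_true(all(abs(apply(gt$li, 2, sd) - 0.5) < 0.02))

  # perfect correlation, degenerate MVN
  cfg1 <- cohort_config(n_subjects = 200, regions = r[1:2],
                        laterality_corr = matrix(c(1, 1, 1, 1), 2),
                        atypical_fraction = 0, rng_seed = 9)
  gt1 <- sample_laterality(cfg1)
  expect_equal(gt1$realized_corr[1, 2], 1.0, tolerance = 1e-12)

  # determinism
  expect_identical(sample_laterality(cfg1), sample_laterality(cfg1))
})

test_that("handedness mixture flips means and lowers dominance agreement", {
  r <- list(region_spec("a", c(-10, 0, 0)), region_spec("b", c(-20, 0, 0)))
  cfg <- cohort_config(n_subjects = 4000, regions = r,
                       laterality_corr = matrix(c(1, .6, .6, 1), 2),
                       atypical_fraction = 0.4, atypical_mode = "joint",
                       rng_seed = 5)
  gt <- sample_laterality(cfg)
  at <- gt$handedness == "atypical"
  expect_equal(mean(at), 0.4, tolerance = 0.05)
  expect_true(all(gt$mean_sign[at, ] == -1))
  expect_true(all(gt$mean_sign[!at, ] == 1))

  cfg_i <- cohort_config(n_subjects = 4000, regions = r,
                         laterality_corr = matrix(c(1, .6, .6, 1), 2),
                         atypical_fraction = 0.4,
                         atypical_mode = "independent", rng_seed = 5)
  gt_i <- sample_laterality(cfg_i)
  ati <- gt_i$handedness == "atypical"
  # independent flips decorrelate the two regions' dominance signs
  agree_joint <- mean(rowSums(gt$mean_sign[at, ]) != 0)
  agree_ind <- mean(rowSums(gt_i$mean_sign[ati, ]) != 0)
  expect_equal(agree_joint, 1)
  expect_equal(agree_ind, 0.5, tolerance = 0.05)
})

test_that("rendering realizes LI as the planted left/right split", {
  g <- symmetric_grid(c(16, 12, 12))
  ctr <- c(-7, -1, -1)
  lin_l <- lin_of(g, mni_to_voxel(g, ctr))
  lin_r <- lin_of(g, mni_to_voxel(g, ctr * c(-1, 1, 1)))

  # LI = 0, no noise: exactly mirror-symmetric image
  co0 <- planted_cohort(0, g, ctr)
  v <- co0$Y[1, ]
  expect_equal(v, v[mirror_indices(g)])

  # lambda = 1: left peak exceeds right peak by LI at the centre pair
  # (tolerance covers the far Gaussian tail of the mirrored blob)
  co1 <- planted_cohort(1.5, g, ctr, lambda = 1)
  expect_equal(unname(co1$Y[1, lin_l] - co1$Y[1, lin_r]), 1.5,
               tolerance = 1e-6)
  expect_equal(unname(co1$Y[1, lin_r]), 2.0, tolerance = 1e-6)

  # lambda = 0: left stays at base, right reduced by LI
  co2 <- planted_cohort(1.5, g, ctr, lambda = 0)
  expect_equal(unname(co2$Y[1, lin_l]), 2.0, tolerance = 1e-6)
  expect_equal(unname(co2$Y[1, lin_r]), 2.0 - 1.5, tolerance = 1e-6)
})

test_that("smoothing preserves mirror symmetry and total mass", {
  g <- symmetric_grid(c(12, 10, 8))
  img <- symmetric_image(g, 4)
  sm <- smooth_gaussian(as.vector(img$values), g, 6)
  expect_equal(sm, sm[mirror_indices(g)])
  # interior blob mass is preserved by a normalized kernel
  v <- rep(0, n_voxels(g))
  v[lin_of(g, c(6L, 5L, 4L))] <- 1
  expect_equal(sum(smooth_gaussian(v, g, 3)), 1, tolerance = 1e-6)
})

test_that("rendered cohorts are reproducible and blob truncation warns", {
  g <- symmetric_grid(c(16, 12, 12))
  cfg <- cohort_config(n_subjects = 3,
                       regions = list(region_spec("r", c(-7, -1, -1), 2.5)),
                       noise_sd = 1, smooth_fwhm_mm = 4, rng_seed = 11)
  expect_identical(render_cohort(cfg, g)$Y, render_cohort(cfg, g)$Y)

  big <- cohort_config(n_subjects = 1,
                       regions = list(region_spec("r", c(-7, -1, -1), 12)),
                       noise_sd = 0, smooth_fwhm_mm = 0, rng_seed = 1)
  expect_warning(render_cohort(big, g), "truncated")
})
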