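test_that("group mean t map matches the closed-form one-sample t", {
  g <- tiny_grid()
  V <- n_voxels(g)
  L <- rbind(rep(0, V), rep(0, V), rep(0, V))
  i <- lin_of(g, c(2L, 2L, 2L))
  L[, i] <- c(1, 2, 3)
  # keep antisymmetry of the fixture
  L[, mirror_indices(g)[i]] <- -c(1, 2, 3)
  lmaps <- structure(list(grid = g, L = L, variant = "difference"),
                     class = "lat_maps")
  sm <- group_mean_laterality(lmaps)
  expect_equal(sm$statistic[i], 2 / (1 / sqrt(3)))   # mean/(sd/sqrt(n)) = 3.4641
  expect_equal(sm$statistic[i], 3.4641, tolerance = 1e-4)
  expect_equal(sm$df, 2L)
  # all-identical voxels have zero variance and are flagged missing
  L2 <- L; L2[, i] <- 5; L2[, mirror_indices(g)[i]] <- -5
  lm2 <- structure(list(grid = g, L = L2, variant = "difference"),
                   class = "lat_maps")
  sm2 <- group_mean_laterality(lm2)
  expect_true(is.na(sm2$statistic[i]))
  expect_gte(sm2$n_degenerate, 2)
  # antisymmetry of the t map
  p <- mirror_indices(g)
  ok <- !is.na(sm$statistic)
  expect_equal(sm$statistic[ok], -sm$statistic[p][ok])
})

test_that("null t-map moments match the t distribution", {
  g <- symmetric_grid(c(10, 8, 8))
  set.seed(31)
  n <- 12
  L0 <- matrix(rnorm(n * n_voxels(g)), n)
  L0 <- L0 - L0[, mirror_indices(g)]   # antisymmetric null laterality
  lmaps <- structure(list(grid = g, L = L0, variant = "difference"),
                     class = "lat_maps")
  tv <- group_mean_laterality(lmaps)$statistic
  df <- n - 1
  expect_equal(mean(tv), 0, tolerance = 0.05)
  expect_equal(var(tv), df / (df - 2), tolerance = 0.1)
})

test_that("seed regression slope and t equal lm() voxel by voxel", {
  g <- tiny_grid(c(4, 4, 2))
  set.seed(13)
  n <- 15
  Y <- matrix(rnorm(n * n_voxels(g)), n)
  s <- rnorm(n)
  cov1 <- rnorm(n)
  fit <- seed_covariance(list(Y = Y, grid = g), s, covariates = cbind(age = cov1))
  for (j in c(1, 7, 20)) {
    o <- summary(lm(Y[, j] ~ s + cov1))$coefficients
    expect_equal(fit$slope[j], o["s", "Estimate"], tolerance = 1e-10)
    expect_equal(fit$t[j], o["s", "t value"], tolerance = 1e-10)
  }
  expect_equal(fit$df, n - 3L)

  # exact linear relation: slope 2, r = 1
  Yx <- matrix(0, 4, n_voxels(g))
  Yx[, 3] <- c(2, 4, 6, 8)
  Yx[, 5] <- 1
  f2 <- seed_covariance(list(Y = Yx, grid = g), c(1, 2, 3, 4))
  expect_equal(f2$slope[3], 2)
  expect_equal(seedcov_r(f2)[3], 1, tolerance = 1e-7)
  # constant voxel: slope 0 (t degenerate, zero residual variance)
  expect_equal(f2$slope[5], 0)

  expect_error(seed_covariance(list(Y = Y, grid = g), s,
                               covariates = cbind(dup = s)),
               "collinear")
  expect_error(seed_covariance(list(Y = Y, grid = g), rep(1, n)),
               "zero variance")
})

test_that("laterality covariance equals the left-right activation split", {
  # OLS is linear in the response, so the slope map on laterality maps is
  # the difference of the hemisphere-wise slope maps on raw images
  g <- symmetric_grid(c(10, 8, 8))
  set.seed(23)
  n <- 14
  x <- list(Y = matrix(rnorm(n * n_voxels(g)), n), grid = g)
  s <- rnorm(n)
  lmaps <- cohort_laterality(x)
  f_lat <- seed_covariance(lmaps, s)
  f_l <- seed_covariance(x, s, hemisphere = "left")
  f_r <- seed_covariance(x, s, hemisphere = "right")
  lab <- as.vector(hemisphere_mask(g))
  left <- which(lab == 1L)
  p <- mirror_indices(g)
  expect_equal(f_lat$slope[left], f_l$slope[left] - f_r$slope[p][left],
               tolerance = 1e-10)
})

test_that("t to z conversion matches tail probabilities", {
  t <- c(-8, -2.5, -0.3, 0, 0.3, 2.5, 8, 40)
  z <- t_to_z(t, 11)
  expect_equal(pnorm(abs(z), lower.tail = FALSE),
               pt(abs(t), 11, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(sign(z), sign(t))
  expect_true(all(diff(z) > 0))   # monotone
})

test_that("dependent correlation z matches an independently coded oracle", {
  # oracle coded directly from the published formula, separate from the
  # package implementation
  oracle <- function(r1, r2, r12, n) {
    fz <- function(r) 0.5 * log((1 + r) / (1 - r))
    rb <- (r1^2 + r2^2) / 2
    f <- (1 - r12) / (2 * (1 - rb))
    if (f > 1) f <- 1
    h <- (1 - f * rb) / (1 - rb)
    (fz(r1) - fz(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  }
  expect_equal(meng_z(0.6, 0.3, 0.4, 82), oracle(0.6, 0.3, 0.4, 82),
               tolerance = 1e-6)
  expect_equal(meng_z(-0.2, 0.55, 0.1, 40), oracle(-0.2, 0.55, 0.1, 40),
               tolerance = 1e-6)
  # identical correlations: z = 0; swapping negates
  expect_equal(meng_z(0.45, 0.45, 0.3, 82), 0)
  expect_equal(meng_z(0.6, 0.3, 0.4, 82), -meng_z(0.3, 0.6, 0.4, 82))
  expect_error(meng_z(1, 0.3, 0.2, 50), "degenerate")
})

test_that("compare_seed_correlations reads the requested voxel", {
  g <- tiny_grid()
  set.seed(41)
  n <- 30
  x <- list(Y = matrix(rnorm(n * n_voxels(g)), n), grid = g)
  sA <- rnorm(n); sB <- rnorm(n)
  mm <- voxel_to_mni(g, c(3L, 2L, 2L))
  res <- compare_seed_correlations(x, sA, sB, mm)
  v <- x$Y[, lin_of(g, c(3L, 2L, 2L))]
  expect_equal(res$r_A, cor(v, sA))
  expect_equal(res$z, meng_z(cor(v, sA), cor(v, sB), cor(sA, sB), n))
  swapped <- compare_seed_correlations(x, sB, sA, mm)
  expect_equal(swapped$z, -res$z)
})
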