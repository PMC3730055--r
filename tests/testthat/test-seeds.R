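test_that("voxels_in_sphere matches a brute-force whole-grid distance scan", {
  g <- symmetric_grid(c(14, 12, 10))
  all_idx <- arrayInd(seq_len(n_voxels(g)), g$dims)
  all_mm <- voxel_to_mni(g, all_idx)
  for (seed in list(seed_spec("a", c(-7, -1, -1), 4),
                    seed_spec("b", c(-6, 0, 2), 5.5),
                    seed_spec("c", c(3, 3, -3), 7))) {
    got <- attr(voxels_in_sphere(g, seed), "linear")
    want <- which(sqrt(rowSums(sweep(all_mm, 2, seed$center_mm)^2)) <=
                    seed$diameter_mm / 2 + 1e-9)
    expect_identical(got, as.integer(want))
  }
})

test_that("sphere membership is monotone in diameter and can be empty", {
  g <- symmetric_grid(c(14, 12, 10))
  ctr <- c(-5, -1, 1)
  sizes <- c(2, 4, 6, 8, 12)
  sets <- lapply(sizes, function(d)
    attr(voxels_in_sphere(g, seed_spec("s", ctr, d)), "linear"))
  for (k in seq_along(sets)[-1])
    expect_true(all(sets[[k - 1]] %in% sets[[k]]))
  # a sphere too small to reach any voxel centre errors helpfully
  expect_error(voxels_in_sphere(g, seed_spec("tiny", c(-6, 0, 0), 0.1)),
               "larger diameter")
})

test_that("eigenvariate reduces to the voxel series for single-voxel VOIs", {
  e <- principal_eigenvariate(matrix(c(1, 2, 3), 3, 1))
  expect_equal(cor(e, c(1, 2, 3)), 1)
  # duplicated columns do not change the summary
  M <- matrix(rnorm(30), 10, 3)
  e1 <- principal_eigenvariate(M)
  e2 <- principal_eigenvariate(M[, c(1, 1, 2, 2, 3, 3)])
  expect_equal(abs(cor(e1, e2)), 1, tolerance = 1e-10)
  expect_error(principal_eigenvariate(matrix(1, 5, 3)), "no variance")
})

test_that("eigenvariate matches an independent full-decomposition oracle", {
  set.seed(12)
  for (rep_i in 1:5) {
    M <- matrix(rnorm(82 * 7), 82, 7)
    e <- principal_eigenvariate(M)
    # oracle: full eigendecomposition of the covariance, PC1 scores
    Mc <- scale(M, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(Mc) / (nrow(M) - 1), symmetric = TRUE)
    score <- drop(Mc %*% ev$vectors[, 1])
    expect_lt(min(max(abs(e * sqrt(7) - score)),
                  max(abs(e * sqrt(7) + score))), 1e-8)
    # scaling contract: variance equals mean variance explained per voxel
    expect_equal(var(e), ev$values[1] / 7, tolerance = 1e-10)
    # sign contract: non-negative correlation with the mean series
    expect_gte(cor(e, rowMeans(M)), 0)
  }
})

test_that("eigenvariate is invariant to voxel order and y/z flips", {
  g <- symmetric_grid(c(14, 12, 10))
  set.seed(3)
  x <- list(Y = matrix(rnorm(12 * n_voxels(g)), 12), grid = g)
  seed <- seed_spec("s", c(-5, -1, 1), 6)
  s1 <- extract_seed_series(x, seed)
  expect_identical(attr(s1, "n_voxels_used"),
                   nrow(voxels_in_sphere(g, seed)))

  vox <- attr(voxels_in_sphere(g, seed), "linear")
  M <- x$Y[, vox]
  set.seed(4)
  perm <- sample(ncol(M))
  expect_equal(principal_eigenvariate(M[, perm]),
               principal_eigenvariate(M), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("mirrored extraction reads the homologous sphere", {
  g <- symmetric_grid(c(14, 12, 10))
  set.seed(5)
  x <- list(Y = matrix(rnorm(8 * n_voxels(g)), 8), grid = g)
  seed <- seed_spec("s", c(-5, -1, 1), 4)
  sm <- extract_seed_series(x, seed, method = "mean",
                            hemisphere = "mirrored")
  vox <- attr(voxels_in_sphere(g, seed_spec("m", c(5, -1, 1), 4)), "linear")
  expect_equal(as.numeric(sm), rowMeans(x$Y[, vox, drop = FALSE]))
})
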