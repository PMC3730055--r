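make_signed <- function(S, grid) {
  structure(list(grid = grid, S = S, n_ties = rowSums(S == 0, na.rm = TRUE)),
            class = "signed_maps")
}

test_that("CL matches exhaustive enumeration on a 5-subject cohort", {
  g <- tiny_grid(c(4, 4, 2))
  V <- n_voxels(g)
  p <- mirror_indices(g)
  seed_sign <- c(1L, 1L, -1L, 1L, -1L)
  vox_sign <- c(1L, -1L, -1L, 1L, 1L)
  i <- lin_of(g, c(2L, 2L, 1L))
  S <- matrix(0L, 5, V)
  S[, i] <- vox_sign
  S[, p[i]] <- -vox_sign
  cl <- colat_map(make_signed(S, g), seed_sign, "seedX")
  # subjects 1, 3, 4 match: 3/5
  expect_equal(cl$cl[i], 3 / 5)
  expect_equal(cl$n_effective[i], 5)
  # homologue complementarity at the constructed pair
  expect_equal(cl$cl[i] + cl$cl[p[i]], 1)
  # the summary reads the same voxel
  tab <- colat_summary(cl, list(probe = voxel_to_mni(g, c(2L, 2L, 1L))))
  expect_equal(tab$CL[tab$region == "probe"], 0.6)
})

test_that("perfect concordance and its homologue bracket the CL range", {
  g <- tiny_grid(c(4, 4, 2))
  p <- mirror_indices(g)
  i <- lin_of(g, c(1L, 3L, 2L))
  S <- matrix(0L, 4, n_voxels(g))
  S[, i] <- 1L
  S[, p[i]] <- -1L
  cl <- colat_map(make_signed(S, g), rep(1L, 4))
  expect_equal(cl$cl[i], 1.0)
  expect_equal(cl$cl[p[i]], 0.0)
  # voxels with no non-tied subject are missing, not zero
  j <- lin_of(g, c(2L, 1L, 1L))
  expect_true(is.na(cl$cl[j]))
  expect_equal(cl$n_effective[j], 0)
})

test_that("homologue complementarity holds map-wide for tie-free cohorts", {
  g <- tiny_grid()
  set.seed(61)
  x <- list(Y = matrix(rnorm(9 * n_voxels(g)), 9), grid = g)
  lmaps <- cohort_laterality(x)
  sm <- cohort_signs(lmaps)
  seed <- seed_spec("s", c(-3, -1, -1), 4.5)
  cl <- colat_map(sm, seed_signs(lmaps, seed))
  p <- mirror_indices(g)
  ok <- cl$n_effective > 0
  expect_equal(cl$cl[ok] + cl$cl[p][ok], rep(1, sum(ok)))
  expect_true(all(cl$cl >= 0 & cl$cl <= 1, na.rm = TRUE))
  expect_true(all(cl$n_effective <= 9))
})

test_that("ties are excluded from numerator and denominator", {
  g <- tiny_grid(c(4, 4, 2))
  p <- mirror_indices(g)
  i <- lin_of(g, c(2L, 3L, 1L))
  S <- matrix(0L, 4, n_voxels(g))
  S[, i] <- c(1L, 0L, -1L, 1L)
  S[, p[i]] <- -S[, i]
  seed_sign <- c(1L, 1L, 1L, 0L)
  cl <- colat_map(make_signed(S, g), seed_sign)
  # contributing subjects: 1 (match) and 3 (mismatch) -> 1/2
  expect_equal(cl$cl[i], 0.5)
  expect_equal(cl$n_effective[i], 2)
})

test_that("seed signs use the uncentred summary and rescale invariantly", {
  g <- symmetric_grid(c(16, 12, 12))
  ctr <- c(-7, -1, -1)
  li <- c(0.8, -0.5, 1.2, 0.3, -0.1)
  co <- planted_cohort(li, g, ctr, lambda = 1)
  lmaps <- cohort_laterality(co)
  seed <- seed_spec("r1", ctr, 4)
  s_eig <- seed_signs(lmaps, seed)
  s_mean <- seed_signs(lmaps, seed, method = "mean")
  expect_identical(as.integer(s_eig), as.integer(sign(li)))
  expect_identical(as.integer(s_mean), as.integer(sign(li)))
  # positive rescaling of all maps leaves signs unchanged
  sc <- co; sc$Y <- co$Y * 3.7
  expect_identical(as.integer(seed_signs(cohort_laterality(sc), seed)),
                   as.integer(s_eig))
  # a fully symmetric subject is a tie
  co0 <- planted_cohort(c(0, 0), g, ctr)
  expect_identical(as.integer(seed_signs(cohort_laterality(co0), seed)),
                   c(0L, 0L))
})

test_that("summary flags out-of-grid peaks and finds the map maximum", {
  g <- tiny_grid(c(4, 4, 2))
  S <- matrix(1L, 3, n_voxels(g))
  S[, mirror_indices(g)[lin_of(g, c(1L, 1L, 1L))]] <- 1L
  cl <- colat_map(make_signed(S, g), c(1L, 1L, 1L))
  expect_error(colat_summary(cl, list(far = c(500, 0, 0))), "outside")
  tab <- colat_summary(cl, list(a = voxel_to_mni(g, c(1L, 2L, 1L))))
  expect_equal(tab$CL[1], 1)
  expect_equal(tab$region[nrow(tab)], "map maximum")
})

test_that("subject-count mismatch is rejected", {
  g <- tiny_grid(c(4, 4, 2))
  S <- matrix(1L, 3, n_voxels(g))
  expect_error(colat_map(make_signed(S, g), c(1L, 1L)), "mismatch")
})
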