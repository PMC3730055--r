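#' Meng-Rosenthal-Rubin z for two dependent overlapping correlations
#'
#' Tests whether a common variable (here a voxel series) correlates more
#' strongly with one seed than with another, accounting for the
#' correlation between the two seeds. Positive z means the first
#' correlation is larger.
#'
#' The statistic is
#' `z = (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))` with
#' `z1, z2` the Fisher transforms of `r1, r2`,
#' `rbar2 = (r1^2 + r2^2) / 2`, `f = min(1, (1 - r12) / (2 * (1 - rbar2)))`
#' and `h = (1 - f * rbar2) / (1 - rbar2)`.
#'
#' @param r1 correlation of the shared variable with seed A.
#' @param r2 correlation of the shared variable with seed B.
#' @param r12 correlation between the two seeds.
#' @param n number of subjects.
#' @return signed z statistic.
#' @export
meng_z <- function(r1, r2, r12, n) {
  stopifnot(n > 3)
  if (any(abs(c(r1, r2)) >= 1))
    stop("degenerate correlation |r| = 1: Fisher transform undefined")
  if (abs(r12) >= 1)
    stop("degenerate seed correlation |r12| = 1")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
}

#' Compare the correlations of a voxel with two seed series
#'
#' At a given voxel (MNI mm), computes the across-subject correlation of
#' the voxel's map values with each of two seed series and returns the
#' [meng_z()] statistic for the difference (positive when seed A's
#' correlation is larger).
#'
#' @param x a `lat_maps` or `lat_cohort`.
#' @param seedA,seedB per-subject numeric series over the same subjects.
#' @param voxel_mm MNI coordinate of the voxel to test.
#' @return list with `z`, `r_A`, `r_B`, `r_AB`, `n`, `voxel_mm`.
#' @export
compare_seed_correlations <- function(x, seedA, seedB, voxel_mm) {
  M <- if (!is.null(x$L)) x$L else x$Y
  stopifnot(is.matrix(M), length(seedA) == nrow(M),
            length(seedB) == nrow(M))
  idx <- mni_to_voxel(x$grid, voxel_mm)
  lin <- idx[1] + (idx[2] - 1L) * x$grid$dims[1] +
    (idx[3] - 1L) * prod(x$grid$dims[1:2])
  v <- M[, lin]
  if (any(is.na(v))) stop("voxel has missing values")
  rA <- stats::cor(v, as.numeric(seedA))
  rB <- stats::cor(v, as.numeric(seedB))
  rAB <- stats::cor(as.numeric(seedA), as.numeric(seedB))
  list(z = meng_z(rA, rB, rAB, nrow(M)),
       r_A = rA, r_B = rB, r_AB = rAB, n = nrow(M), voxel_mm = voxel_mm)
}
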