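#' Gaussian spatial smoothing on a symmetric grid
#'
#' Separable Gaussian convolution with zero padding at the volume edges
#' (the convention of standard fMRI packages). Because the kernel is
#' symmetric and the grid is mirror-symmetric, smoothing commutes with the
#' homologue map: smoothing a mirror-symmetric volume yields a
#' mirror-symmetric volume.
#'
#' @param x numeric 3D array, vector of length `n_voxels(grid)`, or an
#'   n x V matrix of row-vectorized volumes (all rows smoothed).
#' @param grid a [symmetric_grid()].
#' @param fwhm_mm full width at half maximum in mm (scalar, isotropic, or
#'   length-3). `0` is a no-op.
#' @return object of the same shape as `x`.
#' @export
smooth_gaussian <- function(x, grid, fwhm_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  if (all(fwhm_mm <= 0)) return(x)
  K <- .smoothing_kernels(grid, fwhm_mm)
  if (is.matrix(x) && !(length(dim(x)) == 3)) {
    out <- x
    for (i in seq_len(nrow(x)))
      out[i, ] <- as.vector(.smooth_vol(array(x[i, ], grid$dims), K))
    return(out)
  }
  vec <- is.null(dim(x))
  v <- .smooth_vol(array(as.numeric(x), grid$dims), K)
  if (vec) as.vector(v) else v
}

# per-axis dense convolution matrices (zero-padded, kernel sums to 1)
.smoothing_kernels <- function(grid, fwhm_mm) {
  lapply(1:3, function(ax) {
    sigma_vox <- fwhm_mm[ax] / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm[ax]
    if (sigma_vox <= 0) return(NULL)
    r <- max(1L, ceiling(4 * sigma_vox))
    w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
    w <- w / sum(w)
    n <- grid$dims[ax]
    G <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      i <- seq_len(n)
      k <- i + j
      ok <- k >= 1 & k <= n
      G[cbind(i[ok], k[ok])] <- G[cbind(i[ok], k[ok])] + w[j + r + 1]
    }
    G
  })
}

.smooth_vol <- function(vol, K) {
  d <- dim(vol)
  if (!is.null(K[[1]]))
    vol <- array(K[[1]] %*% matrix(vol, d[1], d[2] * d[3]), d)
  if (!is.null(K[[2]])) {
    v <- aperm(vol, c(2, 1, 3))
    v <- array(K[[2]] %*% matrix(v, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    vol <- aperm(v, c(2, 1, 3))
  }
  if (!is.null(K[[3]]))
    vol <- array(matrix(vol, d[1] * d[2], d[3]) %*% t(K[[3]]), d)
  vol
}
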