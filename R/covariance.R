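#' Convert t statistics to signed standard-normal deviates
#'
#' Maps each t to the z with the same (one-tailed) tail probability,
#' preserving sign; computed on the log scale so extreme statistics do not
#' underflow.
#'
#' @param t numeric vector of t statistics.
#' @param df degrees of freedom.
#' @return numeric vector of z-equivalents.
#' @export
t_to_z <- function(t, df) {
  z <- rep(NA_real_, length(t))
  ok <- !is.na(t)
  lp <- stats::pt(abs(t[ok]), df, lower.tail = FALSE, log.p = TRUE)
  z[ok] <- sign(t[ok]) * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  z
}

#' Group mean laterality map (one-sample t)
#'
#' Tests, at each voxel, whether the across-subject mean laterality differs
#' from zero: `t = mean / (sd / sqrt(n))`. The map is antisymmetric across
#' hemispheres because every subject map is. Voxels with zero variance (or
#' any missing subject) carry a missing statistic and are counted.
#'
#' @param lmaps a `lat_maps` object (>= 3 subjects).
#' @return object of class `stat_map`: list with `grid`, `statistic` (t),
#'   `z`, `effect` (mean), `df`, `n_subjects`, `contrast_label`,
#'   `n_degenerate`.
#' @export
group_mean_laterality <- function(lmaps) {
  stopifnot(inherits(lmaps, "lat_maps"))
  L <- lmaps$L
  n <- nrow(L)
  if (n < 3) stop("need at least 3 subjects for a group t-map")
  m <- colMeans(L)
  s2 <- (colSums(L^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  se <- sqrt(s2 / n)
  t <- m / se
  t[!is.finite(t)] <- NA_real_
  n_degen <- sum(is.na(t) & !is.na(m)) + sum(is.na(m))
  structure(list(grid = lmaps$grid, statistic = t,
                 z = t_to_z(t, n - 1), effect = m, df = n - 1L,
                 n_subjects = n, contrast_label = "group mean laterality",
                 n_degenerate = n_degen),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Statistic map:", x$contrast_label, "\n")
  cat("  n =", x$n_subjects, " df =", x$df, "\n")
  cat("  max |z| =", format(max(abs(x$z), na.rm = TRUE), digits = 4),
      " degenerate voxels:", x$n_degenerate, "\n")
  invisible(x)
}

.design_matrix <- function(s, n, covariates) {
  X <- cbind(intercept = 1, seed = as.numeric(s))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  if (nrow(X) != n)
    stop("seed series length (", nrow(X), ") does not match number of maps (",
         n, ")")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear design: column(s) ", paste(drop, collapse = ", "),
         " are linearly dependent on the others")
  }
  X
}

#' Across-subject covariance of maps with a seed series
#'
#' The central fit of the package: a mass-univariate ordinary least squares
#' regression, at every voxel, of the subject map values on
#' `[intercept, seed, covariates]`, returning the slope and t/z maps for
#' the seed regressor. Run it on laterality maps to find where laterality
#' covaries with seed laterality; run it on raw contrast images restricted
#' to one hemisphere (see `hemisphere`) to decompose a laterality
#' correlation into its left-increase and right-decrease components.
#'
#' @param x a `lat_maps` or `lat_cohort` (or list with matrix `L` or `Y`
#'   and `grid`).
#' @param seed_series per-subject numeric vector (e.g. from
#'   [extract_seed_series()]); must have nonzero variance.
#' @param covariates optional numeric matrix of nuisance regressors.
#' @param hemisphere `"both"` (default), `"left"` or `"right"`: restricts
#'   the fitted voxels to one hemisphere (midline voxels are excluded from
#'   either hemisphere).
#' @return An object of class `seedcov`: per-voxel `slope`, `t`, `z`
#'   (vectors of length `n_voxels(grid)`, `NA` outside the fitted set),
#'   `df`, `n_subjects`, `seed_name`, plus the design and response needed
#'   by [fwe_threshold()] and `residuals()`.
#' @seealso [fwe_threshold()], [compare_seed_correlations()],
#'   [make_peak_table()]
#' @examples
#' g <- symmetric_grid(c(8, 8, 8), c(2, 2, 2))
#' cfg <- cohort_config(n_subjects = 12,
#'                      regions = list(region_spec("r1", c(-1, -1, 1), 2)),
#'                      smooth_fwhm_mm = 0, rng_seed = 7)
#' co <- render_cohort(cfg, g)
#' lm_ <- cohort_laterality(co)
#' s <- extract_seed_series(lm_, seed_spec("r1", c(-1, -1, 1), 4))
#' fit <- seed_covariance(lm_, s)
#' fit
#' @export
seed_covariance <- function(x, seed_series, covariates = NULL,
                            hemisphere = c("both", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  M <- if (!is.null(x$L)) x$L else x$Y
  stopifnot(is.matrix(M), inherits(x$grid, "symmetric_grid"))
  n <- nrow(M)
  s <- as.numeric(seed_series)
  if (stats::var(s) == 0) stop("seed series has zero variance")
  X <- .design_matrix(s, n, covariates)
  p <- ncol(X)
  if (n <= p) stop("need more subjects than regressors")

  V <- ncol(M)
  fit_cols <- which(colSums(is.na(M)) == 0)
  if (hemisphere != "both") {
    lab <- as.vector(hemisphere_mask(x$grid))
    want <- if (hemisphere == "left") 1L else 2L
    fit_cols <- intersect(fit_cols, which(lab == want))
  }
  Ym <- M[, fit_cols, drop = FALSE]

  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Ym)
  res <- Ym - X %*% B
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * XtXi[2, 2])
  tt <- ifelse(se > 0, B[2, ] / se, NA_real_)

  slope <- t_ <- rep(NA_real_, V)
  slope[fit_cols] <- B[2, ]
  t_[fit_cols] <- tt
  structure(list(grid = x$grid, slope = slope, t = t_,
                 z = t_to_z(t_, n - p), df = n - p, n_subjects = n,
                 seed_name = attr(seed_series, "seed_name") %||% "seed",
                 hemisphere = hemisphere,
                 n_degenerate = sum(is.na(tt)),
                 fit_cols = fit_cols, X = X, Y = Ym,
                 source = if (!is.null(x$L)) "laterality" else "activation"),
            class = "seedcov")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.seedcov <- function(x, ...) {
  cat("Seed covariance fit: maps ~ intercept + ", x$seed_name,
      if (ncol(x$X) > 2) paste0(" + ", ncol(x$X) - 2, " covariate(s)"),
      "\n", sep = "")
  cat("  source: ", x$source, " maps, hemisphere = ", x$hemisphere,
      "\n", sep = "")
  cat("  n = ", x$n_subjects, ", df = ", x$df, ", voxels fitted = ",
      length(x$fit_cols), "\n", sep = "")
  cat("  max |z| = ", format(max(abs(x$z), na.rm = TRUE), digits = 4),
      " at MNI [",
      paste(voxel_to_mni(x$grid,
                         arrayInd(which.max(abs(x$z)), x$grid$dims)[1, ]),
            collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' @export
summary.seedcov <- function(object, ...) {
  z <- object$z[object$fit_cols]
  out <- list(seed_name = object$seed_name, n = object$n_subjects,
              df = object$df, n_voxels = length(object$fit_cols),
              n_degenerate = object$n_degenerate,
              z_quantiles = stats::quantile(z, c(0, .25, .5, .75, 1),
                                            na.rm = TRUE))
  class(out) <- "summary.seedcov"
  out
}

#' @export
print.summary.seedcov <- function(x, ...) {
  cat("Seed covariance summary ('", x$seed_name, "')\n", sep = "")
  cat("  n =", x$n, " df =", x$df, " voxels =", x$n_voxels,
      " degenerate =", x$n_degenerate, "\n")
  cat("  z quantiles:\n")
  print(x$z_quantiles)
  invisible(x)
}

#' @export
coef.seedcov <- function(object, ...) object$slope

#' @export
residuals.seedcov <- function(object, ...) {
  B <- chol2inv(chol(crossprod(object$X))) %*%
    crossprod(object$X, object$Y)
  object$Y - object$X %*% B
}

#' @export
predict.seedcov <- function(object, seed_values = NULL, ...) {
  X <- object$X
  if (!is.null(seed_values)) {
    if (ncol(X) > 2)
      stop("predict with new seed values requires a covariate-free fit")
    X <- cbind(1, as.numeric(seed_values))
  }
  B <- chol2inv(chol(crossprod(object$X))) %*%
    crossprod(object$X, object$Y)
  X %*% B
}

#' @export
plot.seedcov <- function(x, slice = NULL, ...) {
  za <- array(x$z, x$grid$dims)
  if (is.null(slice)) {
    peak <- arrayInd(which.max(abs(x$z)), x$grid$dims)
    slice <- peak[1, 3]
  }
  graphics::image(za[, , slice], main = paste0("|z|, axial slice ", slice,
                                               " ('", x$seed_name, "')"),
                  xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Extract the per-voxel correlation between maps and seed
#'
#' For a covariate-free fit this is the plain Pearson correlation between
#' the seed series and each voxel's values; with covariates it is the
#' partial correlation given the nuisance regressors.
#'
#' @param fit a `seedcov` object.
#' @return numeric vector, length `n_voxels(grid)`.
#' @export
seedcov_r <- function(fit) {
  t <- fit$t
  r <- t / sqrt(t^2 + fit$df)
  r
}
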