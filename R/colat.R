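#' Per-subject lateralization sign of a seed region
#'
#' The direction (+1 left, -1 right, 0 tie) each subject lateralizes at a
#' seed, taken as the sign of the seed's extracted laterality value: the
#' principal eigenvariate by default, or the sphere mean (the two can
#' differ; both are offered because either scalar can legitimately be
#' signed).
#'
#' Unlike the covariance workflow, where the eigenvariate is computed on
#' the column-centred VOI matrix (only across-subject variation matters),
#' the dominance sign must retain each subject's absolute laterality
#' level: here the first singular vector of the *uncentred* subject x
#' voxel matrix is used, sign-aligned so that its loadings sum positive.
#' For a lateralized seed this reduces to (approximately) the subject's
#' signed laterality amplitude; a centred eigenvariate would only code
#' deviation from the cohort mean and carries no dominance information.
#'
#' @param lmaps a `lat_maps` object (cohort laterality maps).
#' @param seed a [seed_spec()].
#' @param method `"eigenvariate"` (default) or `"mean"`.
#' @return integer vector in {-1, 0, 1}, one per subject, with the seed
#'   series as attribute `values`.
#' @export
seed_signs <- function(lmaps, seed, method = c("eigenvariate", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(lmaps, "lat_maps"))
  vox <- voxels_in_sphere(lmaps$grid, seed)
  M <- lmaps$L[, attr(vox, "linear"), drop = FALSE]
  if (any(is.na(M))) stop("seed '", seed$name, "': VOI overlaps missing voxels")
  v <- if (method == "mean") rowMeans(M) else .uncentered_eigenvariate(M)
  s <- as.integer(sign(as.numeric(v)))
  attr(s, "values") <- as.numeric(v)
  attr(s, "seed_name") <- seed$name
  s
}

# first singular vector of the raw (uncentred) VOI matrix, scaled by its
# singular value, loadings oriented positive
.uncentered_eigenvariate <- function(M) {
  sv <- svd(M, nu = 1, nv = 1)
  e <- sv$u[, 1] * sv$d[1] / sqrt(ncol(M))
  if (sum(sv$v[, 1]) < 0) e <- -e
  e
}

#' Voxel-wise co-lateralization proportion map
#'
#' At each voxel, the proportion of subjects whose lateralization sign
#' matches their lateralization sign at the seed:
#' `cl(v) = #\{i: sign_i(v) = seedsign_i, both nonzero\} / #\{i: both nonzero\}`.
#' Tied (exactly zero) subjects are excluded from numerator and
#' denominator; `n_effective` records the per-voxel count of contributing
#' subjects and voxels with none are missing. Because voxel signs are
#' antisymmetric across hemispheres, `cl(v) + cl(h(v)) = 1` wherever
#' subjects contribute.
#'
#' @param signed_maps a `signed_maps` object from [cohort_signs()].
#' @param seed_sign_per_subject integer vector in {-1, 0, 1}, e.g. from
#'   [seed_signs()].
#' @param seed_name label stored in the result.
#' @return object of class `colat_map`: `grid`, `cl` (per-voxel proportion,
#'   vector), `n_effective`, `seed_name`, `n_subjects`.
#' @export
colat_map <- function(signed_maps, seed_sign_per_subject,
                      seed_name = attr(seed_sign_per_subject, "seed_name")) {
  stopifnot(inherits(signed_maps, "signed_maps"))
  S <- signed_maps$S
  ss <- as.integer(seed_sign_per_subject)
  if (length(ss) != nrow(S))
    stop("subject-count mismatch: ", length(ss), " seed signs for ",
         nrow(S), " maps")
  valid <- (!is.na(S)) & (S != 0L) & (ss != 0L)
  agree <- (S * ss) > 0
  agree[!valid] <- FALSE
  n_eff <- colSums(valid)
  cl <- ifelse(n_eff > 0, colSums(agree) / n_eff, NA_real_)
  structure(list(grid = signed_maps$grid, cl = cl, n_effective = n_eff,
                 seed_name = seed_name %||% "seed", n_subjects = nrow(S)),
            class = "colat_map")
}

#' @export
print.colat_map <- function(x, ...) {
  cat("Co-lateralization map, seed '", x$seed_name, "': ",
      x$n_subjects, " subjects\n", sep = "")
  ok <- !is.na(x$cl)
  cat("  CL range ", paste(format(range(x$cl[ok]), digits = 3),
                           collapse = " .. "),
      "; max at MNI [",
      paste(voxel_to_mni(x$grid,
                         arrayInd(which.max(x$cl), x$grid$dims)[1, ]),
            collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Summarize co-lateralization at peak coordinates
#'
#' CL at each requested peak (MNI mm) plus the whole-map maximum,
#' formatted as a table with columns region, x, y, z, CL, n_effective.
#'
#' @param clmap a [colat_map()] result.
#' @param peaks_mm numeric matrix (k x 3) of MNI coordinates, or a named
#'   list of coordinates; names become region labels.
#' @return data.frame; the final row is the whole-map maximum.
#' @export
colat_summary <- function(clmap, peaks_mm) {
  if (is.list(peaks_mm)) {
    labs <- names(peaks_mm) %||% paste0("peak", seq_along(peaks_mm))
    peaks_mm <- do.call(rbind, peaks_mm)
  } else {
    if (is.null(dim(peaks_mm))) peaks_mm <- matrix(peaks_mm, nrow = 1)
    labs <- rownames(peaks_mm) %||% paste0("peak", seq_len(nrow(peaks_mm)))
  }
  dims <- clmap$grid$dims
  idx <- mni_to_voxel(clmap$grid, peaks_mm)  # errors listing out-of-grid peaks
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] + (idx[, 3] - 1L) * prod(dims[1:2])
  rows <- data.frame(region = labs,
                     x = peaks_mm[, 1], y = peaks_mm[, 2], z = peaks_mm[, 3],
                     CL = clmap$cl[lin], n_effective = clmap$n_effective[lin],
                     stringsAsFactors = FALSE)
  imax <- which.max(clmap$cl)
  mm <- voxel_to_mni(clmap$grid, arrayInd(imax, dims)[1, ])
  rbind(rows, data.frame(region = "map maximum",
                         x = mm[1], y = mm[2], z = mm[3],
                         CL = clmap$cl[imax],
                         n_effective = clmap$n_effective[imax]))
}
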