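#' Define a spherical seed volume of interest
#'
#' @param name seed label.
#' @param center_mm MNI coordinate of the sphere centre.
#' @param diameter_mm sphere diameter in mm (default 4, i.e. radius 2;
#'   boundary inclusive). At 2 mm voxels this selects 1-7 voxels depending
#'   on how the centre aligns with voxel centres, so the number of voxels
#'   used is always reported alongside extracted values.
#' @return list of class `seed_spec`.
#' @export
seed_spec <- function(name, center_mm, diameter_mm = 4) {
  stopifnot(length(center_mm) == 3, diameter_mm > 0)
  structure(list(name = as.character(name),
                 center_mm = as.numeric(center_mm),
                 diameter_mm = as.numeric(diameter_mm)),
            class = "seed_spec")
}

#' Default ventral occipito-temporal seed set
#'
#' The three vOT subdivisions conventionally used to seed laterality
#' covariance analyses of word processing: posterior (pvOT) at MNI
#' `[-42, -70, -10]`, middle (mvOT) at `[-44, -54, -16]` and anterior
#' (avOT) at `[-44, -44, -16]`, each a 4 mm diameter sphere.
#'
#' @param diameter_mm sphere diameter, default 4 mm.
#' @return named list of [seed_spec()] objects.
#' @export
vot_seeds <- function(diameter_mm = 4) {
  list(
    pvOT = seed_spec("pvOT", c(-42, -70, -10), diameter_mm),
    mvOT = seed_spec("mvOT", c(-44, -54, -16), diameter_mm),
    avOT = seed_spec("avOT", c(-44, -44, -16), diameter_mm)
  )
}

#' Voxels inside a spherical VOI
#'
#' All voxels whose centres lie at Euclidean distance `<= diameter/2` from
#' the seed centre, in deterministic lexicographic index order. Candidates
#' are taken from the bounding box of the sphere and filtered by exact
#' distance.
#'
#' @param grid a [symmetric_grid()].
#' @param seed a [seed_spec()].
#' @return integer matrix (k x 3) of voxel indices, with attribute
#'   `linear` giving the column-major linear indices.
#' @export
voxels_in_sphere <- function(grid, seed) {
  stopifnot(inherits(seed, "seed_spec"))
  r <- seed$diameter_mm / 2
  ctr <- seed$center_mm
  ax <- vector("list", 3)
  for (a in 1:3) {
    mm <- grid$affine[a, a] * seq_len(grid$dims[a]) + grid$affine[a, 4]
    ax[[a]] <- which(abs(mm - ctr[a]) <= r + 1e-9)
    if (length(ax[[a]]) == 0)
      stop("seed '", seed$name, "': no voxel centre within ", r,
           " mm of the centre along axis ", a,
           "; use a larger diameter_mm")
  }
  cand <- as.matrix(expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  mm <- voxel_to_mni(grid, cand)
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1)
  d2 <- rowSums(sweep(mm, 2, ctr)^2)
  keep <- d2 <= r^2 + 1e-9
  if (!any(keep))
    stop("seed '", seed$name, "': sphere of diameter ", seed$diameter_mm,
         " mm contains no voxel centre; use a larger diameter_mm")
  idx <- cand[keep, , drop = FALSE]
  lin <- idx[, 1] + (idx[, 2] - 1L) * grid$dims[1] +
    (idx[, 3] - 1L) * prod(grid$dims[1:2])
  ord <- order(lin)   # ascending linear (column-major) order
  idx <- idx[ord, , drop = FALSE]
  storage.mode(idx) <- "integer"
  attr(idx, "linear") <- as.integer(lin[ord])
  idx
}

#' Principal eigenvariate of a subject x voxel matrix
#'
#' The standard single-number-per-subject summary of a VOI: the first left
#' singular vector of the column-centred subject x voxel matrix, scaled so
#' that its sample variance equals the mean variance explained per voxel,
#' and sign-aligned so that its correlation with the across-voxel mean
#' series is non-negative. With a single voxel it reduces (up to centring)
#' to that voxel's series.
#'
#' @param data numeric matrix, subjects in rows, voxels in columns; at
#'   least 2 subjects, all values finite.
#' @return numeric vector, one value per subject, with attribute
#'   `var_explained` (fraction of VOI variance carried by the first
#'   component).
#' @export
principal_eigenvariate <- function(data) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= 2, ncol(data) >= 1)
  if (any(!is.finite(data)))
    stop("VOI data contain non-finite values")
  Mc <- sweep(data, 2, colMeans(data))
  if (max(abs(Mc)) == 0)
    stop("no variance in VOI: all subject series are constant")
  sv <- svd(Mc, nu = 1, nv = 1)
  e <- sv$u[, 1] * sv$d[1] / sqrt(ncol(data))
  ref <- rowMeans(Mc)
  al <- sum(e * ref)
  if (al < 0 || (al == 0 && sum(sv$v[, 1]) < 0)) e <- -e
  attr(e, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  e
}

#' Extract a per-subject seed series from maps or images
#'
#' Extracts, for each subject, a scalar summary of the values inside a
#' spherical VOI: the principal eigenvariate (default) or the sphere mean.
#' Run it on laterality maps for laterality series, or on raw contrast
#' images at the seed (and at the mirrored coordinate) for the
#' hemisphere-specific activation series used by hemisphere-wise
#' covariance decompositions.
#'
#' @param x a `lat_maps`, `lat_cohort`, or list with matrix `Y` or `L` and
#'   `grid`.
#' @param seed a [seed_spec()].
#' @param method `"eigenvariate"` (default) or `"mean"`.
#' @param hemisphere `"as_given"` (default) extracts at the seed centre;
#'   `"mirrored"` extracts at the left-right mirrored centre.
#' @return object of class `seed_series`: numeric per-subject vector with
#'   attributes `seed_name`, `n_voxels_used`, `method`, `source`.
#' @export
extract_seed_series <- function(x, seed,
                                method = c("eigenvariate", "mean"),
                                hemisphere = c("as_given", "mirrored")) {
  method <- match.arg(method)
  hemisphere <- match.arg(hemisphere)
  M <- if (!is.null(x$L)) x$L else x$Y
  stopifnot(is.matrix(M), inherits(x$grid, "symmetric_grid"))
  sp <- seed
  if (hemisphere == "mirrored")
    sp <- seed_spec(paste0(seed$name, "_mirror"),
                    seed$center_mm * c(-1, 1, 1), seed$diameter_mm)
  vox <- voxels_in_sphere(x$grid, sp)
  sub <- M[, attr(vox, "linear"), drop = FALSE]
  if (any(is.na(sub)))
    stop("seed '", sp$name, "': VOI overlaps missing voxels")
  vals <- if (method == "eigenvariate") principal_eigenvariate(sub)
          else rowMeans(sub)
  structure(as.numeric(vals),
            seed_name = sp$name, n_voxels_used = nrow(vox), method = method,
            source = if (!is.null(x$L)) "laterality" else "activation",
            class = "seed_series")
}

#' @export
print.seed_series <- function(x, ...) {
  cat("Seed series '", attr(x, "seed_name"), "' (", attr(x, "method"),
      ", ", attr(x, "source"), "): ", length(x), " subjects, ",
      attr(x, "n_voxels_used"), " voxels\n", sep = "")
  print(summary(as.numeric(x)))
  invisible(x)
}
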