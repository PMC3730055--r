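#' Build a left-right symmetric voxel grid
#'
#' Defines the voxel lattice on which all maps live: dimensions, voxel size,
#' and a voxel-index to MNI-mm affine. The grid must be mirror-symmetric
#' about the mid-sagittal plane `x = 0` mm so that every voxel has a unique
#' homologue at MNI `(-x, y, z)`; an optional exact `x = 0` column maps to
#' itself (midline).
#'
#' By default the origin is chosen so that voxel-centre x-coordinates come in
#' `+/-` pairs: for even `nx` the centres straddle zero, for odd `nx` the
#' middle column sits exactly on the midline.
#'
#' @param dims integer vector of length 3, voxels along x, y, z.
#' @param voxel_size_mm positive numeric vector of length 3, in mm.
#'   Default 2 mm isotropic.
#' @param origin_mm MNI-mm coordinate of the centre of voxel `(1, 1, 1)`.
#'   If `NULL`, x is centred symmetrically about 0 and y, z are centred
#'   about 0 as well.
#' @return An object of class `symmetric_grid` with fields `dims`,
#'   `voxel_size_mm`, `affine` (4x4, maps 1-based voxel index to mm), and
#'   `mirror_x` (the x-index permutation realizing the homologue map).
#' @examples
#' g <- symmetric_grid(c(4, 2, 2))
#' voxel_to_mni(g, c(1, 1, 1))
#' @export
symmetric_grid <- function(dims, voxel_size_mm = c(2, 2, 2), origin_mm = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (is.null(origin_mm)) {
    origin_mm <- -(dims - 1) / 2 * voxel_size_mm
  }
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(origin_mm) == 3)
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(voxel_size_mm, 3)
  # affine maps 1-based indices: mm = origin + (idx - 1) * size
  affine[1:3, 4] <- origin_mm - voxel_size_mm
  g <- structure(
    list(dims = dims, voxel_size_mm = voxel_size_mm, affine = affine),
    class = "symmetric_grid"
  )
  g$mirror_x <- .mirror_x_permutation(g)
  g
}

#' Reconstruct a symmetric grid from a NIfTI affine
#'
#' Accepts any affine that is axis-aligned in x (the x row/column of the
#' rotation part touches only the x axis); oblique x axes are rejected
#' because the homologue map is then not representable as an index
#' permutation.
#'
#' @param dims integer triple.
#' @param affine 4x4 matrix mapping 1-based voxel indices to MNI mm.
#' @return A `symmetric_grid`.
#' @export
grid_from_affine <- function(dims, affine) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, is.matrix(affine), all(dim(affine) == c(4, 4)))
  rot <- affine[1:3, 1:3]
  if (any(abs(rot[1, 2:3]) > 1e-6) || any(abs(rot[2:3, 1]) > 1e-6))
    stop("grid not mirror-symmetric: affine is oblique in x; ",
         "the homologue map requires an axis-aligned x axis")
  g <- structure(
    list(dims = dims,
         voxel_size_mm = sqrt(colSums(rot^2)),
         affine = affine),
    class = "symmetric_grid"
  )
  g$mirror_x <- .mirror_x_permutation(g)
  g
}

# x-index permutation j such that MNI x of voxel j equals -x of voxel i;
# errors if any column has no mirror partner.
.mirror_x_permutation <- function(grid) {
  nx <- grid$dims[1]
  i <- seq_len(nx)
  x <- grid$affine[1, 1] * i + grid$affine[1, 4]
  tol <- 1e-6
  perm <- integer(nx)
  for (k in i) {
    j <- which(abs(x + x[k]) < tol)
    if (length(j) != 1)
      stop("grid not mirror-symmetric about x = 0: voxel column at x = ",
           format(x[k]), " mm has no unique mirror partner on the x axis")
    perm[k] <- j
  }
  if (!identical(perm[perm], i))
    stop("grid not mirror-symmetric about x = 0: mirror map on the x axis ",
         "is not an involution")
  perm
}

#' @export
print.symmetric_grid <- function(x, ...) {
  cat("Symmetric voxel grid\n")
  cat("  dims      :", paste(x$dims, collapse = " x "),
      sprintf(" (%d voxels)\n", prod(x$dims)))
  cat("  voxel size:", paste(format(x$voxel_size_mm), collapse = " x "), "mm\n")
  xs <- x$affine[1, 1] * seq_len(x$dims[1]) + x$affine[1, 4]
  cat("  x centres :", format(min(xs)), "..", format(max(xs)), "mm",
      if (any(abs(xs) < 1e-6)) "(midline column present)" else "", "\n")
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a `symmetric_grid`.
#' @return integer voxel count.
#' @export
n_voxels <- function(grid) as.integer(prod(grid$dims))

#' Convert voxel indices to MNI mm coordinates
#'
#' @param grid a `symmetric_grid`.
#' @param idx integer vector of length 3, or an n x 3 matrix of 1-based
#'   voxel indices.
#' @return numeric vector or n x 3 matrix of mm coordinates.
#' @export
voxel_to_mni <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  storage.mode(idx) <- "double"
  mm <- idx %*% t(grid$affine[1:3, 1:3]) +
    rep(1, nrow(idx)) %o% grid$affine[1:3, 4]
  if (nrow(mm) == 1) drop(mm) else mm
}

#' Convert MNI mm coordinates to the nearest voxel index
#'
#' @param grid a `symmetric_grid`.
#' @param mm numeric vector of length 3 or n x 3 matrix.
#' @return integer vector or matrix of 1-based voxel indices.
#' @export
mni_to_voxel <- function(grid, mm) {
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1)
  idx <- sweep(mm, 2, grid$affine[1:3, 4]) %*% t(solve(grid$affine[1:3, 1:3]))
  idx <- round(idx)
  bad <- idx < 1 | idx > rep(1, nrow(idx)) %o% as.double(grid$dims)
  if (any(bad))
    stop("coordinate outside the grid: ",
         paste(apply(mm[rowSums(bad) > 0, , drop = FALSE], 1,
                     function(r) paste0("[", paste(r, collapse = ", "), "]")),
               collapse = ", "))
  storage.mode(idx) <- "integer"
  if (nrow(idx) == 1) drop(idx) else idx
}

#' Homologue voxel under the left-right mirror map
#'
#' Returns, for each voxel, the voxel whose MNI coordinate is `(-x, y, z)`.
#' The map is an involution and fixes midline (`x = 0`) voxels. It is
#' computed through the affine, not by flipping array indices, so
#' non-canonical (but x-axis-aligned) orientations are handled.
#'
#' @param grid a `symmetric_grid`.
#' @param voxel integer triple or n x 3 matrix of 1-based voxel indices.
#' @return index triple (or matrix) of the homologous voxel(s).
#' @examples
#' g <- symmetric_grid(c(10, 10, 10))
#' homologue(g, c(2, 5, 5))
#' @export
homologue <- function(grid, voxel) {
  single <- is.null(dim(voxel))
  if (single) voxel <- matrix(voxel, nrow = 1)
  if (any(voxel < 1) || any(sweep(voxel, 2, grid$dims) > 0))
    stop("voxel index out of bounds")
  out <- voxel
  out[, 1] <- grid$mirror_x[voxel[, 1]]
  storage.mode(out) <- "integer"
  if (single) drop(out) else out
}

#' Linear-index permutation realizing the homologue map
#'
#' Voxels are stored in column-major (x fastest) order; this returns the
#' permutation `p` such that `values[p]` transports every voxel's value to
#' its homologue.
#'
#' @param grid a `symmetric_grid`.
#' @return integer vector of length `n_voxels(grid)`.
#' @export
mirror_indices <- function(grid) {
  nx <- grid$dims[1]
  rest <- prod(grid$dims[2:3])
  as.vector(outer(grid$mirror_x, (seq_len(rest) - 1L) * nx, `+`))
}

#' Test two grids for equality
#' @param a,b `symmetric_grid` objects.
#' @param tol tolerance on affine entries, mm.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  identical(a$dims, b$dims) && all(abs(a$affine - b$affine) < tol)
}

#' Hemisphere labels for every voxel
#'
#' Labels each voxel by the sign of its MNI x coordinate using the
#' convention 1 = left (x < 0), 2 = right (x > 0), 3 = midline (x = 0),
#' 0 = outside (where `brain` is FALSE).
#'
#' @param grid a `symmetric_grid`.
#' @param brain optional logical 3D array (or vector) marking in-brain
#'   voxels; `NULL` means everything is in-brain.
#' @return An object of class `hemisphere_mask`: integer 3D array of labels
#'   with the grid attached as attribute `grid`.
#' @export
hemisphere_mask <- function(grid, brain = NULL) {
  nx <- grid$dims[1]
  x <- grid$affine[1, 1] * seq_len(nx) + grid$affine[1, 4]
  lab_x <- ifelse(abs(x) < 1e-6, 3L, ifelse(x < 0, 1L, 2L))
  labels <- array(rep(lab_x, prod(grid$dims[2:3])), dim = grid$dims)
  if (!is.null(brain)) {
    stopifnot(length(brain) == n_voxels(grid))
    labels[!brain] <- 0L
  }
  structure(labels, grid = grid, class = "hemisphere_mask")
}

#' @export
print.hemisphere_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = 0:3,
                      labels = c("outside", "left", "right", "midline")))
  cat("Hemisphere mask:",
      paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}
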