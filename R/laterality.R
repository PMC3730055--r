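#' Voxel-wise laterality map for one subject
#'
#' Codes, at each voxel, the difference in activity between that voxel and
#' its left-right homologue: `li(v) = beta(v) - beta(h(v))` (variant
#' `"difference"`, the default) or the normalized index
#' `li(v) = (beta(v) - beta(h(v))) / (|beta(v)| + |beta(h(v))| + eps)`
#' (variant `"normalized"`). The map is antisymmetric under hemisphere
#' exchange and zero on midline voxels; if either member of a voxel pair is
#' missing, both are missing in the map.
#'
#' The difference variant is the default because it is exactly the
#' task-by-hemisphere interaction of contrast estimates and is linear in
#' the input image; the normalized variant is provided for comparison and
#' is not used by downstream defaults.
#'
#' @param img a [contrast_image()].
#' @param mask optional [hemisphere_mask()]; voxels labelled outside become
#'   missing.
#' @param variant `"difference"` or `"normalized"`.
#' @param eps small positive constant guarding zero denominators in the
#'   normalized variant (default 1e-9; at `eps = 0` a `0/0` voxel is
#'   missing).
#' @return An object of class `laterality_map`: list with `grid`,
#'   `li_values` (3D array), `subject_id`, `variant`.
#' @export
compute_laterality <- function(img, mask = NULL,
                               variant = c("difference", "normalized"),
                               eps = 1e-9) {
  stopifnot(inherits(img, "contrast_image"))
  variant <- match.arg(variant)
  v <- as.vector(img$values)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(v))
    v[as.vector(mask) == 0L] <- NA_real_
  }
  li <- .laterality_values(v, img$grid, variant, eps)
  structure(list(grid = img$grid, li_values = array(li, img$grid$dims),
                 subject_id = img$subject_id, variant = variant),
            class = "laterality_map")
}

# vectorized laterality for a single vectorized volume
.laterality_values <- function(v, grid, variant, eps) {
  m <- v[mirror_indices(grid)]
  if (variant == "difference") v - m
  else (v - m) / (abs(v) + abs(m) + eps)
}

#' Laterality maps for a whole cohort
#'
#' Matrix form of [compute_laterality()]: each row of `Y` is one subject's
#' vectorized contrast image and each row of the result the corresponding
#' laterality map.
#'
#' @param x a `lat_cohort`, or a list with `Y` (n x V matrix) and `grid`.
#' @param variant,eps as in [compute_laterality()].
#' @return list of class `lat_maps`: `grid`, `L` (n x V matrix), `variant`.
#' @export
cohort_laterality <- function(x, variant = c("difference", "normalized"),
                              eps = 1e-9) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(x$Y), inherits(x$grid, "symmetric_grid"))
  M <- x$Y[, mirror_indices(x$grid), drop = FALSE]
  L <- if (variant == "difference") x$Y - M
       else (x$Y - M) / (abs(x$Y) + abs(M) + eps)
  structure(list(grid = x$grid, L = L, variant = variant),
            class = "lat_maps")
}

#' @export
print.lat_maps <- function(x, ...) {
  cat("Laterality maps (", x$variant, "): ", nrow(x$L), " subjects, ",
      ncol(x$L), " voxels\n", sep = "")
  invisible(x)
}

#' @export
print.laterality_map <- function(x, ...) {
  cat("Laterality map (", x$variant, "), subject ", x$subject_id, "\n",
      sep = "")
  cat("  range:", paste(format(range(x$li_values, na.rm = TRUE), digits = 4),
                        collapse = " .. "), "\n")
  invisible(x)
}

#' Signed (+1/-1) lateralization map
#'
#' Reduces a laterality map to its sign at each voxel: `+1` where left
#' activation exceeds the homologous right, `-1` for the opposite, `0` for
#' an exact tie (continuous data makes ties measure-zero; constructed data
#' can produce them, and they are counted).
#'
#' @param lmap a `laterality_map`.
#' @return object of class `signed_map`: list with `grid`, `signs` (3D
#'   array in {-1, 0, +1, NA}), `subject_id`, `n_ties`.
#' @export
sign_map <- function(lmap) {
  stopifnot(inherits(lmap, "laterality_map"))
  s <- sign(lmap$li_values)
  structure(list(grid = lmap$grid, signs = s, subject_id = lmap$subject_id,
                 n_ties = sum(s == 0, na.rm = TRUE)),
            class = "signed_map")
}

#' Signed lateralization maps for a cohort
#'
#' @param lmaps a `lat_maps` object.
#' @return list of class `signed_maps`: `grid`, `S` (n x V matrix in
#'   {-1, 0, 1, NA}), `n_ties` per subject.
#' @export
cohort_signs <- function(lmaps) {
  stopifnot(inherits(lmaps, "lat_maps"))
  S <- sign(lmaps$L)
  structure(list(grid = lmaps$grid, S = S,
                 n_ties = rowSums(S == 0, na.rm = TRUE)),
            class = "signed_maps")
}

#' Mirror an image across the mid-sagittal plane
#'
#' Transports every voxel's value to its homologue. An involution:
#' `flip_image(flip_image(img))` restores the original bit-exactly.
#'
#' @param img a `contrast_image`.
#' @return the flipped `contrast_image`.
#' @export
flip_image <- function(img) {
  stopifnot(inherits(img, "contrast_image"))
  v <- as.vector(img$values)[mirror_indices(img$grid)]
  contrast_image(v, img$grid, img$subject_id)
}
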