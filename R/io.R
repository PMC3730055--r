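#' Construct a contrast image on a symmetric grid
#'
#' A contrast image holds one subject's task-versus-baseline effect-size map
#' (arbitrary BOLD units). Voxels outside the analysis mask are `NA`, never
#' zero; `NA` propagates into every derived map.
#'
#' @param values numeric 3D array (or vector of length `n_voxels(grid)`).
#' @param grid a [symmetric_grid()].
#' @param subject_id identifier, stored with the image.
#' @return An object of class `contrast_image`: list with `grid`, `values`
#'   (3D array), `subject_id`.
#' @export
contrast_image <- function(values, grid, subject_id = NA_character_) {
  stopifnot(inherits(grid, "symmetric_grid"))
  if (length(values) != n_voxels(grid))
    stop("grid mismatch: image has ", length(values), " voxels, grid has ",
         n_voxels(grid))
  values <- array(as.numeric(values), dim = grid$dims)
  structure(list(grid = grid, values = values, subject_id = subject_id),
            class = "contrast_image")
}

#' @export
print.contrast_image <- function(x, ...) {
  v <- x$values
  cat("Contrast image, subject", x$subject_id, "\n")
  cat("  grid:", paste(x$grid$dims, collapse = " x "),
      "voxels;", sum(is.na(v)), "missing\n")
  cat("  range:", paste(format(range(v, na.rm = TRUE), digits = 4),
                        collapse = " .. "), "\n")
  invisible(x)
}

#' Read a 3D NIfTI volume as a contrast image
#'
#' The file must be a 3D scalar NIfTI-1 volume with a usable affine
#' (sform or qform). Non-finite voxels are loaded as missing (`NA`). If
#' `grid` is supplied the volume is checked against it and a "grid
#' mismatch" error raised on disagreement — use this when reading a cohort
#' that must share one grid.
#'
#' @param path file path (.nii or .nii.gz).
#' @param grid optional reference `symmetric_grid` to enforce.
#' @param subject_id identifier; defaults to the file name.
#' @return A `contrast_image`.
#' @export
read_volume <- function(path, grid = NULL,
                        subject_id = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3)
    stop("expected a 3D volume, got ", length(d), "D input: ", path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code == 0 && hdr$qform_code == 0)
    stop("volume has no affine (sform and qform both absent): ", path)
  xf <- RNifti::xform(img)
  aff <- diag(4)
  aff[1:3, 1:4] <- xf[1:3, 1:4]
  # NIfTI affines map 0-based indices; convert to the 1-based convention
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(1, 3)
  g <- grid_from_affine(d, aff)
  if (!is.null(grid) && !same_grid(grid, g))
    stop("grid mismatch: ", path, " has dims ",
         paste(d, collapse = "x"), " and a different geometry than the ",
         "reference grid (", paste(grid$dims, collapse = "x"), ")")
  vals <- as.array(img)
  vals[!is.finite(vals)] <- NA_real_
  contrast_image(vals, if (is.null(grid)) g else grid, subject_id)
}

#' Write a contrast image (or any per-voxel map) as NIfTI
#'
#' Missing voxels are written as NaN. The grid's affine is stored as the
#' sform (code 2, aligned to MNI).
#'
#' @param img a `contrast_image`, or a numeric array/vector with a `grid`.
#' @param path output path (.nii or .nii.gz).
#' @param grid required when `img` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path, grid = NULL) {
  if (inherits(img, "contrast_image")) {
    grid <- img$grid
    values <- img$values
  } else {
    stopifnot(inherits(grid, "symmetric_grid"))
    values <- array(as.numeric(img), dim = grid$dims)
  }
  values[is.na(values)] <- NaN
  nii <- RNifti::asNifti(values)
  aff <- grid$affine
  # back to NIfTI's 0-based convention
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(1, 3)
  nii <- RNifti::`sform<-`(nii, structure(aff, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a cohort of volumes sharing one grid
#'
#' @param paths character vector of NIfTI paths.
#' @param subject_ids identifiers, default derived from file names.
#' @return list with `grid` and `Y`, an n_subjects x n_voxels matrix
#'   (rownames = subject ids) in column-major voxel order.
#' @export
read_cohort <- function(paths,
                        subject_ids = sub("\\.nii(\\.gz)?$", "", basename(paths))) {
  stopifnot(length(paths) >= 1)
  first <- read_volume(paths[1], subject_id = subject_ids[1])
  grid <- first$grid
  Y <- matrix(NA_real_, length(paths), n_voxels(grid),
              dimnames = list(subject_ids, NULL))
  Y[1, ] <- as.vector(first$values)
  for (i in seq_along(paths)[-1])
    Y[i, ] <- as.vector(read_volume(paths[i], grid = grid,
                                    subject_id = subject_ids[i])$values)
  list(grid = grid, Y = Y)
}
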