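#' Define a lateralized activation region for simulation
#'
#' A region is a Gaussian activation blob placed at a left-hemisphere MNI
#' coordinate and, mirrored, at its right-hemisphere homologue. The
#' subject-specific laterality index (LI) of the region splits into a left
#' increase and a right decrease according to the region's
#' `left_increase_fraction` in the cohort config.
#'
#' @param name region label.
#' @param center_mm MNI coordinate of the left-hemisphere centre; `x` must
#'   be negative (left).
#' @param sigma_mm spatial scale (Gaussian sigma) of the blob, mm.
#' @param base_amplitude mean bilateral activation in contrast-image units.
#' @return list of class `region_spec`.
#' @export
region_spec <- function(name, center_mm, sigma_mm = 6, base_amplitude = 2) {
  center_mm <- as.numeric(center_mm)
  stopifnot(length(center_mm) == 3, sigma_mm > 0)
  if (center_mm[1] >= 0)
    stop("region '", name, "': center_mm must be in the left hemisphere (x < 0)")
  structure(list(name = as.character(name), center_mm = center_mm,
                 sigma_mm = as.numeric(sigma_mm),
                 base_amplitude = as.numeric(base_amplitude)),
            class = "region_spec")
}

#' Configure a synthetic lateralized cohort
#'
#' Specifies the generative model for a multi-subject cohort of contrast
#' images: per-region laterality indices drawn from a multivariate normal
#' with a given across-subject correlation structure, a handedness mixture
#' in which a minority of subjects is atypically lateralized, a split of
#' each LI into left-hemisphere increase versus right-hemisphere decrease,
#' additive white noise, and Gaussian smoothing emulating standard fMRI
#' preprocessing.
#'
#' Defaults (LI mean 1.0, sd 0.5, noise sd 1.0 in blob amplitude units,
#' 6 mm FWHM smoothing, 2 mm voxels) are package conventions chosen to
#' mimic group fMRI effect-size maps; see the package vignette.
#'
#' @param n_subjects number of subjects (default 82).
#' @param regions list of [region_spec()] objects.
#' @param laterality_mean per-region mean LI (scalar recycled).
#' @param laterality_sd per-region sd of LI (scalar recycled).
#' @param laterality_corr region x region correlation matrix of LI across
#'   subjects (default identity). Must be symmetric positive semi-definite
#'   with unit diagonal.
#' @param left_increase_fraction per-region lambda in `[0, 1]`: a subject's
#'   LI is realized as `lambda * LI` added on the left and `(1 - lambda) * LI`
#'   subtracted on the right. `1` = pure left increase, `0` = pure right
#'   decrease, default `0.5` = both.
#' @param atypical_fraction proportion of subjects with atypical (non
#'   left-dominant) lateralization; their region mean LIs are sign-flipped.
#' @param atypical_mode `"independent"` (default): each region's mean flips
#'   independently for an atypical subject, allowing crossed or
#'   effectively bilateral dominance; `"joint"`: all regions flip together
#'   (strictly mirrored dominance).
#' @param noise_sd sd of additive white voxel noise (before smoothing).
#' @param smooth_fwhm_mm Gaussian smoothing FWHM in mm (default 6).
#' @param smooth_order `"after_noise"` (default; smooths signal plus noise,
#'   as when contrast images are estimated from smoothed data),
#'   `"before_noise"`, or `"none"`.
#' @param rng_seed integer governing all randomness in the cohort.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 82,
                          regions,
                          laterality_mean = 1.0,
                          laterality_sd = 0.5,
                          laterality_corr = NULL,
                          left_increase_fraction = 0.5,
                          atypical_fraction = 0.12,
                          atypical_mode = c("independent", "joint"),
                          noise_sd = 1.0,
                          smooth_fwhm_mm = 6,
                          smooth_order = c("after_noise", "before_noise", "none"),
                          rng_seed = 1L) {
  if (inherits(regions, "region_spec")) regions <- list(regions)
  stopifnot(n_subjects >= 1, length(regions) >= 1,
            all(vapply(regions, inherits, TRUE, "region_spec")))
  R <- length(regions)
  if (is.null(laterality_corr)) laterality_corr <- diag(R)
  laterality_corr <- as.matrix(laterality_corr)
  stopifnot(all(dim(laterality_corr) == R))
  if (max(abs(laterality_corr - t(laterality_corr))) > 1e-8 ||
      max(abs(diag(laterality_corr) - 1)) > 1e-8)
    stop("laterality_corr must be symmetric with unit diagonal")
  if (min(eigen(laterality_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("laterality_corr is not positive semi-definite")
  stopifnot(atypical_fraction >= 0, atypical_fraction <= 1,
            all(left_increase_fraction >= 0), all(left_increase_fraction <= 1),
            noise_sd >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects),
    regions = regions,
    laterality_mean = rep_len(laterality_mean, R),
    laterality_sd = rep_len(laterality_sd, R),
    laterality_corr = laterality_corr,
    left_increase_fraction = rep_len(left_increase_fraction, R),
    atypical_fraction = atypical_fraction,
    atypical_mode = match.arg(atypical_mode),
    noise_sd = noise_sd,
    smooth_fwhm_mm = smooth_fwhm_mm,
    smooth_order = match.arg(smooth_order),
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_subjects, "subjects,",
      length(x$regions), "regions\n")
  cat("  regions:", paste(vapply(x$regions, `[[`, "", "name"),
                          collapse = ", "), "\n")
  cat("  LI mean", paste(format(x$laterality_mean), collapse = "/"),
      " sd", paste(format(x$laterality_sd), collapse = "/"),
      " atypical", format(x$atypical_fraction),
      paste0("(", x$atypical_mode, ")"), "\n")
  cat("  noise sd", format(x$noise_sd), " smoothing",
      format(x$smooth_fwhm_mm), "mm FWHM,", x$smooth_order, "\n")
  invisible(x)
}

#' Draw per-subject ground-truth laterality indices
#'
#' Samples each subject's region LI vector from a multivariate normal with
#' the configured means, sds and correlation matrix. Subjects flagged
#' atypical (a Bernoulli draw at `atypical_fraction`) have region means
#' sign-flipped — jointly or independently per region according to
#' `atypical_mode`. Deterministic given `rng_seed`.
#'
#' @param config a [cohort_config()].
#' @return list of class `ground_truth`: `li` (n_subjects x n_regions
#'   matrix), `handedness` (`"typical"`/`"atypical"`), `mean_sign`
#'   (n x R matrix of the applied mean signs), and `realized_corr`
#'   (sample correlation matrix of the planted LI values; `NA` for
#'   single-subject cohorts).
#' @export
sample_laterality <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  R <- length(config$regions)
  rn <- vapply(config$regions, `[[`, "", "name")
  withr_seed <- config$rng_seed
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(withr_seed)

  atyp <- stats::runif(n) < config$atypical_fraction
  mean_sign <- matrix(1, n, R)
  if (any(atyp)) {
    if (config$atypical_mode == "joint") {
      mean_sign[atyp, ] <- -1
    } else {
      mean_sign[atyp, ] <- sample(c(-1, 1), sum(atyp) * R, replace = TRUE)
    }
  }
  # PSD (possibly singular) correlation: sample through the eigen square root
  ed <- eigen(config$laterality_corr, symmetric = TRUE)
  A <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), R) %*% t(ed$vectors)
  Z <- matrix(stats::rnorm(n * R), n, R) %*% A
  li <- mean_sign * matrix(config$laterality_mean, n, R, byrow = TRUE) +
    Z * matrix(config$laterality_sd, n, R, byrow = TRUE)
  dimnames(li) <- list(NULL, rn)
  structure(list(
    li = li,
    handedness = ifelse(atyp, "atypical", "typical"),
    mean_sign = mean_sign,
    realized_corr = if (n > 2) stats::cor(li) else matrix(NA_real_, R, R)
  ), class = "ground_truth")
}

# unit-amplitude Gaussian blob (vector over the grid), centred at mm
.blob <- function(grid, center_mm, sigma_mm) {
  d <- grid$dims
  ax <- lapply(1:3, function(a)
    (grid$affine[a, a] * seq_len(d[a]) + grid$affine[a, 4] - center_mm[a])^2)
  q <- rep(ax[[1]], times = d[2] * d[3]) +
    rep(rep(ax[[2]], each = d[1]), times = d[3]) +
    rep(ax[[3]], each = d[1] * d[2])
  exp(-q / (2 * sigma_mm^2))
}

#' Render a synthetic cohort of contrast images
#'
#' For each subject and region, places a Gaussian blob of amplitude
#' `base_amplitude + lambda * LI` at the region centre and
#' `base_amplitude - (1 - lambda) * LI` at the mirrored centre, adds white
#' noise, and smooths. The planted ground truth is returned alongside the
#' images.
#'
#' @param config a [cohort_config()].
#' @param grid a [symmetric_grid()]; region centres must lie inside it.
#' @param truth optional pre-sampled [sample_laterality()] result (for
#'   reuse); defaults to sampling from `config`.
#' @return list of class `lat_cohort`: `grid`, `Y` (n_subjects x n_voxels
#'   matrix of vectorized images), `truth`, `config`.
#' @export
render_cohort <- function(config, grid, truth = sample_laterality(config)) {
  stopifnot(inherits(config, "cohort_config"), inherits(grid, "symmetric_grid"))
  n <- config$n_subjects
  V <- n_voxels(grid)
  R <- length(config$regions)
  mirror <- mirror_indices(grid)

  BL <- matrix(0, V, R)
  lo <- voxel_to_mni(grid, c(1L, 1L, 1L))
  hi <- voxel_to_mni(grid, grid$dims)
  for (r in seq_len(R)) {
    reg <- config$regions[[r]]
    mni_to_voxel(grid, reg$center_mm)  # errors if centre out of grid
    if (any(reg$center_mm - 3 * reg$sigma_mm < pmin(lo, hi)) ||
        any(reg$center_mm + 3 * reg$sigma_mm > pmax(lo, hi)))
      warning("region '", reg$name, "' blob extends outside the grid; truncated")
    BL[, r] <- .blob(grid, reg$center_mm, reg$sigma_mm)
  }
  BR <- BL[mirror, , drop = FALSE]

  base <- vapply(config$regions, `[[`, 0, "base_amplitude")
  lam <- config$left_increase_fraction
  AL <- matrix(base, n, R, byrow = TRUE) +
    truth$li * matrix(lam, n, R, byrow = TRUE)
  AR <- matrix(base, n, R, byrow = TRUE) -
    truth$li * matrix(1 - lam, n, R, byrow = TRUE)
  Y <- tcrossprod(AL, BL) + tcrossprod(AR, BR)

  if (config$smooth_order == "before_noise" && config$smooth_fwhm_mm > 0)
    Y <- smooth_gaussian(Y, grid, config$smooth_fwhm_mm)
  if (config$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    for (s in seq_len(n)) {
      # per-subject stream derived deterministically from the cohort seed
      set.seed((config$rng_seed + 104729L * s) %% .Machine$integer.max)
      Y[s, ] <- Y[s, ] + stats::rnorm(V, sd = config$noise_sd)
    }
  }
  if (config$smooth_order == "after_noise" && config$smooth_fwhm_mm > 0)
    Y <- smooth_gaussian(Y, grid, config$smooth_fwhm_mm)
  rownames(Y) <- sprintf("sub-%03d", seq_len(n))
  structure(list(grid = grid, Y = Y, truth = truth, config = config),
            class = "lat_cohort")
}

#' @export
print.lat_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$Y), "subjects on a",
      paste(x$grid$dims, collapse = "x"), "grid\n")
  cat("  atypical:", sum(x$truth$handedness == "atypical"), "subjects\n")
  invisible(x)
}

#' Extract one subject's image from a cohort
#' @param cohort a `lat_cohort`.
#' @param i subject index.
#' @return a `contrast_image`.
#' @export
cohort_image <- function(cohort, i) {
  contrast_image(cohort$Y[i, ], cohort$grid, rownames(cohort$Y)[i])
}

#' Write a cohort to disk
#'
#' Writes one NIfTI per subject, a ground-truth TSV (`subject_id`,
#' `handedness`, one LI column per region) and a JSON manifest.
#'
#' @param cohort a `lat_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(cohort$Y)
  files <- file.path(dir, paste0(ids, "_con.nii.gz"))
  for (i in seq_along(ids))
    write_volume(cohort$Y[i, ], files[i], grid = cohort$grid)
  gt <- data.frame(subject_id = ids, handedness = cohort$truth$handedness,
                   cohort$truth$li, check.names = FALSE)
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    n_subjects = cohort$config$n_subjects,
    regions = lapply(cohort$config$regions, unclass),
    rng_seed = cohort$config$rng_seed,
    files = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
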