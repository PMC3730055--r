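#' Peak table across one or more seed covariance analyses
#'
#' Reduces thresholded fits to a table of local maxima, one row per peak,
#' with one z column per seed and a significance flag per seed: `"fwe"`
#' (survives the permutation family-wise threshold), `"unc"` (exceeds the
#' uncorrected forming threshold only), or `"n.s."`. Peaks are greedy
#' local maxima separated by at least `min_peak_distance_mm` (default
#' 8 mm, a conventional reporting choice).
#'
#' @param fits list of [seed_covariance()] fits (one per seed).
#' @param reports list of matching [fwe_threshold()] reports.
#' @param min_peak_distance_mm minimum distance between reported peaks.
#' @return data.frame with columns x, y, z then, per seed, `z_<name>` and
#'   `sig_<name>`; empty (with header) when nothing is suprathreshold.
#' @export
make_peak_table <- function(fits, reports, min_peak_distance_mm = 8) {
  if (inherits(fits, "seedcov")) fits <- list(fits)
  if (inherits(reports, "fwe_report")) reports <- list(reports)
  stopifnot(length(fits) == length(reports))
  nm <- vapply(fits, `[[`, "", "seed_name")

  cand_mm <- NULL
  cand_z <- numeric(0)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    rp <- reports[[i]]
    t_form <- stats::qt(rp$voxelwise_p_uncorrected / 2, f$df,
                        lower.tail = FALSE)
    lin <- f$fit_cols[!is.na(f$t[f$fit_cols]) &
                        abs(f$t[f$fit_cols]) > t_form]
    if (length(lin) == 0) next
    mm <- voxel_to_mni(f$grid, arrayInd(lin, f$grid$dims))
    if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1)
    cand_mm <- rbind(cand_mm, mm)
    cand_z <- c(cand_z, abs(f$z[lin]))
  }
  base_cols <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))
  for (s in nm) {
    base_cols[[paste0("z_", s)]] <- numeric(0)
    base_cols[[paste0("sig_", s)]] <- character(0)
  }
  if (is.null(cand_mm)) return(base_cols)

  ord <- order(-cand_z)
  picked <- NULL
  for (i in ord) {
    p <- cand_mm[i, ]
    if (is.null(picked) ||
        all(sqrt(rowSums(sweep(picked, 2, p)^2)) >= min_peak_distance_mm))
      picked <- rbind(picked, p)
  }

  rows <- lapply(seq_len(nrow(picked)), function(k) {
    mm <- picked[k, ]
    row <- data.frame(x = mm[1], y = mm[2], z = mm[3])
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      rp <- reports[[i]]
      idx <- mni_to_voxel(f$grid, mm)
      lin <- idx[1] + (idx[2] - 1L) * f$grid$dims[1] +
        (idx[3] - 1L) * prod(f$grid$dims[1:2])
      zv <- f$z[lin]
      t_form <- stats::qt(rp$voxelwise_p_uncorrected / 2, f$df,
                          lower.tail = FALSE)
      flag <- if (lin %in% rp$significant_voxels) "fwe"
              else if (!is.na(f$t[lin]) && abs(f$t[lin]) > t_form) "unc"
              else "n.s."
      row[[paste0("z_", nm[i])]] <- zv
      row[[paste0("sig_", nm[i])]] <- flag
    }
    row
  })
  do.call(rbind, rows)
}

.as_regions <- function(x) {
  lapply(x, function(r)
    region_spec(r$name, unlist(r$center_mm),
                r$sigma_mm %||% 6, r$base_amplitude %||% 2))
}

.as_seeds <- function(x) {
  lapply(x, function(s)
    seed_spec(s$name, unlist(s$center_mm), s$diameter_mm %||% 4))
}

#' Run the full laterality covariance pipeline
#'
#' Executes simulate (or load) -> laterality maps -> seed extraction ->
#' seed covariance with permutation FWE -> co-lateralization, writing all
#' outputs (NIfTI maps, TSV tables, JSON reports) and a run manifest with
#' seeds and file hashes. Re-running with the same config reproduces every
#' numeric output exactly.
#'
#' @param config a list, or path to a YAML/JSON file, with elements:
#'   \describe{
#'     \item{out_dir}{output directory.}
#'     \item{grid}{list with `dims` and optional `voxel_size_mm`.}
#'     \item{cohort}{arguments for [cohort_config()], with `regions` a list
#'       of lists (`name`, `center_mm`, `sigma_mm`, `base_amplitude`);
#'       alternatively `cohort_dir` naming a directory of NIfTI volumes.}
#'     \item{seeds}{list of lists (`name`, `center_mm`, `diameter_mm`).}
#'     \item{variant}{laterality variant, default `"difference"`.}
#'     \item{n_permutations, alpha, forming_p}{inference settings
#'       (defaults 1000, 0.05, 0.001).}
#'     \item{analysis_seed}{rng seed for the permutation stream.}
#'   }
#' @return the run manifest (list), invisibly; written as
#'   `run_manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
              else yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir), !is.null(config$seeds))
  # pre-flight checks before any computation
  if (!is.null(config$cohort_dir) && !dir.exists(config$cohort_dir))
    stop("pre-flight: cohort_dir does not exist: ", config$cohort_dir)
  if (is.null(config$cohort_dir) && is.null(config$cohort))
    stop("pre-flight: config needs either 'cohort' (simulation) or 'cohort_dir'")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  variant <- config$variant %||% "difference"
  nperm <- config$n_permutations %||% 1000
  alpha <- config$alpha %||% 0.05
  forming_p <- config$forming_p %||% 0.001
  aseed <- config$analysis_seed %||% 1L
  seeds <- .as_seeds(config$seeds)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  # stage: cohort ------------------------------------------------------
  cohort <- stage("simulate", {
    if (!is.null(config$cohort_dir)) {
      paths <- sort(list.files(config$cohort_dir, "\\.nii(\\.gz)?$",
                               full.names = TRUE))
      if (length(paths) == 0)
        stop("no NIfTI volumes in ", config$cohort_dir)
      co <- read_cohort(paths)
      structure(list(grid = co$grid, Y = co$Y, truth = NULL, config = NULL),
                class = "lat_cohort")
    } else {
      gcfg <- config$grid
      grid <- symmetric_grid(unlist(gcfg$dims),
                             unlist(gcfg$voxel_size_mm %||% c(2, 2, 2)))
      cargs <- config$cohort
      cargs$regions <- .as_regions(cargs$regions)
      if (!is.null(cargs$laterality_corr))
        cargs$laterality_corr <-
          matrix(unlist(cargs$laterality_corr), length(cargs$regions))
      cc <- do.call(cohort_config, cargs)
      co <- render_cohort(cc, grid)
      write_cohort(co, file.path(out, "cohort"))
      co
    }
  })

  # stage: laterality maps ---------------------------------------------
  lmaps <- stage("latmap", cohort_laterality(cohort, variant = variant))
  smaps <- cohort_signs(lmaps)

  # stage: seed extraction ---------------------------------------------
  series <- stage("seed-extract", {
    lapply(seeds, function(sp) extract_seed_series(lmaps, sp))
  })
  names(series) <- vapply(seeds, `[[`, "", "name")
  ser_df <- data.frame(subject_id = rownames(cohort$Y) %||%
                         seq_len(nrow(cohort$Y)),
                       lapply(series, as.numeric), check.names = FALSE)
  utils::write.table(ser_df, file.path(out, "seed_series.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage: covariance + FWE --------------------------------------------
  fits <- list()
  reports <- list()
  for (i in seq_along(seeds)) {
    nm <- seeds[[i]]$name
    fits[[nm]] <- stage("covary", seed_covariance(lmaps, series[[nm]]))
    reports[[nm]] <- stage("covary",
      fwe_threshold(fits[[nm]], n_permutations = nperm, alpha = alpha,
                    forming_p = forming_p, rng_seed = aseed + i))
    write_volume(fits[[nm]]$z, file.path(out, paste0("zmap_", nm, ".nii.gz")),
                 grid = cohort$grid)
    rep_i <- reports[[nm]]
    jsonlite::write_json(
      list(seed = nm, method = rep_i$method,
           n_permutations = rep_i$n_permutations,
           alpha = rep_i$fwe_p, forming_p = rep_i$voxelwise_p_uncorrected,
           threshold = rep_i$threshold, n_significant = rep_i$n_significant,
           clusters = rep_i$clusters),
      file.path(out, paste0("fwe_", nm, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  peaks <- make_peak_table(fits, reports)
  utils::write.table(peaks, file.path(out, "peak_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage: co-lateralization -------------------------------------------
  cl_tabs <- list()
  for (i in seq_along(seeds)) {
    nm <- seeds[[i]]$name
    cl <- stage("colat", colat_map(smaps, seed_signs(lmaps, seeds[[i]])))
    write_volume(cl$cl, file.path(out, paste0("colat_", nm, ".nii.gz")),
                 grid = cohort$grid)
    pk <- if (nrow(peaks) > 0) as.matrix(peaks[, c("x", "y", "z")])
          else matrix(unlist(seeds[[i]]$center_mm), nrow = 1)
    cl_tabs[[nm]] <- cbind(seed = nm, colat_summary(cl, pk))
  }
  cl_all <- do.call(rbind, cl_tabs)
  utils::write.table(cl_all, file.path(out, "colat_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run_manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("latcov")),
    n_subjects = nrow(cohort$Y),
    seeds = lapply(seeds, unclass),
    variant = variant,
    n_permutations = nperm, alpha = alpha, forming_p = forming_p,
    analysis_seed = aseed,
    cohort_seed = if (!is.null(cohort$config)) cohort$config$rng_seed,
    outputs = basename(files),
    md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                  basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
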