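#' Null calibration of the permutation FWE procedure
#'
#' Simulates cohorts with no planted seed-target correlation (a bilateral
#' region with zero LI plus smoothed white noise), extracts the seed
#' eigenvariate from the rendered laterality maps, and runs the maxT
#' permutation procedure, recording whether any null voxel is declared
#' significant. Voxels within `exclude_mm` of the seed sphere or its
#' mirror are excluded from the search: the eigenvariate is genuinely
#' dependent on them (shared smoothed noise), so they are not null.
#'
#' Also pools the voxel-wise null correlations, whose standard deviation
#' should match `1 / sqrt(n_subjects - 1)`.
#'
#' @param n_replicates number of simulated cohorts (default 500).
#' @param n_subjects subjects per cohort (default 82).
#' @param dims grid dimensions (default 24^3, 2 mm voxels).
#' @param n_permutations permutations per cohort (default 1000).
#' @param alpha FWE level (default 0.05).
#' @param exclude_mm exclusion radius around seed and mirror (default 10).
#' @param rng_seed master seed; every replicate derives its cohort and
#'   permutation seeds from it.
#' @return list with `fwe_rate` (fraction of cohorts with any
#'   suprathreshold null voxel), `r_sd` (pooled sd of null correlations),
#'   `expected_r_sd`, `n_replicates`, `n_permutations`, `alpha`.
#' @export
calibrate_null_fwe <- function(n_replicates = 500, n_subjects = 82,
                               dims = c(24, 24, 24), n_permutations = 1000,
                               alpha = 0.05, exclude_mm = 10,
                               rng_seed = 1L) {
  grid <- symmetric_grid(dims)
  center <- c(-11, -1, -1)
  seed <- seed_spec("null_seed", center, 4)
  reg <- region_spec("null_seed_region", center, sigma_mm = 4)

  mm <- voxel_to_mni(grid, arrayInd(seq_len(n_voxels(grid)), grid$dims))
  d_seed <- sqrt(rowSums(sweep(mm, 2, center)^2))
  d_mirr <- sqrt(rowSums(sweep(mm, 2, center * c(-1, 1, 1))^2))
  excl <- d_seed <= exclude_mm | d_mirr <= exclude_mm

  hits <- logical(n_replicates)
  r_ss <- 0
  r_n <- 0
  for (rep_i in seq_len(n_replicates)) {
    cfg <- cohort_config(
      n_subjects = n_subjects, regions = list(reg),
      laterality_mean = 0, laterality_sd = 0, atypical_fraction = 0,
      noise_sd = 1, smooth_fwhm_mm = 6,
      rng_seed = (rng_seed + 7919L * rep_i) %% .Machine$integer.max)
    co <- render_cohort(cfg, grid)
    lm_ <- cohort_laterality(co)
    ser <- extract_seed_series(lm_, seed)
    lm_$L[, excl] <- NA_real_
    # |t| is mirror-symmetric on laterality maps, so the left hemisphere
    # carries the whole-brain maxT
    fit <- seed_covariance(lm_, ser, hemisphere = "left")
    rp <- fwe_threshold(fit, n_permutations = n_permutations, alpha = alpha,
                        rng_seed = (rng_seed + 104729L * rep_i) %%
                          .Machine$integer.max)
    hits[rep_i] <- rp$any_significant
    rv <- seedcov_r(fit)[fit$fit_cols]
    r_ss <- r_ss + sum(rv^2)
    r_n <- r_n + length(rv)
  }
  list(fwe_rate = mean(hits), r_sd = sqrt(r_ss / r_n),
       expected_r_sd = 1 / sqrt(n_subjects - 1),
       n_replicates = n_replicates, n_permutations = n_permutations,
       alpha = alpha)
}

# default three-region geometry for recovery studies on a 40^3 grid
.recovery_regions <- function(rho) {
  list(
    regions = list(
      region_spec("seed_region", c(-17, -17, -17), sigma_mm = 6),
      region_spec("target", c(-17, 17, -17), sigma_mm = 6),
      region_spec("null_region", c(-17, 1, 17), sigma_mm = 6)
    ),
    corr = matrix(c(1, rho, 0,
                    rho, 1, 0,
                    0, 0, 1), 3, 3)
  )
}

#' Recovery of a planted seed-target laterality correlation
#'
#' Simulates cohorts in which the laterality of a target region correlates
#' `rho` with the laterality of a seed region while a third region is
#' uncorrelated, runs the full measurement pipeline (render -> laterality
#' maps -> seed eigenvariate -> voxel-wise correlation and permutation
#' FWE), and reports (i) Fisher-z coverage of each replicate's realized
#' ground-truth correlation by the 95% interval around the measured
#' correlation at the target centre, (ii) detection power for the target
#' at the FWE threshold, and (iii) the false detection rate at the
#' uncorrelated region.
#'
#' @param n_replicates number of cohorts (default 200).
#' @param n_subjects subjects per cohort (default 82).
#' @param rho planted seed-target correlation (default 0.6).
#' @param dims grid dimensions (default 40^3, so 6 mm-sigma regions fit
#'   without truncation).
#' @param n_permutations permutations for FWE (default 499).
#' @param detect_mm a region counts as detected when a FWE-significant
#'   voxel lies within this distance of its centre (default 8 mm).
#' @param rng_seed master seed.
#' @return list with `coverage`, `power_target` (detection under the
#'   height-or-extent reporting rule), `power_target_height` (peak-level
#'   correction alone), `fpr_null`, `mean_r` (mean measured correlation at
#'   the target centre), `mean_r_true` (mean realized ground-truth
#'   correlation), and the settings.
#' @export
simulate_recovery <- function(n_replicates = 200, n_subjects = 82,
                              rho = 0.6, dims = c(40, 40, 40),
                              n_permutations = 499, detect_mm = 8,
                              rng_seed = 1L) {
  grid <- symmetric_grid(dims)
  geo <- .recovery_regions(rho)
  seed_sp <- seed_spec("seed_region", geo$regions[[1]]$center_mm, 4)
  tgt_mm <- geo$regions[[2]]$center_mm
  nul_mm <- geo$regions[[3]]$center_mm
  tgt_lin <- .lin_index(grid, mni_to_voxel(grid, tgt_mm))

  mm <- voxel_to_mni(grid, arrayInd(seq_len(n_voxels(grid)), grid$dims))
  near_tgt <- sqrt(rowSums(sweep(mm, 2, tgt_mm)^2)) <= detect_mm
  near_nul <- sqrt(rowSums(sweep(mm, 2, nul_mm)^2)) <= detect_mm

  cover <- det_t <- det_th <- det_n <- logical(n_replicates)
  r_obs <- r_true <- numeric(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    cfg <- cohort_config(
      n_subjects = n_subjects, regions = geo$regions,
      laterality_corr = geo$corr, atypical_fraction = 0,
      rng_seed = (rng_seed + 7919L * rep_i) %% .Machine$integer.max)
    co <- render_cohort(cfg, grid)
    lm_ <- cohort_laterality(co)
    ser <- extract_seed_series(lm_, seed_sp)
    fit <- seed_covariance(lm_, ser, hemisphere = "left")
    rp <- fwe_threshold(fit, n_permutations = n_permutations,
                        method = "both",
                        rng_seed = (rng_seed + 104729L * rep_i) %%
                          .Machine$integer.max)
    r_obs[rep_i] <- seedcov_r(fit)[tgt_lin]
    r_true[rep_i] <- stats::cor(co$truth$li[, "seed_region"],
                                co$truth$li[, "target"])
    cover[rep_i] <- abs(atanh(r_obs[rep_i]) - atanh(r_true[rep_i])) <=
      stats::qnorm(0.975) / sqrt(n_subjects - 3)
    det_t[rep_i] <- any(near_tgt[rp$significant_voxels])
    det_th[rep_i] <- any(near_tgt[rp$significant_voxels_height])
    det_n[rep_i] <- any(near_nul[rp$significant_voxels])
  }
  list(coverage = mean(cover), power_target = mean(det_t),
       power_target_height = mean(det_th),
       fpr_null = mean(det_n), mean_r = mean(r_obs),
       mean_r_true = mean(r_true), rho = rho,
       n_replicates = n_replicates, n_permutations = n_permutations)
}

.lin_index <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  as.integer(idx[, 1] + (idx[, 2] - 1L) * grid$dims[1] +
               (idx[, 3] - 1L) * prod(grid$dims[1:2]))
}

#' Dissociation of three seeds with disjoint planted targets
#'
#' A scaled-down analogue of a multi-seed covariance study: three seed
#' regions each correlate (rho = 0.6) with one private target region and
#' with nothing else. Each replicate runs the three seed analyses, builds
#' the peak table, and checks that every target is assigned to its
#' planted seed (FWE-significant for it, not for the others); the
#' dependent-correlation z toward the planted seed is recorded at every
#' target.
#'
#' @param n_replicates number of cohorts (default 24).
#' @param n_subjects subjects per cohort (default 82).
#' @param n_permutations permutations per seed analysis (default 499).
#' @param rng_seed master seed.
#' @return list with `assignment_rate` (fraction of replicate x target
#'   cases correctly and exclusively assigned), `median_meng_z` (median
#'   over replicates, targets and competitor seeds of the z favouring the
#'   planted seed), and the settings.
#' @export
simulate_dissociation <- function(n_replicates = 24, n_subjects = 82,
                                  n_permutations = 499, rng_seed = 1L) {
  grid <- symmetric_grid(c(40, 48, 48))
  sc <- list(c(-17, -25, -25), c(-17, -25, 25), c(-17, 25, -25))
  tc <- list(c(-17, 25, 25), c(-17, 1, -25), c(-17, 1, 25))
  regions <- c(
    lapply(1:3, function(i) region_spec(paste0("S", i), sc[[i]], 6)),
    lapply(1:3, function(i) region_spec(paste0("T", i), tc[[i]], 6))
  )
  corr <- diag(6)
  for (i in 1:3) corr[i, i + 3] <- corr[i + 3, i] <- 0.6
  seeds <- lapply(1:3, function(i) seed_spec(paste0("S", i), sc[[i]], 4))

  assigned <- 0L
  total <- 0L
  zs <- numeric(0)
  for (rep_i in seq_len(n_replicates)) {
    cfg <- cohort_config(
      n_subjects = n_subjects, regions = regions, laterality_corr = corr,
      atypical_fraction = 0,
      rng_seed = (rng_seed + 7919L * rep_i) %% .Machine$integer.max)
    co <- render_cohort(cfg, grid)
    lm_ <- cohort_laterality(co)
    series <- lapply(seeds, function(sp) extract_seed_series(lm_, sp))
    fits <- lapply(series, function(s) seed_covariance(lm_, s, hemisphere = "left"))
    reps <- lapply(seq_along(fits), function(i)
      fwe_threshold(fits[[i]], n_permutations = n_permutations,
                    method = "both",
                    rng_seed = (rng_seed + 104729L * rep_i + i) %%
                      .Machine$integer.max))
    pt <- make_peak_table(fits, reps)
    for (i in 1:3) {
      total <- total + 1L
      ok <- FALSE
      if (nrow(pt) > 0) {
        d <- sqrt((pt$x - tc[[i]][1])^2 + (pt$y - tc[[i]][2])^2 +
                    (pt$z - tc[[i]][3])^2)
        k <- which.min(d)
        if (d[k] <= 8) {
          flags <- vapply(1:3, function(j) pt[[paste0("sig_S", j)]][k], "")
          ok <- flags[i] == "fwe" && all(flags[-i] != "fwe")
        }
      }
      assigned <- assigned + ok
      for (j in setdiff(1:3, i))
        zs <- c(zs, compare_seed_correlations(lm_, series[[i]], series[[j]],
                                              tc[[i]])$z)
    }
  }
  list(assignment_rate = assigned / total, median_meng_z = stats::median(zs),
       n_replicates = n_replicates, n_permutations = n_permutations)
}

#' Hemisphere-wise decomposition of a laterality correlation
#'
#' Generates cohorts in which target laterality correlates 0.6 with seed
#' laterality and is realized either purely as a left-hemisphere increase
#' (`lambda = 1`) or purely as a right-hemisphere decrease (`lambda = 0`),
#' then regresses the raw contrast images of each hemisphere on the seed
#' laterality series and reads the z at the target centre and at its
#' mirror. Pure left increase should show the correlation only on the
#' left; pure right decrease only on the right, with negative sign.
#'
#' @param n_replicates cohorts per lambda case (default 11).
#' @param n_subjects subjects per cohort (default 82).
#' @param rng_seed master seed.
#' @return list with `left_increase` and `right_decrease`, each holding
#'   the median z at the left and right target homologues.
#' @export
simulate_mechanism <- function(n_replicates = 11, n_subjects = 82,
                               rng_seed = 1L) {
  grid <- symmetric_grid(c(24, 24, 24))
  seed_c <- c(-11, -11, -11)
  tgt_c <- c(-11, 11, -11)
  seed_sp <- seed_spec("seed_region", seed_c, 4)
  tgt_l <- .lin_index(grid, mni_to_voxel(grid, tgt_c))
  tgt_r <- .lin_index(grid, mni_to_voxel(grid, tgt_c * c(-1, 1, 1)))

  run_case <- function(lambda_target, offset) {
    zl <- zr <- numeric(n_replicates)
    for (rep_i in seq_len(n_replicates)) {
      cfg <- cohort_config(
        n_subjects = n_subjects,
        regions = list(region_spec("seed_region", seed_c, 4),
                       region_spec("target", tgt_c, 4)),
        laterality_corr = matrix(c(1, .6, .6, 1), 2),
        left_increase_fraction = c(0.5, lambda_target),
        atypical_fraction = 0,
        rng_seed = (rng_seed + offset + 7919L * rep_i) %%
          .Machine$integer.max)
      co <- render_cohort(cfg, grid)
      lm_ <- cohort_laterality(co)
      ser <- extract_seed_series(lm_, seed_sp)
      fit_l <- seed_covariance(co, ser, hemisphere = "left")
      fit_r <- seed_covariance(co, ser, hemisphere = "right")
      zl[rep_i] <- fit_l$z[tgt_l]
      zr[rep_i] <- fit_r$z[tgt_r]
    }
    list(z_left = stats::median(zl), z_right = stats::median(zr))
  }
  list(left_increase = run_case(1, 0L),
       right_decrease = run_case(0, 50000L),
       n_replicates = n_replicates)
}

#' Effect of atypical lateralization on co-lateralization
#'
#' Simulates cohorts at increasing atypical-dominance fractions and
#' records the co-lateralization proportion at a target region whose
#' laterality correlates 0.6 with the seed. Under the independent
#' (crossed-dominance) handedness model, CL at the target should fall
#' monotonically as the atypical fraction rises.
#'
#' @param fractions atypical fractions to simulate (default 0, 0.2, 0.4).
#' @param n_replicates cohorts per fraction (default 30).
#' @param n_subjects subjects per cohort (default 82).
#' @param rng_seed master seed.
#' @return list with `fractions`, `cl` (mean CL at the target centre per
#'   fraction), `n_replicates`.
#' @export
simulate_handedness_effect <- function(fractions = c(0, 0.2, 0.4),
                                       n_replicates = 30, n_subjects = 82,
                                       rng_seed = 1L) {
  grid <- symmetric_grid(c(24, 24, 24))
  seed_c <- c(-11, -11, -11)
  tgt_c <- c(-11, 11, -11)
  seed_sp <- seed_spec("seed_region", seed_c, 4)
  tgt_l <- .lin_index(grid, mni_to_voxel(grid, tgt_c))

  cl_mean <- numeric(length(fractions))
  for (fi in seq_along(fractions)) {
    cls <- numeric(n_replicates)
    for (rep_i in seq_len(n_replicates)) {
      cfg <- cohort_config(
        n_subjects = n_subjects,
        regions = list(region_spec("seed_region", seed_c, 4),
                       region_spec("target", tgt_c, 4)),
        laterality_corr = matrix(c(1, .6, .6, 1), 2),
        atypical_fraction = fractions[fi],
        rng_seed = (rng_seed + 7919L * rep_i + 1000L * fi) %%
          .Machine$integer.max)
      co <- render_cohort(cfg, grid)
      lm_ <- cohort_laterality(co)
      cl <- colat_map(cohort_signs(lm_), seed_signs(lm_, seed_sp))
      cls[rep_i] <- cl$cl[tgt_l]
    }
    cl_mean[fi] <- mean(cls)
  }
  list(fractions = fractions, cl = cl_mean, n_replicates = n_replicates)
}
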