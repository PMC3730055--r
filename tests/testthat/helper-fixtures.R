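# Small grids and cohorts used across the suite. Everything is built in
# code at test time; no stored binaries.

tiny_grid <- function(dims = c(8, 6, 4), vox = c(2, 2, 2)) {
  symmetric_grid(dims, vox)
}

# linear index helper mirroring the package's column-major layout
lin_of <- function(grid, idx) {
  as.integer(idx[1] + (idx[2] - 1L) * grid$dims[1] +
               (idx[3] - 1L) * prod(grid$dims[1:2]))
}

# a deterministic random image on a grid
random_image <- function(grid, seed = 1, subject_id = "s1") {
  set.seed(seed)
  contrast_image(rnorm(n_voxels(grid)), grid, subject_id)
}

# an exactly mirror-symmetric image
symmetric_image <- function(grid, seed = 1) {
  img <- random_image(grid, seed)
  v <- as.vector(img$values)
  contrast_image((v + v[mirror_indices(grid)]) / 2, grid, "sym")
}

# small noiseless single-region cohort with planted LI values
planted_cohort <- function(li_values, grid = symmetric_grid(c(16, 12, 12)),
                           center = c(-7, -1, -1), lambda = 1,
                           sigma = 2.5, noise_sd = 0, smooth = 0) {
  n <- length(li_values)
  cfg <- cohort_config(
    n_subjects = n,
    regions = list(region_spec("r1", center, sigma_mm = sigma)),
    laterality_mean = 0, laterality_sd = 1, atypical_fraction = 0,
    left_increase_fraction = lambda,
    noise_sd = noise_sd, smooth_fwhm_mm = smooth, rng_seed = 42
  )
  truth <- sample_laterality(cfg)
  truth$li[, 1] <- li_values
  render_cohort(cfg, grid, truth = truth)
}
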