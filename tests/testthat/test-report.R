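pipeline_config_fixture <- function(out_dir, n_perm = 150) {
  list(
    out_dir = out_dir,
    grid = list(dims = c(16, 16, 12)),
    cohort = list(
      n_subjects = 10,
      regions = list(
        list(name = "seedR", center_mm = c(-7, -5, -1), sigma_mm = 2.5),
        list(name = "tgtR", center_mm = c(-7, 5, 1), sigma_mm = 2.5)
      ),
      laterality_corr = c(1, 0.6, 0.6, 1),
      atypical_fraction = 0,
      noise_sd = 0.5, smooth_fwhm_mm = 4, rng_seed = 77
    ),
    seeds = list(list(name = "seedR", center_mm = c(-7, -3, -1),
                      diameter_mm = 4)),
    n_permutations = n_perm,
    analysis_seed = 3
  )
}

test_that("a 10-subject smoke cohort completes all stages reproducibly", {
  d1 <- file.path(tempdir(), "run1")
  d2 <- file.path(tempdir(), "run2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- run_pipeline(pipeline_config_fixture(d1))
  m2 <- run_pipeline(pipeline_config_fixture(d2))
  for (f in c("seed_series.tsv", "peak_table.tsv", "colat_summary.tsv",
              "cohort/ground_truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_identical(m1$md5, m2$md5)
  expect_true(file.exists(file.path(d1, "run_manifest.json")))
  expect_true(file.exists(file.path(d1, "zmap_seedR.nii.gz")))
  expect_true(file.exists(file.path(d1, "fwe_seedR.json")))
  # the seed's own region must be flagged for its own analysis
  pk <- read.delim(file.path(d1, "peak_table.tsv"))
  expect_gt(nrow(pk), 0)
})

test_that("pre-flight validation fails before any computation", {
  cfg <- pipeline_config_fixture(file.path(tempdir(), "never"))
  cfg$cohort <- NULL
  cfg$cohort_dir <- file.path(tempdir(), "no_such_dir")
  expect_error(run_pipeline(cfg), "pre-flight")
  expect_false(dir.exists(file.path(tempdir(), "never")))
  expect_error(run_pipeline(file.path(tempdir(), "missing.yaml")),
               "not found")
})

test_that("a YAML config file round-trips through the pipeline", {
  d <- file.path(tempdir(), "run_yaml")
  unlink(d, recursive = TRUE)
  cfg <- pipeline_config_fixture(d)
  yf <- file.path(tempdir(), "pipeline.yaml")
  yaml::write_yaml(cfg, yf)
  m <- run_pipeline(yf)
  expect_true(file.exists(file.path(d, "peak_table.tsv")))
  expect_equal(m$n_subjects, 10)
})

test_that("peak tables localize a planted cluster and flag significance", {
  g <- symmetric_grid(c(12, 10, 10))
  set.seed(71)
  n <- 40
  s <- rnorm(n)
  Y <- matrix(rnorm(n * n_voxels(g)), n)
  ctr <- c(3L, 5L, 5L)
  tgt <- lin_of(g, ctr)
  Y[, tgt] <- Y[, tgt] + 2.5 * s
  x <- list(Y = Y, grid = g)
  fit <- seed_covariance(x, structure(s, seed_name = "sA",
                                      class = "seed_series"))
  rp <- fwe_threshold(fit, n_permutations = 300, rng_seed = 5)
  pt <- make_peak_table(fit, rp)
  expect_gt(nrow(pt), 0)
  d <- sqrt((pt$x - voxel_to_mni(g, ctr)[1])^2 +
              (pt$y - voxel_to_mni(g, ctr)[2])^2 +
              (pt$z - voxel_to_mni(g, ctr)[3])^2)
  expect_lte(min(d), 2)   # planted centre recovered within one voxel
  expect_identical(pt$sig_sA[which.min(d)], "fwe")
  # peaks respect the minimum separation
  if (nrow(pt) > 1) {
    dm <- as.matrix(dist(pt[, c("x", "y", "z")]))
    expect_true(all(dm[upper.tri(dm)] >= 8))
  }
})

test_that("empty suprathreshold sets give an empty table with header", {
  g <- tiny_grid(c(4, 4, 2))
  set.seed(72)
  x <- list(Y = matrix(rnorm(10 * n_voxels(g)), 10), grid = g)
  fit <- seed_covariance(x, rnorm(10))
  # forming threshold impossible to reach with df = 8
  rp <- fwe_threshold(fit, n_permutations = 100, forming_p = 1e-12,
                      rng_seed = 2)
  pt <- make_peak_table(fit, rp)
  expect_identical(nrow(pt), 0L)
  expect_true(all(c("x", "y", "z", "z_seed", "sig_seed") %in% names(pt)))
})
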