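Package: latcov
Title: Voxel-Based Laterality, Seed Covariance and Co-Lateralization
    Mapping for fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying hemispheric lateralization of task fMRI at
    voxel resolution. Given per-subject contrast images resampled into a
    left-right symmetric standard space, the package computes voxel-wise
    laterality maps (left minus homologous right), extracts principal
    eigenvariate summaries from spherical seed regions, fits across-subject
    mass-univariate regressions of laterality (or hemisphere-specific
    activation) on seed laterality with permutation-based family-wise error
    control, tests differences between dependent seed correlations, and
    builds voxel-wise co-lateralization proportion maps. A synthetic-cohort
    generator with planted regional laterality, across-subject correlation
    structure, a handedness mixture, spatial smoothing and noise provides
    ground truth for validation, and a pipeline driver runs the full
    analysis reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
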