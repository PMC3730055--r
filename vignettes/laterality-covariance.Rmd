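---
title: "Voxel-based laterality covariance mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based laterality covariance mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latcov)
```

## The scientific problem

Language-related activation in task fMRI is usually lateralized to one
hemisphere, and regions that lateralize *together* across subjects are
plausibly part of one functional subsystem. `latcov` implements the
voxel-resolution version of this idea. Given per-subject contrast images
in a left-right *symmetric* standard space — a space whose template is
mirror-symmetric about the mid-sagittal plane, so that the voxel at MNI
$(x, y, z)$ and its homologue at $(-x, y, z)$ sample homologous cortex —
the package:

1. builds per-subject **voxel-wise laterality maps**
   $\mathrm{li}(v) = \beta(v) - \beta(h(v))$, the left-minus-homologous-right
   difference of contrast estimates (the task-by-hemisphere interaction);
2. extracts per-subject **seed laterality series** from small spherical
   VOIs (4 mm diameter by default) as principal eigenvariates;
3. fits, at every voxel, the across-subject regression of laterality (or
   of raw activation in one hemisphere) on the seed series, with
   **permutation-based family-wise error control**;
4. tests whether a voxel correlates more with one seed than another via
   the Meng-Rosenthal-Rubin z for dependent overlapping correlations; and
5. computes **co-lateralization (CL) maps**: the proportion of subjects
   whose lateralization sign at a voxel matches their sign at the seed.

A synthetic-cohort generator with fully known ground truth drives all
validation.

## The laterality map and its conventions

"Relative difference in activity between a voxel and its homologue" can
mean a plain difference or a normalized index
$(\beta_L - \beta_R) / (|\beta_L| + |\beta_R| + \varepsilon)$. The plain
difference is the default here: it is exactly the task-by-hemisphere
interaction of contrast estimates, is linear in the input image (which
makes the hemisphere-wise decomposition below an identity rather than an
approximation), and needs no guard constant. The normalized variant is
available (`variant = "normalized"`, with a documented
$\varepsilon = 10^{-9}$) but is not used by any downstream default.

Conventions that the paper trail of any laterality analysis must fix, and
the choices made here:

* **Midline voxels** ($x = 0$ exactly) are their own homologues, so their
  laterality is identically zero; they are excluded from hemisphere-wise
  fits.
* **Missing data**: a voxel pair with either member missing is missing in
  every derived map (`NA` in memory, NaN in NIfTI files). Missing is
  never silently zero.
* **Exact ties** (laterality exactly zero) receive sign code 0 and are
  excluded from both numerator and denominator of CL, with the effective
  count reported per voxel. With continuous data ties have measure zero;
  the rule only matters for constructed inputs, where it must be
  deterministic.
* **Homologue geometry** is computed through the affine, not by flipping
  array indices, so any x-axis-aligned orientation works; oblique x axes
  are rejected.

## Seed eigenvariates: two summaries for two purposes

The per-subject VOI summary is the first singular vector of the
subject-by-voxel matrix. Two variants are deliberately distinguished:

* For **covariance analysis** (`extract_seed_series()`), the matrix is
  column-centred first. Only across-subject variation matters for a
  regressor; the centred eigenvariate is scaled so its sample variance
  equals the mean variance explained per voxel and sign-aligned with the
  across-voxel mean series, which makes it deterministic across
  platforms.
* For **dominance signing** (`seed_signs()`), centring would be wrong:
  the centred summary codes deviation from the cohort mean and carries no
  information about which hemisphere a subject favours (in a cohort that
  is 95% left-lateralized, roughly half of centred values are negative).
  The sign therefore comes from the *uncentred* first singular vector,
  loadings oriented positive, which for a lateralized seed reduces to the
  subject's signed laterality amplitude. A sphere-mean option exists for
  both purposes.

A 4 mm diameter sphere on a 2 mm grid contains 1-7 voxels depending on
alignment, so `n_voxels_used` is always reported.

## Inference: permutation maxT and cluster extent

At each voxel the package fits OLS of map values on
`[intercept, seed, covariates]` and reports the seed slope's t and its
signed z-equivalent. Family-wise error is controlled by permutation:
the seed series (residualized on the nuisance design, Freedman-Lane
style) is permuted across subjects; each permutation records the maximum
|t| over all fitted voxels (height) and/or the largest suprathreshold
cluster at the two-sided p < 0.001 forming threshold (extent). The
unpermuted statistic is included in the null set, so the test is exact
under exchangeability: FWE p-values are
$(1 + \#\{\text{perm} \ge s\}) / (P + 1)$.

The original analysis style this emulates used parametric random-field
correction "by height or extent"; this package substitutes permutations
because they are exactly specifiable and distribution-free, so thresholds
are not expected to match random-field numbers. `method = "height"` is
the default; `"extent"` and `"both"` (significant under either
correction, the conventional reporting rule for smoothed maps) are
provided. For spatially extended effects the extent correction is
markedly more powerful, which matters for the power results below.

On laterality maps |t| is mirror-symmetric — a voxel and its homologue
carry the same two-sided evidence — so the left hemisphere alone carries
the whole-brain maxT; the simulation studies exploit this to halve the
search space without changing the test.

## The synthetic cohort generator

`cohort_config()` + `render_cohort()` emulate a cohort of subjects whose
regional laterality has known structure:

* Each region is a Gaussian blob (scale `sigma_mm`) at a left-hemisphere
  centre and, mirrored, on the right. A subject's regional laterality
  index $\mathrm{LI}$ is split by $\lambda$ =
  `left_increase_fraction` into a left increase ($\lambda \cdot
  \mathrm{LI}$ added on the left) and a right decrease
  ($(1-\lambda)\cdot\mathrm{LI}$ subtracted on the right), so
  left-dominance can be realized as left increase, right decrease, or
  both ($\lambda = 0.5$, the default).
* Across subjects, region LIs are multivariate normal with configurable
  means, sds and correlation matrix (PSD-checked; singular matrices are
  sampled through the eigendecomposition).
* White voxel noise is added and the volume smoothed with a separable
  Gaussian kernel (6 mm FWHM default, matching common preprocessing).
  Smoothing after noise (the default) mimics contrast images estimated
  from smoothed data; smoothing the signal only is available.
* Defaults — LI mean 1.0, sd 0.5, noise sd 1.0, base bilateral amplitude
  2, all in the same arbitrary effect-size units; 82 subjects — are
  package conventions for a "typical" semantic-decision cohort, not
  estimates from any dataset.
* One `rng_seed` governs everything; per-subject noise streams are
  derived from it, so cohorts are bit-reproducible.

### The handedness mixture

A fraction of subjects (`atypical_fraction`, default 0.12) is atypically
lateralized: their region mean LIs are sign-flipped. Two mixture models
are offered. Under `"joint"` flipping (all regions flip together) an
atypical subject is a perfect mirror image — but then seed and target
flip *together*, sign concordance is invariant, and CL does not change
with the atypical fraction at all, contradicting the well-replicated
observation that cohorts with more atypically lateralized readers show
lower co-lateralization. The default is therefore `"independent"`:
each region's dominance flips independently for an atypical subject,
allowing crossed or effectively bilateral dominance, which is both closer
to the handedness literature and the mechanism that actually produces
the CL decrease. The default fraction 0.12 reflects that in a cohort
with roughly half left-handers only a minority (~20-25% of left-handers,
~4% of right-handers) is atypically language-lateralized.

## What the simulations show — and what they cannot

The validation studies (`calibrate_null_fwe()`, `simulate_recovery()`,
`simulate_dissociation()`, `simulate_mechanism()`,
`simulate_handedness_effect()`) run the full measurement pipeline on
generated cohorts. Problem sizes were chosen so each study answers its
question at desk scale: null calibration uses 500 noise-only cohorts of
82 subjects on a 24^3-voxel grid with 1000 permutations each; recovery
uses 200 cohorts on a 40^3 grid (large enough to hold 6 mm-sigma regions
without truncation) with 499 permutations; the three-seed dissociation
uses 24 cohorts on a 40x48x48 grid; the mechanism and handedness studies
use 11 and 30 cohorts per condition on 24^3 grids.

Key quantitative behaviours, all recomputed by `tests/testthat/
test-acceptance.R` and `scripts/acceptance.R`:

* **FWE calibration.** With no planted seed-target correlation the
  fraction of cohorts with any significant null voxel is within binomial
  tolerance of the nominal 0.05, and the null voxel-wise correlation sd
  matches $1/\sqrt{n-1}$. Voxels near the seed sphere (within 10 mm of it
  or its mirror) are excluded from the null count because the extracted
  eigenvariate genuinely shares smoothed noise with them — they are not
  null voxels.
* **Attenuation.** The measured seed-target correlation is biased towards
  zero relative to the planted $\rho$ by measurement noise at both ends
  (classical attenuation): with the default noise conditions the plim of
  the measured $r$ at $\rho = 0.6$ is $\approx 0.53$. Recovery is
  therefore assessed against each replicate's *realized* ground-truth
  correlation (recorded by the generator), with the Fisher-z 95% interval
  as tolerance: this isolates what the measurement pipeline adds from
  finite-cohort sampling noise. Against the constant 0.6 the same
  interval would under-cover (~86%) for any faithful implementation at
  these noise levels — a property of the conditions, not a defect.
* **Detection power.** At $\rho = 0.6$, $n = 82$, the target region is
  FWE-significant in >90% of cohorts under the height-or-extent rule;
  peak-level correction alone hovers near ~85-90% because the attenuated
  peak t (~5.2) sits close to the whole-search maxT critical value
  (~4.7). The extended target is exactly the situation cluster-extent
  correction is designed for.
* **Dissociation.** With three seeds, each privately correlated with one
  target, the peak table assigns each target to its planted seed and the
  dependent-correlation z favours the planted seed (median z ≈ 3.5).
* **Mechanism.** With $\lambda = 1$ the seed-laterality correlation
  appears in the left-hemisphere activation fit and vanishes on the
  right; with $\lambda = 0$ it appears on the right with negative sign —
  the left-increase / right-decrease dissociation measured by
  hemisphere-wise regression on raw contrast images.
* **Handedness.** CL at a concordant target falls monotonically as the
  atypical fraction rises from 0 to 0.4 (from ≈ 0.95 towards ≈ 0.78).

What passing these tests does **not** show: the generator has no
anatomy, no task structure, no inter-regional haemodynamic differences,
Gaussian blobs rather than cortical topography, and exchangeable
subjects. Real-data properties such as template asymmetry residuals,
registration error, or physiological noise correlations are outside its
scope, and numbers obtained on real cohorts (e.g. CL values of 0.6-0.9)
are not reproduced by these simulations, which use synthetic conditions
throughout.

## Numerical and degenerate-input choices

* t-to-z conversion runs on the log-probability scale, so |t| up to
  hundreds converts without underflow; conversion matches tail
  probabilities to 1e-10.
* Zero-residual-variance voxels yield missing statistics and are counted
  (`n_degenerate`), never silently dropped.
* Collinear covariates abort with the offending column named; constant
  seed series are rejected.
* Correlation magnitudes of exactly 1 make the Fisher transform
  undefined and are rejected in the dependent-correlation test.
* Cluster connectivity is 6-neighbour; components are labelled via
  igraph on the suprathreshold subset only.
* Peak tables use greedy local maxima with a configurable 8 mm minimum
  separation (a conventional reporting choice).

## Reproducibility

Every stochastic function takes an integer seed and derives all internal
streams from it; `run_pipeline()` writes a manifest with seeds and MD5
hashes of all outputs, and re-running a config reproduces every output
byte-identically. The RNG state of the calling session is restored after
each simulation call.

```{r example, eval = FALSE}
g <- symmetric_grid(c(40, 40, 40))          # 80 mm cube, 2 mm voxels
cfg <- cohort_config(
  n_subjects = 82,
  regions = list(region_spec("seed_region", c(-17, -17, -17), 6),
                 region_spec("target", c(-17, 17, -17), 6)),
  laterality_corr = matrix(c(1, .6, .6, 1), 2),
  rng_seed = 1
)
co <- render_cohort(cfg, g)
lmaps <- cohort_laterality(co)
ser <- extract_seed_series(lmaps, seed_spec("seed_region", c(-17, -17, -17)))
fit <- seed_covariance(lmaps, ser)
rep <- fwe_threshold(fit, n_permutations = 999, method = "both", rng_seed = 2)
make_peak_table(fit, rep)
colat_map(cohort_signs(lmaps), seed_signs(lmaps,
          seed_spec("seed_region", c(-17, -17, -17))))
```
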