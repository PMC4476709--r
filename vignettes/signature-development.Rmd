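---
title: "Developing and evaluating affective brain signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and evaluating affective brain signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectsig)
```

# The problem and the model

Standard fMRI analyses ask where the brain responds to emotional stimuli.
This package asks the predictive question instead: can a fixed pattern of
voxel weights, applied to a new person's condition-level beta image by a
simple dot product, predict how intensely that person reports feeling?
A signature here is a weight vector $w$ over in-mask voxels plus an
intercept $b$; its expression in an image $\beta$ is the pattern response

$$PR = \beta \cdot w + b,$$

in rating units when trained on ratings. The estimator is LASSO-PCR:

1. voxel features are mean-centered (no variance scaling — voxel units
   are homogeneous, and scaling would up-weight low-variance voxels);
2. PCA reduces the centered matrix to at most $n_{\mathrm{obs}} - 1$
   components;
3. the component scores enter an L1-penalized least-squares fit, which
   zeroes most component coefficients;
4. the surviving components are refit by ordinary least squares, so the
   retained directions are not biased toward zero by the penalty;
5. the refit coefficients are back-projected through the loadings to a
   voxel map, with the intercept adjusted for the centering.

Steps 1–5 make the voxel-space prediction $X w + b$ *identical* to the
component-space prediction; this back-projection identity is enforced by
tests at $10^{-6}$ and is the main internal consistency check of the
fitting code.

The model assumes the outcome is (approximately) interval-scaled and
monotone in the underlying experience, that condition-level beta images
are comparable across subjects after normalization to a common space,
and that a single linear pattern — shared across subjects — carries the
predictive signal. The within-subject tooling (`fit_within_subject()`)
exists precisely to probe how much is lost by the shared-pattern
assumption.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_components` | $n_{\mathrm{obs}}-1$ | components | maximal lossless PCA; smaller values can be forced for replication experiments |
| `penalty` | `"cv"` | glmnet $\lambda$ | inner 5-fold CV on the component scores; a fixed numeric value gives exact reproducibility |
| `fraction` (split) | 2/3 | subjects | training share; test size is `round((1/3) n)`; stratified on subject-mean ratings with a 0.1-rating-unit balance requirement at $n \ge 30$ |
| `B` (bootstrap) | 5000 | resamples | scale down for exploratory runs; z and p stabilize in the low hundreds |
| bootstrap `unit` | subject | — | resampling whole subjects preserves within-subject dependence; row-level resampling is available |
| threshold `rule` | `p:0.001` | — | uncorrected p from the bootstrap z; `fdr:q` applies Benjamini–Hochberg over in-mask voxels |
| `k` (extent) | 10 | voxels | removes connected survivors smaller than k (26-connectivity by default) |
| `cut_fraction` | 0.31 | of max merge height | the dendrogram cut governing the subnetwork count; deliberately exposed as a tunable |

# The synthetic-data generator

`sim_config()` + `simulate_dataset()` generate the study conditions the
rest of the package is validated against. An observation for subject $s$
at rating level $r$ is

$$x_{s,r} = r\,(\alpha + \delta_s)\,t + \varepsilon,$$

with ground-truth pattern $t$ (contiguous signed blobs, smoothed, placed
with a separation margin so distinct systems stay distinct), effect size
$\alpha$ (default 0.5 per rating unit), subject amplitude deviations
$\delta_s \sim N(0, 0.1)$, and $\varepsilon$ a Gaussian random field:
white noise smoothed by a separable Gaussian kernel (FWHM 3 voxels,
circular convolution) and rescaled so the marginal voxel SD equals
`noise_sd` (default 1) exactly, including on small grids where the
kernel folds onto itself. Rating levels are present per subject with
probabilities (0.98, 0.88, 0.98, 0.88, 0.80), matching the empirical
fact that many participants never use the extreme ratings — this is what
makes the subject-exclusion rules of the extreme-level classification
tests reachable by tests. The pain modality uses three levels
(low/medium/high) and, in validation scenarios, a ground-truth pattern
orthogonalized against the emotion pattern, giving a true double
dissociation. A trial-level variant (`simulate_trial_dataset()`) and an
HRF-convolved 4-D timeseries generator (`simulate_timeseries()`, double
gamma with the canonical 6 s peak / 16 s undershoot) support the
within-subject, clustering, and chronometry analyses.

What the generator does *not* emulate: physiological and motion
artifacts, spatial misregistration across subjects, non-Gaussian and
spatially non-stationary noise, first-level GLM estimation error, and
session structure. Passing tests therefore demonstrate correctness of
the estimators and the internal consistency of the pipeline under the
stated statistical model — not performance on real scans.

# Numerical choices and degenerate inputs

- **Penalty per bootstrap resample.** Each resample refits with the
  penalty fixed from the full-data fit: deterministic and an order of
  magnitude cheaper than re-running the inner CV, at the cost of
  ignoring penalty-selection variability. `penalty = "cv"` re-selects
  per resample when that variability is the question.
- **Degenerate bootstrap voxels.** Zero bootstrap SD with zero mean
  gives $z = 0, p = 1$; zero SD with non-zero mean is flagged and gets
  the sentinel $p = 1/(B+1)$. The accumulation uses Welford's algorithm
  so that bitwise-identical resample fits produce an exactly zero SD.
- **Single-interval threshold.** Candidates are the midpoints between
  adjacent sorted responses plus one candidate below and above the
  range; the signal-detection bias $c$ uses rates clamped at $1/(2n)$
  per class before the probit transform; ties in $|c|$ break toward
  higher balanced accuracy, then the lower threshold. The scan is exact
  (no optimization), and a brute-force reimplementation in the tests
  confirms both the chosen threshold and the accuracy.
- **Forced choice.** Ties are credited one half; the binomial test uses
  strict wins among non-tied pairs.
- **"Robust ranked" spatial correlation.** Both maps are ranked within
  scope, standardized, and related by Huber M-regression in both
  directions; the symmetrized slope (sign-preserving geometric mean) is
  reported, clamped to $[-1, 1]$. Plain Spearman is also available.
- **ROI-to-rating calibration.** ROI means have no intrinsic rating
  units, so RMSE benchmarking uses a univariate linear calibration
  estimated on the training split only (`calibrate_responses()`).
- **Rank normalization for clustering.** Trial responses are ranked
  within subject per region (average ranks on ties), then z-scored
  within subject; distances are computed on the subject-concatenated
  trial × region matrix. This makes the clustering substrate invariant
  to monotone subject-level response transforms.
- **Ward clustering.** `hclust(method = "ward.D2")` on Euclidean
  distances; the tests verify merge-for-merge agreement with a naive
  $O(n^3)$ centroid-formula implementation.
- **Connectivity.** 26-connectivity for extent filtering and region
  extraction by default (6 available); region order is deterministic
  (size, then smallest voxel index).
- **Virtual lesions.** Operate on the thresholded map; the intercept is
  retained unchanged by `remove` and set to zero by `only`, so the two
  responses sum exactly to the full-map response with the intercept
  counted once.
- **Constant outcomes** (all ratings equal) yield an intercept-only
  model with a warning rather than an error, and correlations that
  cannot be defined are returned as flagged `NA`s, never silently as 0.

# Design decisions on genuinely open points

- **Component count.** The component budget is tied to the number of
  training observations ($n-1$), not the number of subjects; a smaller
  fixed count can be passed for replication-style experiments. (At
  rating-level granularity, subjects × levels rows enter PCA.)
- **Bootstrap resampling unit.** Subject-level by default — rows within
  a subject are strongly dependent, and resampling them independently
  understates weight variability. This is a modeling choice, not a claim
  about any particular published analysis.
- **Vectorization order** is fixed as R's column-major (first axis
  fastest) order over the mask's `TRUE` cells, so two loads of one mask
  always agree; masks, images and weight maps must share grid and
  affine, with an explicit `resample_grid()` (nearest-neighbour for
  masks, trilinear for continuous maps) for anything that does not.
- **Intercept storage.** NIfTI has no intercept slot; it travels in a
  JSON sidecar next to the map and is restored on read.
- **Dendrogram cut at 31%** of the maximum merge height is a default,
  not a discovery procedure: the resulting cluster count is reported,
  and the cut is a parameter precisely because reasonable analysts can
  cut elsewhere.
- **Command surface.** The package's functions (and `run_pipeline()`,
  which executes simulate → train → bootstrap → evaluate → cluster →
  lesion from a YAML config and writes a JSON manifest with parameters,
  seeds and file digests) are the interface; no shell wrapper is
  shipped.

# Problem sizes used in validation

The test suite and `scripts/acceptance.R` run on simulated grids of
roughly $10\times10\times8$ to $16\times16\times12$ voxels with 6–60
subjects, bootstrap depths of 20–150, and 20–30 trials per subject for
the within-subject and clustering analyses. These sizes were chosen so
the full validation executes in minutes on a single CPU while keeping
every estimator in its intended regime (more observations than selected
components, both classes present in every classification cell, several
voxels per true region after thresholding).

# Known limitations

- Pooled k-fold prediction correlations carry a small *conservative*
  bias under the null: when a fold model degenerates to its intercept,
  it predicts the training-fold mean outcome, which anti-correlates
  with the held-out fold's outcomes. In our null simulations this biases
  the mean cross-validated $r$ to about $-0.06$ at 20 trials and 5
  folds. The tests therefore check that null simulations never look like
  *positive* decoding signal; users comparing small within-subject
  correlations to zero should keep the artifact's sign in mind.
- Balanced-accuracy standard errors use the independent-binomial
  approximation per class; for small cells the exact binomial p-value
  against chance is the more trustworthy quantity.
- The bootstrap p-values come from the normal approximation to the
  bootstrap z; percentile intervals are not implemented.
- Classification cells that compare two modalities concatenate two
  independent samples; their single-interval threshold is estimated on
  the pooled responses, which assumes comparable response scales across
  the two test sets.
- Evaluation of published signatures against released response tables
  is supported by `read_response_table()` (canonical column sniffing,
  including per-cluster `C_*` columns), but no third-party data ship
  with the package; the corresponding acceptance checks run only when
  the user supplies those tables under `inst/extdata/`.
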