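---
title: "Methods: hierarchical partner-matched ICA, Granger causality, and connectivity-based classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical partner-matched ICA, Granger causality, and connectivity-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpmica)
```

# Overview

`hpmica` implements a complete resting-state fMRI connectivity analysis as a
reusable, tested pipeline:

1. **Subject-level spatial ICA** decomposes each subject's 4D run into
   spatially independent component maps and their time courses.
2. **Hierarchical partner matching (HPM)** pairs components across subjects
   by spatial similarity (first level), then pairs the resulting cluster
   representatives across ICA model orders (second level), and keeps, for
   each cluster-of-clusters, the first-level cluster with the highest
   Cronbach's alpha — the most reproducible version of each network.
3. **Group statistics** compare the matched subject maps between groups with
   a covariate-adjusted voxelwise linear model, corrected by a Monte-Carlo
   cluster-extent threshold and optionally restricted to resting-state
   network (RSN) masks; a severity score can be correlated with per-subject
   cluster summaries.
4. **Granger causality** estimates directed (effective) connectivity between
   the matched networks' time courses, including relay-mediated paths.
5. **Classification** combines functional (map-based) and effective
   (GCI-based) connectivity features and evaluates maximum-uncertainty LDA
   (MLDA) and a Gaussian-kernel SVM under leave-one-out cross-validation
   (LOOCV) with fold-nested feature selection.

Because clinical resting-state data of this kind are rarely shareable, the
package ships a **synthetic cohort generator** that plants known spatial
networks, known directed couplings, and known group differences, so every
stage of the pipeline is falsifiable against ground truth.

# The synthetic cohort model

Each subject's data are generated as

$$X_v(t) = \sum_{k=1}^{K} a_{k} \, s_k(v)\, z_k(t) + \varepsilon_v(t),$$

where $s_k$ are smooth, spatially separated, unit-norm source maps; $z_k$
are network time courses following a stable lag-1 vector autoregression
$z_t = C\, z_{t-1} + \eta_t$; $a_k$ are per-subject network amplitudes; and
$\varepsilon$ is white Gaussian observation noise.

Group differences enter in exactly the two ways the analysis is designed to
detect:

* **Amplitude (functional-connectivity analog):** group A's multipliers for
  networks 1–3 are raised by one between-subject standard deviation
  (multiplier 1.2 versus 1.0 with `amp_sd = 0.2`).
* **Coupling (effective-connectivity analog):** the directed edges
  $2 \to 1$ and $3 \to 1$ are weakened by 0.3 in group A, mimicking reduced
  top-down influence in a patient group.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_per_group` | 12 | desk-scale version of a 20-per-group clinical cohort |
| `grid` | 16 × 16 × 8 | smallest grid that places 6 non-overlapping networks with room for background voxels |
| `n_volumes`, `tr_seconds` | 150, 2 s | scaled down from a typical 8-minute, 240-volume acquisition |
| `n_networks` | 6 | enough to exercise matching, relays, and selection |
| `signal_scale` | 10 | puts peak in-blob signal SD near 1, so `noise_sd = 0.5` is half the signal SD — the regime in which planted structure is recoverable |
| `noise_sd` | 0.5 | see above |
| `smooth_fwhm_mm` | 6 | sources are smooth at roughly two voxel widths |

A severity score is generated for group A as a noisy linear readout of the
network-1 amplitude (readout slope and noise chosen so the population
correlation with the true amplitude is about 0.8), giving the
severity-correlation stage something real to find. Age and sex are drawn
from matched distributions with **zero true effect** by default, so
covariate adjustment is testable as a no-op; `confound_age = TRUE` injects a
real age effect for sensitivity studies.

What the generator deliberately does **not** emulate: hemodynamic response
convolution, physiological and motion artifacts, scanner drift beyond a
linear trend, spatial inhomogeneity of noise, and anatomical (MNI-space)
realism. Passing tests therefore demonstrate that the *statistical
machinery* is correct under the stated model, not that the pipeline is
robust to every artifact of real acquisitions.

# Preprocessing

The pipeline accepts already-aligned volumes. Preprocessing is minimal and
explicit: optional separable Gaussian smoothing parameterized by FWHM in mm
(per-axis $\sigma_\text{vox} = \mathrm{FWHM} / (2\sqrt{2\ln 2}\,
d_\text{vox})$), then per-voxel linear detrending and scaling to zero mean,
unit variance. Smoothing uses symmetric (edge-repeating) reflection at the
boundaries, which conserves total intensity exactly — the right behaviour on
the small grids the generator produces. Zero-variance in-mask voxels are
dropped from the mask with a warning; the default mask is the set of
nonzero-variance voxels, since synthetic grids have no anatomical template.

# Subject-level spatial ICA

The decomposition models the time-by-voxel matrix as mixing (t × N) times
sources (N × voxels), with sources independent across voxels. The estimator
is fixed-point negentropy-maximizing ICA with the logcosh contrast, PCA
whitening and symmetric decorrelation, restarted from three random rotations
(the restart with the best negentropy proxy wins). Maps are z-scored over
the mask and sign-fixed to non-negative skewness (blob-positive); time
courses are flipped to match. Determinism: every restart's initial rotation
is derived from the caller's seed.

Two numerical realities are worth knowing. First, per-voxel standardization
rescales faint out-of-network noise to unit variance, so recovered maps
carry a noise floor and spatial correlations with planted sources saturate
slightly below 1 (about 0.98 for single subjects under the default
conditions; cluster representatives, which average over subjects, reach
0.96–0.98 on the default cohort). Second, disjoint-support sources are not
strictly independent as spatial distributions, which bounds ICA recovery
away from perfection even at high SNR; this is a property of the model, not
of the optimizer.

# Partner matching and reproducibility

Similarity between components is the absolute Pearson correlation of their
z-scored maps. Matching is greedy reciprocal-best: seed a cluster with the
globally most similar cross-subject pair, then admit, per remaining
subject, the component with the highest mean similarity to the current
members, provided its similarity to *every* member reaches
`match_threshold` (default 0.4; ties break to the lower component index).
Each subject contributes at most one component per cluster. On small
problems (≤ 4 subjects × 4 components) this greedy rule provably recovers
the exhaustive best assignment in the test suite's fixtures; an optimal
assignment solver is deliberately not bundled.

Cronbach's alpha scores each cluster with members as items and in-mask
voxels as observations:
$\alpha = \frac{k}{k-1}\left(1 - \sum_i \mathrm{var}_i /
\mathrm{var}_\text{sum}\right)$. This is the only item/observation
orientation that yields one alpha per cluster.

The second level repeats the same matching rule on first-level cluster
representatives across model orders (default sweep `{6, 8, 10}` around the
planted network count; an acquisition-scale sweep such as 20–120 by 10 is a
configuration choice). Groups spanning fewer than `min_orders` distinct
orders (default: a majority of supplied orders) are dropped, and within each
group the alpha-maximal cluster is selected, with ties broken by larger
membership, then lower model order.

# Group statistics

Each selected cluster's member maps (one per subject — never the
representative reused per subject) enter a per-voxel ordinary least squares
fit with intercept, group indicator, age and sex; the group-contrast t is
reported with $df = n - \mathrm{rank}(X)$. Tests are two-sided, since both
stronger and weaker connectivity are of interest.

The cluster-extent threshold is calibrated by Monte Carlo: simulate Gaussian
noise on the analysis grid, smooth at the map FWHM, **re-standardize over
the mask** (without this the voxel threshold loses its nominal level after
smoothing), apply the two-sided voxel threshold, and record the largest
face-connected (6-neighbour) suprathreshold cluster. The extent `k` is the
smallest size whose null exceedance probability is at most the target
family-wise error. The pipeline derives one extent on the full analysis
mask and shares it across clusters; RSN masks are subsets of that mask, so
the shared extent is conservative there. Default simulations per run: 500
(10,000 is a configuration choice at acquisition scale).

RSN masks take the positive tail of each cluster's one-sample t-map at
`mask_p` (default 0.001). The per-subject scalar used for severity
correlation and functional-connectivity features is the mean member-map z
over a surviving cluster's voxels (a peak-voxel option exists); the Pearson
correlation p-value uses the exact t transform.

# Granger causality

For series $y$ and candidate cause $x$, the pairwise index is
$\mathrm{GCI}(x \to y) = \ln(\sigma^2_\text{reduced} /
\sigma^2_\text{full})$, comparing autoregressions of $y$ on its own lags
with and without $x$'s lags. Residual variances use their residual degrees
of freedom by default. This choice matters: with maximum-likelihood
denominators the raw index has an upward bias of order $p/T$ under the
null, and because its sampling SD shrinks at the same rate, within-group
one-sample t-tests of "GCI ≠ 0" reject at far above the nominal level *at
any series length*. The df correction centres the null. The residual null
distribution is still $\chi^2_1$-shaped (right-skewed), so such tests
remain somewhat anticonservative — a property of testing a non-negative
quantity, documented rather than hidden; `small_sample = FALSE` restores
the textbook estimator for which the full model never fits worse.

The relay-mediated index is
$\max\!\big(0, \mathrm{GCI}(x \to y) - \mathrm{GCI}(x \to y \mid
\text{relay})\big)$, where the conditional term augments both models with
the relay's lags (Geweke-style conditional GC). It is large when influence
flows through the relay and near zero when the path is direct or the relay
is independent. This definition is isolated behind one function so an
alternative (e.g. minimum of path-segment GCIs) can be swapped.

The default VAR order is 1 (the generator's ground truth is lag-1);
`select_var_order()` offers BIC selection over 1–5 for data of unknown
order. Estimates below 0 are clipped for reporting but can be retained
unclipped for calibration work. Group summaries mirror the usual reporting
shape: per-group mean ± SD with a within-group nonzero test, plus a
pooled-variance two-sample t per connection.

# Classification

Features are per-subject mean z within each significant group-difference
cluster (functional connectivity) concatenated with all per-subject GCIs
between selected networks (effective connectivity). LOOCV holds out one
subject per fold; **feature standardization parameters and the two-sample
t-test selection (p < 0.05, uncorrected) are computed on the n − 1 training
rows only** and then applied to the held-out row. If no feature passes the
selection level in a fold, the single smallest-p feature is kept so no fold
is left featureless.

MLDA regularizes the pooled within-class covariance by raising every
eigenvalue below the mean eigenvalue to that mean, then uses the classical
discriminant $w = S_*^{-1}(\mu_1 - \mu_2)$ with the boundary at the
projected-mean midpoint. When no eigenvalue lies below the mean (an equal
spectrum), MLDA coincides with classical LDA exactly; in the n < d regime it
stays finite and deterministic. Final feature weights are averaged over the
folds in which each feature was selected, with selection frequencies
reported alongside.

The kernel SVM uses $k(u, v) = \exp(-\lVert u - v\rVert^2 / 2\sigma^2)$
with width $\sigma = 0.5$ by default; "width" is interpreted as $\sigma$
(not the rate $\gamma$), and the soft-margin constant defaults to C = 1 —
both configurable. Sensitivity and specificity take the patient-analog
group as positive, so accuracy always equals
$(\mathrm{sens} \cdot n_+ + \mathrm{spec} \cdot n_-) / n$ exactly.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes the enabled stages in order, deriving every
stage's seed deterministically from the master seed, and writes a JSON
manifest (stage parameters, timings, output files with MD5 hashes) when an
output directory is set. Re-running a configuration reproduces all outputs
bit-identically. `validate_config()` returns structured errors and warnings
(unknown keys with nearest-key hints, unstable couplings, an order list too
short for hierarchical matching) without throwing.

The default problem sizes — 12 subjects per group on a 16 × 16 × 8 grid,
150 volumes, 6 networks, ICA orders {6, 8, 10}, 500 extent simulations —
complete the full pipeline in well under a minute on one CPU and are the
sizes used throughout the test suite; acquisition-scale settings are plain
configuration changes.

# Known limitations

* The partner-matching similarity and greedy rule are a documented stand-in
  for the original HPM formulation, which is not fully specified in public
  descriptions; both are isolated behind `match_components()`.
* Spatial ICA recovery of disjoint-support sources is bounded below 1 by
  the model itself (see above); comparisons against planted maps should
  expect ~0.95–0.98, not 1.0.
* Within-group "GCI ≠ 0" t-tests remain mildly anticonservative under the
  null even after df correction, because the null GCI is skewed.
* No hemodynamic deconvolution precedes Granger estimation; indices are
  interpretable for the planted VAR model, and at acquisition TRs they
  carry the usual caveats of lag-based methods on slow signals.
* Only two-group designs are supported end to end; the GLM accepts
  arbitrary covariates but contrasts only the group indicator.
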