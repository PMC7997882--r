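---
title: "Methods: geographically weighted analysis of areal health data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographically weighted analysis of areal health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Chronic-disease prevalence measured over areal units — the motivating case
is county-level type 2 diabetes prevalence against six socioeconomic and
lifestyle risk factors (obesity, physical inactivity, access to exercise,
food environment, poverty, low education) — is rarely governed by one
spatially constant relationship. A global regression answers "how is the
outcome related to the predictors on average"; the public-health questions
are local: *where* is each risk factor most strongly associated with the
outcome, and where does a global model misrepresent the process? gwareal
implements the standard geographically weighted (GW) toolchain for such
questions: exploratory local statistics, a local linear model (GW-OLS), a
local ensemble model (GW-RF), and a harness to compare their predictive
skill against their global counterparts.

All analyses operate on an `area_frame`: one row per areal unit with a
unique id, planar centroid coordinates, one continuous outcome and p
continuous predictors. Coordinates are treated as planar throughout; all
distances are Euclidean in the supplied units. Longitude/latitude inputs
must be projected upstream (the pipeline offers an equirectangular
fallback, with a warning, for convenience only).

## Spatial weighting

Every GW stage shares one weighting vocabulary:

* **Adaptive bandwidth**: the kernel radius at unit *i* is the distance to
  its k-th nearest neighbour, so each local model sees the same number of
  observations regardless of areal density. Distance ties break toward the
  smaller index, making every neighbourhood deterministic.
* **Kernels**: bi-square `(1 - (d/b)^2)^2` (compactly supported, the
  conventional choice for GW regression and the default everywhere),
  boxcar, and Gaussian. The focal unit always participates in its own
  calibration with weight 1.
* **Discrete neighbourhoods** for the exploratory statistics: binary k-NN
  (default k = 8, the queen-like lattice analogue), optionally
  row-standardized, with an include-self variant for Gi*. The hotspot and
  cluster statistics of desktop GIS tools do not document one canonical
  neighbourhood; k-NN with k = 8 is the package default and both k and the
  scheme are configurable.

The boxcar kernel at bandwidth n plays a special role: it reduces every GW
statistic to its global counterpart, and this global limit is the package's
primary correctness oracle (local coefficients, standard errors, R², AICc
and GW correlation are all tested against their global equivalents at
machine precision).

## Exploratory statistics

**Getis–Ord Gi\*** measures, per unit, how far the self-inclusive
neighbourhood sum of a field sits from its expectation under spatial
randomness, expressed as a z-score; inference is the analytic normal
approximation, matching the desktop-GIS convention, with classes at the
usual 90/95/99 % thresholds. The global standard deviation uses the
population form (divide by n), which is the convention under which the
z-score formula is exact. A constant field has S = 0 and raises a
degenerate-field error rather than returning NaNs.

**Bivariate local Moran's I** is `x̃_i · Σ_j w_ij ỹ_j` with
population-z-standardized variables and row-standardized weights; with
y = x it reduces exactly to the univariate local Moran's I (a tested
identity). Inference is by conditional permutation (hold `x̃_i`, permute ỹ
over the other n − 1 units) with a two-sided pseudo p-value and the +1
correction, the GeoDa convention; the permutation count defaults to 999
and clusters are assigned at α = 0.05 only when pseudo-p < α. The null
calibration of this procedure (rejection rate ≈ α under independence) is
exercised in the acceptance suite. Neither Gi* nor LMI applies a
multiple-testing correction across units by default, matching common
practice for these maps; p-values are returned so any correction can be
applied downstream.

**GW correlation** is the kernel-weighted Pearson correlation at each
unit, a model-free first look at non-stationarity. Units where either
local weighted variance vanishes are flagged undefined rather than
clipped.

## GW-OLS

At every location a weighted least-squares regression
`β(u_i) = (XᵀW_iX)⁻¹XᵀW_i y` is calibrated with the kernel weights centred
there. The implementation follows the standard GW regression inference
chain:

* **Effective number of parameters**: ENP = tr(S), with S the hat matrix
  assembled from the focal rows of each local projection. The hat matrix
  is built exactly (dense) — appropriate for the n ≤ a few thousand units
  this package targets.
* **Residual variance for standard errors**:
  `σ̂² = RSS / (n − 2 tr(S) + tr(SᵀS))`; per-coefficient variances come
  from `σ̂² (XᵀWX)⁻¹XᵀW²X(XᵀWX)⁻¹`.
* **Pseudo-t inference**: df = n − ENP. Because the local tests are
  correlated across space, adjusted p-values apply the dependent-test
  (Bonferroni-style) correction with m = ENP / p_model effective tests per
  coefficient surface: `p_adj = min(1, p_raw · m)`. In the global limit
  ENP = p_model and the adjustment vanishes.
* **Bandwidth selection**: corrected AIC,
  `AICc = 2n ln σ̂ + n ln 2π + n(n + tr S)/(n − 2 − tr S)` with
  `σ̂² = RSS/n`, minimized over the adaptive neighbour count either on an
  explicit grid or by golden-section search on `[p + 3, n]`. Golden
  section assumes a unimodal AICc profile — the standard working
  assumption; the full evaluation trace is returned so a flat or ragged
  profile can be inspected. `tr(S) ≥ n − 2` raises an
  ill-conditioned-bandwidth error.
* **Local R²** uses the focal kernel weights for both the residual and
  total sums of squares, the convention behind "local R²" maps; the global
  adjusted R² uses `1 − (1 − R²)(n − 1)/(n − ENP)`, which collapses to the
  OLS adjusted R² in the global limit.
* **Local VIFs**: each predictor regressed on the others with the focal
  weights; `VIF = 1/(1 − R²_w)`, values above 10⁶ flagged infinite. The
  conventional trouble threshold is 10.
* A reference full-scale configuration for county analyses — adaptive
  bi-square with 248 neighbours — ships in the documentation as the
  documented example bandwidth; at package scale the bandwidth is always
  re-selected by AICc.

Singular local designs (too few positively weighted points, or exact local
collinearity) abort naming the offending location; `on_singular = "drop"`
flags and skips instead.

## GW-RF

The geographically weighted random forest calibrates one regression forest
per location on its adaptive-bandwidth calibration set. Design choices:

* **Membership, not weights**: the calibration set is the focal unit plus
  its k − 1 nearest neighbours, unweighted — matching the cited GW-RF
  formulation in which the bandwidth defines membership. (A
  kernel-weighted bootstrap was considered and rejected as a default
  because it changes the meaning of OOB statistics.)
* **Forest engine**: CART-style variance-reduction trees via the
  randomForest package — bootstrap n with replacement, no depth limit,
  terminal node size 5, mtry defaulting to ⌊p/3⌋ for regression. The
  reference full-scale configuration (k = 284 neighbours, ntree = 2950,
  mtry = 4) is documented; package examples use ntree ≤ 500 and n ≤ 400,
  which preserve every tested property at a fraction of the cost (a
  3108-unit, 2950-tree GW-RF is hours of single-core compute).
* **Importance**: local %IncMSE is reported in the unscaled relative form
  — 100 × (mean per-tree OOB MSE increase under within-tree permutation) /
  forest OOB MSE — because a percent-scale measure is reproducible without
  the standard-error convention; the variance-scaled variant is returned
  alongside (`incmse_scaled`). IncNodePurity is the node-SSE decrease from
  splits on the variable, averaged over trees; it is nonnegative, while
  %IncMSE can legitimately go negative for noise predictors.
* **Local pseudo-R²** = 1 − OOB MSE / var(local y); undefined (flagged)
  where the local outcome is constant.
* **Determinism**: per-location seeds are a Lehmer-style hash of
  (master seed, location index), so importance surfaces are identical
  under any evaluation order; `force_global_seed = TRUE` exists solely to
  verify the k = n definitional limit against the global forest.
* **Ranking**: per location, predictors rank by local %IncMSE descending
  with exact ties resolved by input column order; the rank summary
  reports the share of units where each predictor is 1st/2nd/3rd.
* **Prediction**: the local prediction at a new point comes from the
  forest whose calibration location is nearest (ties to the lower id) and
  is blended with the global companion forest as
  `λ · local + (1 − λ) · global`. The default λ = 1 (purely local) is a
  package choice — the blending convention of published GW-RF software is
  configurable and not uniquely documented — and is exposed as
  `local_weight`.

Hyperparameter search is a random grid search over a candidate table,
scored by K-fold cross-validated MSE, with relative-improvement early
stopping (tolerance 0.001, 2 rounds by default — the tuning convention of
the reference configuration).

## Model comparison

`compare_models()` fits any subset of {OLS, RF, GW-OLS, GW-RF} on a seeded
train/test split (or K folds) and scores RMSE and R² on held-out data.
R² is reported as the squared Pearson correlation of observed and
predicted — the 1:1-plot convention, under which a cross-validated RMSE
close to the outcome scale can coexist with a high R² — and the strict
skill form `1 − SSE/SST` is emitted alongside as `r2_ss`, because the two
genuinely differ for biased predictions. Bandwidths and hyperparameters
are *not* re-selected inside folds unless requested: the default mirrors
the usual sequence of selecting once on the full data, and a nested
selection is available by passing a `NULL` bandwidth in the control list.
Test outcomes are never visible to any calibration (a sentinel test
poisons the held-out outcomes and asserts unchanged predictions).

## The synthetic generator and what passing tests mean

`synth_scenario()` fixes the package's reference study conditions: a
jittered lattice (jitter 0.3), spatially autocorrelated predictors
(Gaussian-kernel smoothing, length-scale 3 lattice units), pairwise
predictor correlation 0.4, outcome noise SD 0.5, and known coefficient
surfaces. These values were chosen once as a plausible stand-in for
county-scale risk-factor data: moderate predictor collinearity, regional
predictor structure, and signal-to-noise at which local models are
stressed but identifiable.

Two generator choices deserve emphasis:

* **Nugget component.** Predictor fields mix the smooth regional component
  with 30 % unsmoothed unit-level variance. Purely smooth fields are both
  unrealistic (areal socioeconomic surfaces always carry short-range
  variability on top of regional trends; typical nugget/sill ratios are
  0.2–0.5) and pathological for local regression: inside one bandwidth a
  purely smooth predictor is nearly constant, leaving local slopes
  unidentified no matter how small the noise.
* **Scaled-down effect sizes.** The `nonlinear` comparison scenario uses
  strong coefficient heterogeneity (gradients spanning −1.5 to 3, a
  central bump, a localized threshold regime and one interaction). At the
  package's reference sizes (400 units, 60-unit calibration sets) local
  forests pay a variance penalty that full-scale analyses (thousands of
  units, ~284-unit neighbourhoods) do not; for the qualitative ordering
  GW-RF ≥ RF and GW-OLS ≥ OLS to be expressible at desk scale, the
  spatial heterogeneity must dominate that penalty. This is standard
  scaled-down benchmark design: shrink n, grow the effect.

Passing tests therefore demonstrate that the estimators recover known
structure under these conditions; they do not certify behaviour on real
county data, whose noise is non-Gaussian, whose geometry is irregular, and
whose predictors are measured with error. The two-regime importance
recovery and gradient slope recovery are run across multiple seeds (9/10
and multi-seed spot checks) precisely to avoid certifying a knife-edge
configuration.

Reference problem sizes used by the test and acceptance workloads: n = 400
units for recovery and comparison scenarios, 100–225 for oracle and
calibration checks, GW-RF forests of 300 trees on 60-unit calibration
sets, and 199–999 permutations for LMI. These sizes keep the full suite in
the low minutes on one core while preserving every tested property.

## Numerical conventions and degenerate inputs

* Standardization inside Gi*/LMI uses the population standard deviation
  (divide by n), under which a checkerboard field standardizes to ±1 and
  the textbook identities hold exactly.
* Constant fields raise classed degenerate-field errors everywhere a
  variance appears in a denominator; constant outcomes in forests produce
  a warning, zero OOB MSE and all-zero importances.
* CSV output is written at 10 significant digits, making pipeline reruns
  byte-identical across runs on the same platform.
* k-NN and nearest-forest ties break toward the smaller index/id;
  importance ties break toward the earlier column. Every tie rule is
  deterministic and tested.
* All stochastic stages consume seeds derived from a single master seed
  via an integer hash kept below 2³¹.

## Known limitations

* Polygon contiguity (queen/rook from shapefiles) is out of scope; the
  supported neighbourhoods are centroid k-NN and distance-band kernels.
  GeoJSON polygons are reduced to mean-of-vertices centroids — a
  documented simplification, not an area-weighted centroid.
* The GW-OLS hat matrix is dense; memory is O(n²). This is comfortable to
  a few thousand units and intentional — the diagnostics (ENP, AICc,
  adjusted p) need the trace terms exactly.
* GW-RF local prediction uses the single nearest calibration forest;
  smoother alternatives (inverse-distance blending of several local
  forests) were left out to keep the prediction rule identical to the
  calibrated-locations semantics.
* Golden-section bandwidth search assumes unimodality; use grid mode when
  in doubt.
* No spatial-econometric error models, multiscale (per-coefficient)
  bandwidths, or survey-weighted upstream estimation: the package starts
  from a prepared areal table.
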