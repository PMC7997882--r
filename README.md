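# gwareal

Geographically weighted regression and random forests for areal health
data.

Disease prevalence aggregated over areal units — the motivating case is
county-level type 2 diabetes prevalence against socioeconomic and
lifestyle risk factors — is almost never governed by one spatially
constant relationship. `gwareal` is a toolkit for asking the local
questions: *where* is each risk factor most strongly associated with the
outcome, where do clusters of high and low prevalence sit, and how much
predictive skill is gained by letting the model vary over space?

The package implements, on a shared kernel-weighting core:

* **Exploratory local statistics** — Getis–Ord Gi\* hotspot z-scores with
  analytic normal inference; bivariate local Moran's I
  \(I_i = \tilde x_i \sum_j w_{ij} \tilde y_j\) with conditional-permutation
  pseudo p-values and HH/LL/HL/LH cluster classes; geographically weighted
  Pearson correlation.
* **GW-OLS** — a weighted least-squares regression
  \(\hat\beta(u_i) = (X^\top W_i X)^{-1} X^\top W_i y\) calibrated at every
  location with an adaptive bi-square kernel; bandwidth chosen by
  minimizing the corrected AIC
  \(\mathrm{AICc} = 2n\ln\hat\sigma + n\ln 2\pi + n\,\frac{n + \mathrm{tr}(S)}{n - 2 - \mathrm{tr}(S)}\);
  pseudo-t inference with dependent-test adjusted p-values and local VIFs.
* **GW-RF** — one regression forest per location on its k-nearest-neighbour
  calibration set, with local out-of-bag error, local pseudo-R², local
  permutation importance (%IncMSE) and node-purity importance surfaces,
  importance rank tables, partial dependence, and random-grid-search
  hyperparameter tuning with early stopping.
* **Evaluation** — seeded train/test and K-fold comparison of OLS, RF,
  GW-OLS and GW-RF by RMSE and R² (squared observed-vs-predicted
  correlation), with per-record prediction tables for 1:1 plots.
* **A synthetic areal-data generator** with known spatially varying
  coefficient surfaces, so every estimator can be tested against
  recoverable ground truth.

All user-facing functions take a data frame first and return tibbles;
results carry `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate 400 county-like units whose first slope rises west-to-east from
0 to 2, select the GW-OLS bandwidth by AICc, and fit:

```r
library(gwareal)

sc  <- synth_scenario("gradient", n_side = 20, noise_sd = 0.5, seed = 1)
sel <- select_bandwidth(sc$frame)
fit <- fit_gwols(sc$frame, kernel_spec("bisquare", adaptive = TRUE,
                                       bandwidth = sel$bandwidth))
fit
#> Geographically weighted OLS fit
#>   n = 400, kernel = bisquare, adaptive bandwidth = 82
#>   ENP = 32.33, AICc = 626.68, R2 = 0.864, adj. R2 = 0.853
#> Local coefficient quartiles:
#>         term     min      q1   median     q3    max
#>  (Intercept)  0.5372  0.8100  0.90841 1.0295 1.2955
#>           x1  0.2759  0.6897  1.02112 1.4393 2.0032
#>           x2 -1.0949 -0.5924 -0.01341 0.5222 0.8112

cor(fit$beta[, "x1"], as.numeric(sc$surfaces[[2]]))
#> [1] 0.939
```

The AICc search lands on an 82-neighbour bandwidth; the local `x1`
coefficients sweep 0.28–2.00 — tracking the true 0-to-2 gradient with
correlation 0.94 — while a global regression would report only their
average. The same data through the geographically weighted forest:

```r
gw <- fit_gwrf(sc$frame, k_neighbors = 60,
               params = rf_params(ntree = 300), seed = 1)
glance(gw)$mean_pseudo_r2
#> [1] 0.519
local_importance_ranking(gw)
#> # A tibble: 2 x 4
#>   predictor pct_rank1 pct_rank2 pct_rank3
#> 1 x1             67.5      32.5         0
#> 2 x2             32.5      67.5         0
```

`x1` is the top-ranked local predictor in 67.5 % of units — exactly the
east-side majority where its true coefficient is large. Hotspot and
cluster maps come from `getis_ord_gi_star()`, `bivariate_local_moran()`
and `plot_hotspots()`; the full stage sequence (exploratory → GW-OLS →
global RF with tuning → GW-RF → four-model comparison) runs from one
config via `run_pipeline()`, and `inst/cli/gwareal.R` exposes each stage
as a shell subcommand.

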