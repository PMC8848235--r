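# bloodbankr

Forecast-driven platelet inventory management for hospital blood banks.

Platelet concentrates expire four days after quality control, production
takes two days, and no fresh units arrive on Sundays or Mondays — so a
transfusion service must order against *predicted* demand, trading
outdating (wasted production, ~US$350/unit) against shortage (emergency
purchases, ~US$700/unit). `bloodbankr` implements that pipeline as a
tested, reproducible whole:

* **Synthetic data** — a calibrated generator for daily transfusion
  counts (negative binomial, multiplicative weekday profile, exponential
  secular trend, AR(1) autocorrelation) with census / planned-surgery /
  CBC covariate columns carrying planted correlations plus decoys.
* **Features** — zero imputation, sparsity and continuity filters, an
  `r² ≥ 0.2` correlation screen, the trailing 7-day demand mean (PL7),
  weekday dummies, and the forward 2-/4-day demand targets.
* **Forecasting** — LASSO (glmnet) and a self-contained LSTM network
  (BPTT, Adam, dropout, L1–L2 regularization, randomized hyperparameter
  search over a fixed space), both evaluated by rolling-origin
  recalibration (train 500 days, predict 28, refit, repeat) with 5-fold
  *blocked* cross-validation inside each training span, plus a
  trend-corrected augmented Dickey–Fuller stationarity check.
* **Metrics** — RMSE, r², MAPE with percentile-bootstrap 95% CIs and
  CI-derived p-values for model differences.
* **Inventory** — an exact integer simulator of shelf-life-stratified
  stock with FIFO issuance, the order-up-to rule
  `o = max(0, P + α − s − o_prev)` (2-day forecast Sun–Wed, 4-day on
  Thu, no orders Fri/Sat), and emergency purchases triggered at stock
  `≤ β` restoring level `γ`.
* **Policy** — total cost `c = 350·Σwaste + 700·Σpurchases` minimized by
  exhaustive grid search over `(α, β, γ) ∈ {0..30}³` (compiled inner
  loop; the full grid runs in seconds).

## Worked example

A complete study on a 1200-day synthetic series — generate data, build
features, run rolling-origin LASSO forecasts, optimize the inventory
policy, and compare against a constant-order baseline:

```r
library(bloodbankr)

cfg <- study_config(
  generator  = generator_config(n_days = 1200, seed = 20080101),
  models     = "lasso",
  alpha_range = 0:30,
  seed       = 1
)
bundle <- run_study(cfg, out_dir = "study_out")

bundle$metrics
#>   model horizon metric estimate  lower  upper
#>   lasso       2   rmse    4.203  3.979  4.451
#>   lasso       2     r2    0.561  0.513  0.603
#>   lasso       2   mape   21.730 20.258 23.381
#>   lasso       4   rmse    7.151  6.783  7.485
#>   lasso       4     r2    0.386  0.328  0.440
#>   lasso       4   mape   17.121 16.120 18.116
```

The 4-day horizon has *lower* relative error than the 2-day horizon —
summing four days smooths the percentage error even though the absolute
RMSE grows.

```r
bundle$comparison[, c("policy", "alpha", "waste_rate", "shortage_rate", "cost")]
#>     policy alpha waste_rate shortage_rate   cost
#>      lasso    10     0.0346       0.00851 103950
#>   baseline     0     0.0479       0.04464 276500
```

With its cost-optimal end-of-day stock target (`α = 10`, `β = γ = 0`:
purchase only what is missing, end the day empty), the forecast-driven
policy wastes 3.5% of transfused volume and covers 0.9% by emergency
purchase, versus 4.8% and 4.5% for a constant-order baseline matched to
mean demand — about a 60% cost reduction over the evaluation horizon.

```r
head(bundle$coefficients, 3)          # strongest LASSO predictors
#>     term mean_weight sd_weight prop_nonzero
#>   wd_fri      -8.232    0.2497            1
#>   wd_thu      -5.628    0.2129            1
#>   wd_sat      -2.973    0.0893            1
bundle$adf$statistic                  # trend-corrected ADF on the series
#> -6.38
```

Friday/Thursday/Saturday dummies carry large negative weights (orders
placed before the weekend face lower weekend demand), with PL7 and the
planted census/CBC covariates among the retained predictors.

Single pieces are available as plain functions on tibbles:
`simulate_platelet_series()`, `build_design_matrix()`,
`rolling_origin_forecast()`, `evaluate_forecasts()`, `step_day()`,
`run_simulation()`, `grid_search_policy()`; fitted objects support
`tidy()` / `glance()` and ledgers support `autoplot()`. A thin CLI with
`simulate-data` … `run-study` subcommands lives at
`inst/cli/platelet-study.R`.

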