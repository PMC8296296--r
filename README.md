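# tvpvarsv

Bayesian time-varying parameter vector autoregression with stochastic
volatility (TVP-VAR-SV) for short daily panels linking epidemic intensity,
urban mobility and air quality — the kind of three-variable system (newly
confirmed cases, subway passenger flow, daily mean PM2.5) used to study how
an epidemic and the activity restrictions it triggers move a city's air
pollution day by day.  Relationships like these shift rapidly with policy
(lockdown, reopening, partial quarantine), so a constant-coefficient VAR
misses exactly what matters; this package estimates the full time path of
the dynamics instead.

## The model

The structural VAR

```
A_t y_t = M_{1,t} y_{t-1} + ... + M_{s,t} y_{t-s} + mu_t
```

is estimated in its reduced form

```
y_t = X_t beta_t + A_t^{-1} Sigma_t eps_t,   eps_t ~ N(0, I_m),
X_t = I_m (x) (y_{t-1}', ..., y_{t-s}'),
```

where `A_t` is unit-lower-triangular (recursive identification),
`Sigma_t = diag(exp(h_{jt}/2))` carries stochastic volatilities
`h_{jt} = ln sigma_jt^2`, and the three state blocks — coefficients
`beta_t`, free elements `alpha_t` of `A_t`, and log-volatilities `h_t` —
all follow first-order random walks with diagonal innovation covariances.

Estimation is a block Gibbs sampler: exact forward-filtering
backward-sampling (FFBS) draws for `beta` and `alpha`, the 10-component
Gaussian-mixture approximation to `ln chi^2_1` plus FFBS for `h`, and
conjugate Gamma updates for the innovation precisions
(`beta` block: Gamma(40, 0.02); `alpha`, `h` blocks: Gamma(4, 0.02);
initial states N(0, 10I), N(0, 10I), N(0, 100I)).  Default run: 10,000
cycles, 1,000 burn-in.

Around the model sit the stages a real analysis needs: a synthetic-data
generator (both exact draws from the TVP-VAR-SV process with known latent
truth, and a realistic "study-like" scenario with two epidemic waves,
weekday mobility structure and seasonal PM2.5), chained-equations multiple
imputation, seasonal adjustment by previous-year monthly means, augmented
Dickey-Fuller screening with MacKinnon critical values and Schwert's lag
cap, MCMC diagnostics (Geweke CD, inefficiency factors, ACF), and
time-varying impulse responses reported either at fixed horizons over time
(1-day / 1-week / 2-week) or as full horizon profiles at chosen dates.

## Worked example

```r
library(tvpvarsv)

# 1. a study-like daily panel with known structure
inputs <- make_study_like_panel(study_scenario_config(seed = 42))
inputs$panel
#> <daily_panel> 242 days (2020-01-01 .. 2020-08-29), 3 series: new, pas, pek
#>   missing cells: 18 (2.5%)

# 2. impute gaps, subtract the 2019 monthly baselines
imp <- impute_missing(inputs$panel, seed = 42)
adj <- seasonal_adjust(imp$consensus, inputs$baseline)
describe(adj)
#>   variable   n    mean     min max     sd
#> 1      new 242    4.05   -3.94  33   7.51
#> 2      pas 242 -291.78 -897.52 120 245.46
#> 3      pek 242    4.72  -36.07  99  21.05

# 3. stationarity screen (three deterministic-term specifications)
adf_table(adj)
#>   variable deterministic statistic chosen_lag  pvalue stars
#> 1      new          none    -3.054          8 0.00223   ***
#> 2      new      constant    -3.603          8 0.00570   ***
#> 3      new         trend    -3.971          8 0.00967   ***
#> 4      pas          none    -0.805         13 0.36847
#> ...

# 4. fit the TVP-VAR-SV (reduced "fast" profile; use the 10,000/1,000
#    default for final inference)
spec <- model_spec(3, 1, c("new", "pas", "pek"))
draws <- run_mcmc(adj, spec, config = mcmc_config(2000, 200, seed = 42))
diagnose(draws)
#> <tvpvar_diagnostics>
#>   beta_mid           mean   0.4923  sd  0.1439  Geweke CD   0.35  IF   1.05
#>   h_mid              mean  -1.6138  sd  0.7711  Geweke CD   7.01  IF   6.22
#>   ...

# 5. time-varying impulse responses: response of PM2.5 to a one-sd
#    epidemic shock, traced at the 1-day horizon across the year
surf <- tv_irf(draws, H = 14)
head(equal_interval_slices(surf, shock = "new", response = "pek",
                           horizons = c(1, 7, 14)), 3)
#>         date horizon value
#> 1 2020-01-02       1 0.182
#> 2 2020-01-03       1 0.181
#> 3 2020-01-04       1 0.180
```

The descriptives table gives each adjusted series' N, mean, min, max and
sample standard deviation; the ADF rows report the unit-root t-statistic,
the AIC-chosen augmentation lag and the MacKinnon p-value (stars: 1/5/10%).
In the diagnostics, Geweke CD is asymptotically N(0,1) for a converged
chain — the large values on the volatility scalars above are what the
reduced profile looks like before convergence, and shrink under the full
profile.  The IRF slice is the posterior-mean response (in the response
variable's units per one-standard-deviation shock) at a fixed horizon, as
a function of the date the shock occurs.

`run_pipeline(pipeline_config(...))` chains all stages and writes the
tables, IRF surfaces and a manifest as CSV/JSON;
`inst/scripts/tvpvar-pipeline.R` is a command-line wrapper.

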