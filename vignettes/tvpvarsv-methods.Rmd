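---
title: "Methods: the TVP-VAR-SV pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TVP-VAR-SV pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model, the estimation machinery, the numerical
choices, and the points where the design was genuinely open and a decision
had to be made.  It is the reference for anyone auditing or extending the
package.

## The model

For an $m$-variable daily panel $y_t$ the structural system is
$$A_t y_t = M_{1,t}\, y_{t-1} + \dots + M_{s,t}\, y_{t-s} + \mu_t ,$$
rewritten in reduced form as
$$y_t = X_t \beta_t + A_t^{-1} \Sigma_t \varepsilon_t,
  \qquad \varepsilon_t \sim N(0, I_m), \qquad
  X_t = I_m \otimes (y_{t-1}', \dots, y_{t-s}'),$$
with $B_{i,t} = A_t^{-1} M_{i,t}$ stacked row-wise into
$\beta_t \in \mathbb{R}^{m^2 s}$.  $A_t$ is unit-lower-triangular, so the
structural shocks are orthogonalized recursively and the identification
depends on the variable ordering.  $\Sigma_t = \mathrm{diag}(e^{h_{jt}/2})$
holds the stochastic volatilities, $h_{jt} = \ln \sigma^2_{jt}$.

All three state blocks drift as first-order random walks,
$$\beta_{t+1} = \beta_t + u_{\beta t}, \quad
  \alpha_{t+1} = \alpha_t + u_{\alpha t}, \quad
  h_{t+1} = h_t + u_{h t},$$
with mutually independent Gaussian innovations and *diagonal* innovation
covariances ($\alpha_t$ stacks the free below-diagonal entries of $A_t$
row-major).  The random-walk form deliberately permits permanent shifts —
the point of the model class is to let lockdown-era dynamics differ from
reopening-era dynamics without specifying break dates.

**Assumptions worth stating plainly.**  Shocks are conditionally Gaussian;
identification is recursive in the given variable ordering; the state
innovations are independent across elements; and the observation equation
is linear in the lagged levels.  None of these are testable from a single
short panel, which is why the package ships a generator that can produce
data *exactly* from this process.

## Priors and their scale

Following standard practice for this model family, the initial states are
$\beta_{s+1} \sim N(0, 10 I)$, $\alpha_{s+1} \sim N(0, 10 I)$,
$h_{s+1} \sim N(0, 100 I)$ — diffuse on the scale of daily data that has
been seasonally adjusted (so levels are anchored near zero).  Each diagonal
state-innovation *precision* $(\Sigma_x)_i^{-2}$ has an independent Gamma
prior: shape 40, rate 0.02 for the $\beta$ block and shape 4, rate 0.02
for the $\alpha$ and $h$ blocks.  Two readings of this specification were
possible and we fixed them as package policy:

* **Shape–rate convention.**  Gamma(40, 0.02) is read as shape 40,
  *rate* 0.02, giving prior-mean precision $2000$, i.e. a per-day
  innovation standard deviation of about $0.022$ for each coefficient —
  tight enough that coefficient paths move slowly, loose enough to track
  regime shifts over weeks.  The shape-scale reading would give absurdly
  large innovation variances for daily data.
* **Precisions, not variances.**  The $-2$ exponent in the conventional
  notation refers to inverse *squared* scales, so the Gamma prior sits on
  the precision of the innovation standard deviation; the conjugate update
  is then Gamma(shape $+ (T_\mathrm{eff}-1)/2$, rate
  $+ \tfrac12 \sum_t \Delta^2$).

## The Gibbs sampler

One cycle updates, in order, $\beta \rightarrow \alpha \rightarrow h
\rightarrow$ innovation variances; states are initialized at their prior
means (zeros) and variances at the Gamma-prior means.  The order and
initialization are unexciting by design: any fixed order is valid for a
Gibbs sampler, and the package exposes each block separately
(`sample_beta()`, `sample_alpha()`, `sample_h()`, `sample_variances()`)
precisely so each conditional can be tested against an oracle.

* **Coefficients.**  Given $(\alpha, h)$, premultiplying the observation
  equation by $A_t$ yields independent Gaussian errors with variances
  $e^{h_{jt}}$, so the $\beta$ path is drawn exactly by a covariance-form
  Kalman filter with sequential scalar updates followed by backward
  sampling (FFBS).
* **Contemporaneous relations.**  With $\hat y_t = y_t - X_t\beta_t$, row
  $j$ of $A_t \hat y_t = \Sigma_t \varepsilon_t$ makes $\hat y_{jt}$ a
  regression on $-\hat y_{1..j-1,t}$ with noise variance $e^{h_{jt}}$ —
  again a linear-Gaussian state space in the stacked $\alpha_t$, drawn by
  the same FFBS kernel.
* **Volatilities.**  $\ln(e_{jt}^2 + c)$ linearizes the SV observation;
  the distribution of $\ln \varepsilon^2$ is approximated by the
  10-component Gaussian mixture refinement of the classic 7-component
  mixture, whose component indicators are drawn given the current path and
  whose conditional model is again linear-Gaussian.  The 10-component
  version was preferred for its better tail behaviour; the approximation's
  mean ($\approx -1.2704$) and variance ($\pi^2/2$) are verified in the
  test suite.  The offset is $c = 10^{-6}$, applied after standardizing
  each residual series to unit sample variance (the sampled path is then
  shifted back by the same constant), so the offset's distortion is
  scale-free.
* **Variances.**  Conjugate Gamma draws per diagonal element.

Numerical policy inside the filter: the state covariance is re-symmetrized
after every update; Cholesky factorizations retry with jitter starting at
$10^{-10}$ and fail loudly (naming the cycle and block) rather than
silently truncating — a loss of positive definiteness signals misuse, not
something to paper over.  Draws use R's RNG stream, so a single
`set.seed()` reproduces an entire run bit-for-bit.

Explosive coefficient draws are *not* rejected; the companion-matrix
spectral radius of each retained draw (at its time-averaged coefficients)
is logged instead, leaving truncation decisions to the analyst.

## Stationarity screening

Each adjusted series is screened by augmented Dickey–Fuller regressions
under three deterministic-term specifications — none, constant, constant
plus trend — matching the three-column layout conventional in applied
tables ("without constant and drift", "with drift", "with constant and
drift").  The augmentation cap follows Schwert's rule
$\lfloor 12 (T/100)^{1/4} \rfloor$, which is 14 at $T = 242$; the order
itself is chosen by AIC over $0..\text{cap}$ on a common sample (a
fixed-lag mode exists for oracle testing, where the lag-0 statistic must
equal a hand-computed OLS t-ratio).  P-values use the MacKinnon (1994)
response-surface polynomials and the 1/5/10% critical values the MacKinnon
(2010) surfaces, both for a single I(1) series.  The implementation was
cross-validated against an independent reference implementation to
$10^{-6}$ on seeded series (frozen in the test suite), and its size and
power at $T = 242$ are measured by Monte Carlo in the acceptance checks.

## Preprocessing

**Multiple imputation.**  Missing cells are filled by chained-equations
MI: each incomplete variable is regressed (Bayesian linear regression with
a weak ridge, error variance drawn from its inverse-gamma conditional,
coefficients from their Gaussian conditional) on a scaled day index,
day-of-week indicators, month indicators, and the other series' same-day
values; ten sweeps per copy, five copies, and the cell-wise mean of the
copies — the consensus panel — feeds the model.  Pooling across
imputations beyond the consensus (Rubin's rules) is intentionally out of
scope: the downstream model consumes one analysis series.  Observed cells
are never modified, which the tests assert cell-wise.

**Seasonal adjustment.**  Each daily value has the *previous year's* mean
for the same variable and calendar month subtracted.  For the epidemic
count series the baseline is defined as zero in every month — no previous
year of the epidemic existed, and a zero baseline keeps counts integral
with a minimum of zero.  This is a genuine judgment call (one could argue
for excluding the series from adjustment altogether; the two choices
coincide).

**Study window.**  The canonical window is 2020-01-01 to 2020-08-29
inclusive — 242 days in a leap year.  An end date of 30 August would give
243 and is rejected by the $N = 242$ bookkeeping used throughout.

## Impulse responses

`irf_at()` freezes the states at their time-$t$ values, forms
$\psi_0 = A_t^{-1}\,\mathrm{diag}(s)$ and iterates
$\psi_k = \sum_{i \le \min(k,s)} B_i \psi_{k-i}$.  Freezing (rather than
integrating over future state evolution) is the standard reporting
convention for this model family and keeps a response at date $t$
interpretable as "the dynamics as they stood on day $t$".  The surface is
the posterior *mean* over retained draws of these per-draw, per-date
responses; 16–84% bands are computed from an evenly thinned subset of
draws (default 200) to bound memory.

The shock is one standard deviation.  Two conventions are offered for
what "one standard deviation" means: the default `average_volatility`
uses each series' posterior time-average of $e^{h_{jt}/2}$, making
responses comparable across dates (variation in the surface then reflects
coefficient changes, not volatility changes); `time_t_volatility` uses the
date-specific volatility.  "One-day horizon" means horizon index 1 —
impact day is horizon 0 — and the default horizon cap is 14 days, the
longest horizon the package's reporting modes use, configurable with a
memory guard.

Equal-interval reporting extracts horizons {1, 7, 14} (short/mid/long
term) as functions of the shock date; time-point reporting extracts full
horizon profiles at chosen dates (defaults: 22 January, 30 March,
17 June 2020 — first outbreak, inter-wave lull, second outbreak).

## The synthetic-data generator

Two generators serve two different purposes.

`simulate_tvpvar()` draws *exactly* from the model: random-walk state
paths with user-set innovation scales, then observations satisfying the
observation equation given those states, returned together with the true
paths.  With all innovation scales zero it degenerates to a
constant-parameter homoskedastic VAR, which the tests exploit
(Yule–Walker variance checks, constant-truth recovery).

`make_study_like_panel()` emulates the *shape* of the study's raw data:
Poisson counts around two Gaussian-shaped epidemic waves (peaks in early
February and mid-June, peak intensities 25 and 20 cases/day, widths 10 and
7 days), subway flow in thousand trips with a weekday/weekend swing of 250,
a logistic collapse of ~750 at late January with slow recovery and a
second dip at the June wave, positive PM2.5 with a winter-over-summer
level difference of 30 µg/m³ and right-skewed noise, 2% sporadic
missingness, and the matching 2019 monthly baselines (zero for the
epidemic series).  One master seed drives independent named substreams per
series, so adding a series never perturbs the others.  These values were
fixed once, at design time, to magnitudes a scientist would call
plausible for a large city's 2020; they are *not* calibrated to any
published table.

What the study-like generator does **not** emulate: epidemic mechanics
(no SEIR structure), weather confounding of PM2.5, holiday calendars, or
reporting artifacts (batch corrections, zero-inflation by weekday).
Passing tests on these data therefore demonstrate that the pipeline's
*mechanics* are correct under realistic magnitudes — not that the model is
adequate for any particular real dataset.

## What the tests and acceptance checks compute

Problem sizes were chosen so the whole suite runs in minutes on one core:
smoother-vs-dense-Gaussian oracles at $T = 30$, IRF companion-matrix
oracles over 100 random stable systems, full-sampler recovery at
$T = 300$ with the reduced profile (2,000 cycles, 200 burn-in; the
"full" profile of 10,000/1,000 remains the analysis default),
volatility-path recovery at $T = 800$, ADF size/power with 2,000 Monte
Carlo replicates at $T = 242$.  The credible-interval calibration check
draws each replicate's innovation variances from their Gamma hyperpriors
(the standard Bayesian-calibration design), which makes the nominal 90%
coverage the correct target for a correct sampler; with exactly-constant
truth instead, the informative innovation prior keeps interval widths at
prior scale and pointwise coverage saturates near 0.99 no matter how
correct the sampler is — which is why the constant-truth check is a
pointwise-error check, not a coverage check.

## Known limitations

* Recursive identification only; responses depend on the variable
  ordering, which is configurable but must be defended scientifically.
* Single chain (matching the usual practice for this sampler); the Geweke
  and inefficiency diagnostics are the convergence evidence, and the fast
  profile visibly under-converges the volatility block — use the full
  profile for inference.
* The imputation model is Gaussian; count series are imputed on the real
  line (acceptable at the daily scale used here, wrong for rare counts).
* No marginal likelihood / lag-order machinery beyond information-criteria
  screening; the pipeline default is one lag.
* Innovation covariances are diagonal by construction, ruling out
  correlated drift between coefficients.
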