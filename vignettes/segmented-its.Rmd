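---
title: "Segmented regression for interrupted time series: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented regression for interrupted time series: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segits)
```

## The design and the model

An interrupted time series (ITS) design observes one unit's continuous
outcome at times $T_1 < T_2 < \dots < T_N$, with an intervention introduced
at a known time $\delta$. The `segits` model is the standard four-parameter
segmented regression: a straight line in each period, with the
post-intervention indicator $X_t = \mathbf{1}\{T \ge \delta\}$.

Two parametrizations of the interaction term are in wide use, and `segits`
implements both:

$$y_t = \beta_0 + \beta_1 T + \beta_2^{B} X_t + \beta_3 X_t T
\qquad\text{and}\qquad
y_t = \beta_0 + \beta_1 T + \beta_2^{W} X_t + \beta_3 X_t (T - \delta).$$

They describe the same pair of pre/post lines — fitted values and residuals
are identical — but $\beta_2$ means different things: the vertical gap
between the lines at $T = 0$ (difference in intercepts) in the first, and
the gap at $T = \delta$ (the immediate effect) in the second. The two are
linked by $\beta_2^{W} = \beta_2^{B} + \beta_3\delta$, which
`convert_parametrization()` applies to both the coefficients and the
covariance (as $J \hat\Sigma J^\top$ with $J$ the identity plus
$\pm\delta$ in position (3, 4)). The six-row effect table produced by
`its_effects()` is therefore numerically identical whichever
parametrization was fitted; only the mapping from table rows to raw
coefficients changes.

Assumptions: a single series; linear mean in each period; an abrupt switch
at a single, known $\delta$; homoskedastic, uncorrelated Gaussian-like
errors. Autocorrelation, seasonality, transition/lag periods, comparison
series and non-Gaussian outcomes are out of scope; for monthly public
health series autocorrelation in particular can make the reported standard
errors optimistic, and users needing those corrections should fit the same
design matrices with GLS/Newey–West machinery elsewhere.

## Conventions that matter

* **Boundary**: an observation at exactly $T = \delta$ is
  *post*-intervention ($X_t = 1$ for $T \ge \delta$). Applied datasets often
  code the first post month at $\delta$, so this is stated rather than
  assumed.
* **Time origin**: times are used as given; $\beta_0$ is always "level at
  $T = 0$", so its meaning depends on the analyst's origin.
  `reorigin = TRUE` shifts the series so the first observation is at 0. For
  the classic Sicily smoking-ban series we adopt months coded $0..57$ with
  $\delta = 36$, so the baseline is the January 2002 level; other codings
  are accepted, they just move the meaning of $\beta_0$.
* **Spacing**: arbitrary, possibly unequal spacing is accepted; the
  closed-form estimators are valid for any spacing. Duplicate times are
  rejected — they suggest panel data, which is a different design.
* Each segment must contain at least two distinct times and $N - 4 \ge 1$,
  so the model is identifiable with positive residual degrees of freedom.

## Estimation

`its_fit()` defaults to the closed-form path. Because the design matrix is
block-structured, the four coefficients reduce to segment-wise
simple-regression algebra on the per-segment sums
($\sum t$, $\sum t^2$, $\sum y$, $\sum ty$; see `segment_summaries()`):
$\hat\beta_0, \hat\beta_1$ from the pre-segment alone,
$\hat\beta_3 = \hat\beta_{3,\text{post}} - \hat\beta_1$ with
$\hat\beta_{3,\text{post}}$ the post-segment slope, and
$\hat\beta_2^{B} = \hat\beta_{2,\text{post}}^{B} - \hat\beta_0$ from the
segment intercepts, with $\hat\beta_2^{W} = \hat\beta_2^{B} +
\delta\hat\beta_3$. Coefficient variances use the matching closed forms in
$\hat\sigma^2 = \text{RSS}/(N-4)$ and the centered sums of squares of times.

Numerical choices:

* The matrix path (`fit_ols_matrix()`) solves the normal equations through
  a QR decomposition of the design matrix (pivoting respected when forming
  $(X^\top X)^{-1}$), not an explicit inverse.
* The closed-form result is cross-checked against the matrix solution at
  **1e−8 relative** on every call; a discrepancy raises an
  internal-consistency error rather than returning silently. The printed
  closed-form variances thus act as a redundant check of the covariance
  diagonal.
* Off-diagonal covariances have no compact printed form; `segits` takes
  them from the full $\hat\sigma^2 (X^\top X)^{-1}$, which is exact and
  general. They are required for standard errors of linear combinations
  — the immediate effect under the time-interaction parametrization
  ($w = (0,0,1,\delta)$), the intercept difference under the other
  ($w = (0,0,1,-\delta)$), and the post-intervention trend
  ($w = (0,1,0,1)$) — via $\sqrt{w^\top \hat\Sigma w}$
  (`linear_combination_se()`).
* $p = 4$ always; no adjustment options. Degrees of freedom for the
  two-sided $t$ tests are $N - 4$, the standard OLS choice for this
  small-sample setting (the model is fixed, so no alternative df is
  defensible). No multiple-testing adjustment is applied: the six rows are
  descriptive summaries of one fitted model, not a family of hypotheses.
* Exact fits ($\hat\sigma^2 = 0$) report zero standard errors and an
  `exact_fit` flag with `NA` p-values — a $t$ statistic is undefined there,
  and reporting $p = 0$ would be wrong.
* Times of very large magnitude (|T| > 1e6) trigger a conditioning warning
  suggesting `reorigin = TRUE`.
* `its_fit_from_coef()` rebuilds a fit object from published coefficient
  values so the effect/translation machinery can be applied to reported
  results; without a covariance the inference columns are `NA` rather than
  fabricated.

## What the synthetic generator emulates

`its_sim_spec()` + `simulate_its()` generate a two-segment linear mean with
iid Gaussian noise — exactly the process under which the OLS derivations
are exact. Defaults are a unit-spaced grid $0..m+n-1$ with $\delta = m$,
mirroring monthly series with the intervention at the first post month (the
Sicily design is $m = 36$, $n = 22$). The generator does **not** emulate
autocorrelation, seasonality, heteroskedasticity, heavy tails, or gradual
intervention uptake; passing Monte Carlo checks therefore validates the
estimators and their standard errors *under the model's own assumptions*,
not robustness to real-data violations of them.

`its_recovery()` fits every replicate under both parametrizations, asserts
the translation identity replicate-by-replicate, and reports bias,
empirical SD vs mean analytic SE, and 95 % $t$-interval coverage per
coefficient and for the immediate effect. Replicate seeds are pre-drawn
from the root seed, making individual replicates reproducible independent
of evaluation order. The package's own validation (see
`tests/testthat/test-acceptance.R`) uses 2000 replicates at $m = n = 30$,
$\sigma = 1$ with a true pure level change of 1 — sizes chosen so the
Monte Carlo error bands (3 MC standard errors for bias, 5 % relative for SE
calibration, binomial error for coverage) are meaningful while the run
stays in the tens of seconds.

## Design choices where the design was open

* **Noise model**: iid Gaussian, matching the homoskedastic uncorrelated
  error assumption behind the closed-form variances; AR(1) noise is
  deliberately excluded (it belongs with the out-of-scope corrections).
* **Default parametrization for simulation specs** is the
  time-since-intervention form, because its $\beta_2$ is directly the
  immediate effect — the quantity a simulation designer usually wants to
  set. Specs translated through the identity generate identical data under
  the same seed.
* **CLI default** fits both parametrizations and verifies
  $\hat\beta_2^{W} = \hat\beta_2^{B} + \delta\hat\beta_3$ at runtime,
  surfacing the core identity in every run; diagnostics go to stderr, the
  machine-readable report to file only.
* **Reporting precision**: full precision internally; rendered reports
  default to 4 significant digits with a `--digits` option.
* **CSV dialect**: comma-separated, header required, `.` decimal, UTF-8; no
  locale handling. Rows with missing outcomes are dropped with a logged
  count. When a 0/1 indicator column is supplied instead of $\delta$, the
  intervention time is inferred as the earliest indicator-1 time and the
  indicator is required to be consistent with the $T \ge \delta$ rule
  (non-monotone indicators are an error, not silently repaired).

## The misinterpretation guard, concretely

```{r}
t <- 0:5
d <- new_its_data(t, ifelse(t < 3, t, 2 * t - 3), delta = 3)
f <- its_fit(d, "bernal")
immediate_effect(f)$estimate        # 0: the lines meet at delta
difference_in_intercepts(f)$estimate # -3: the gap at T = 0
```

Whenever the slope changes ($\beta_3 \neq 0$) and $\delta \neq 0$, these
two quantities differ — here maximally so. Reading the raw $\beta_2$ of the
time-interaction parametrization as "the level change at the intervention"
conflates them.

## Known limitations

Plain OLS standard errors (no HAC/GLS correction); single series; no
covariates beyond the three model terms; no date/calendar handling; no
confidence intervals for relative (percentage) effects. Comparisons with
published analyses of real monthly series are contingent on the plain-OLS
choice: analyses that adjusted for seasonality or autocorrelation will
report different standard errors for the same point estimates.
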