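---
title: "The half logistic-truncated exponential model: methods and design notes"
author: "hltexp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The half logistic-truncated exponential model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hltexp)
```

## The model

Many lifetime samples only make sense above a threshold: a fatigue test
cannot fail before the first recorded cycle fraction, a bearing cannot fail
at zero revolutions. The half logistic-truncated exponential distribution
(HL-TEXPD) addresses this with a two-parameter law on $[a, \infty)$,

$$g(x) = \frac{2\theta e^{-\theta(x-a)}}{\{1+e^{-\theta(x-a)}\}^2},
\qquad
G(x) = \frac{1-e^{-\theta(x-a)}}{1+e^{-\theta(x-a)}},$$

with threshold $a$ (data units) and rate $\theta > 0$ (inverse data
units). It is constructed by a truncated-family composition: take a base
distribution left-truncated at $\tau$, form its cumulative hazard
$H(x) = -\log\{1 - F(x \mid x > \tau)\}$, and evaluate a nonnegative
"generator" cdf $R$ there, giving $G = R \circ H$ with density
$g(x) = r\{H(x)\}\,f(x)/\{1-F(x)\}$. With an exponential base the
composition collapses to the scale-location form
$g(x) = \theta\, r\{\theta(x-a)\}$; with a half-logistic generator that
yields the HL-TEXPD, mathematically a location-shifted half-logistic law.
The `family.R` constructors expose this machinery
(`truncated_exponential_base()`, `half_logistic_generator()`,
`composed_pdf()`, …) so the closed forms in `dhltexp()`/`phltexp()` can be
cross-checked against the general composition; no other named generator is
registered.

One printing slip in the source construction is worth stating once: the
exponential base cdf appears in the literature version of this derivation
with a spurious rate factor ("$1-\theta e^{-\theta x}$"). Only the
standard cdf $1-e^{-\theta x}$ is consistent with the HL-TEXPD
density/cdf pair above, and that is what the package implements; it is not
configurable.

### Properties used by the package

* **Hazard.** $h(t) = \theta/\{1+e^{-\theta(t-a)}\}$ increases
  monotonically from $\theta/2$ at the threshold to the asymptote
  $\theta$: the model suits increasing-failure-rate data and cannot
  represent decreasing or bathtub rates.
* **Quantiles.** $x_p = a + \log\{(1+p)/(1-p)\}/\theta$. The printed
  percentile formula in the source places the exponent ambiguously; this
  reading is the unique one satisfying $G(x_p) = p$, verified in the test
  suite against a bisection inverse of the cdf.
* **Moments.** $E(X^p) = 2\int_0^\infty (a+u/\theta)^p
  e^{-u}(1+e^{-u})^{-2}\,du$. For the standard variable
  $U = \theta(X-a)$, $E(U^k) = 2\,k!\,\eta(k)$ with $\eta$ the Dirichlet
  eta function, giving mean $a + \log(4)/\theta$, variance
  $(\pi^2 - 3\log^2 4)/(3\theta^2) \approx 1.368/\theta^2$, and
  parameter-free skewness $\approx 1.5397$ and (non-excess) kurtosis
  $\approx 6.584$ — the family is location-scale, so shape does not depend
  on $(a, \theta)$. The published closed forms for the third and fourth
  raw moments omit their $a$-free terms (as printed, the third raw moment
  vanishes at $a = 0$, contradicting $E(U^3) = 9\zeta(3)$); the package
  trusts the integral definition and the eta-series identity, which agree
  to quadrature accuracy.
* **Entropy.** Direct integration of $-\int g \log g$ gives
  $2 - \log 2 - \log\theta$ nats. The published constant $1.6989$ equals
  $2 - \log_{10} 2$: the derivation mixes decimal and natural logarithms.
  `hltexp_entropy()` returns the natural-log value, which is the one that
  matches numeric quadrature (checked to $10^{-6}$).

## Estimation

For data $x_1,\dots,x_n$ the log-likelihood is
$$\ell(a,\theta) = n\log 2 + n\log\theta - \theta\sum(x_i-a)
  - 2\sum\log\{1+e^{-\theta(x_i-a)}\}.$$
$\ell$ is increasing in $a$ on the feasible region $a \le \min x_i$, so
the MLE of the threshold is the sample minimum, $\hat a = \min x_i$ — an
order statistic, not an interior optimum. Observations equal to the
minimum then contribute $d_i = 0$ terms, which are finite; no jittering is
applied. The rate solves the score equation
$$n/\theta - \sum d_i + 2\sum \frac{d_i e^{-\theta d_i}}
  {1+e^{-\theta d_i}} = 0,$$
which is strictly decreasing in $\theta$ from $+\infty$ to
$-\sum d_i < 0$: the root is unique. `fit_hltexp()` brackets it starting
from the moment initialiser $\theta_0 = \log(4)/(\bar x - \hat a)$
(inverting the mean formula), expanding the bracket geometrically by
factors of 10 until the score changes sign, then calls `stats::uniroot()`
at relative tolerance $10^{-10}$.

**Standard errors** are observed-information based:
$\mathrm{SE}(\hat\theta) = \{-\ell''(\hat\theta)\}^{-1/2}$ with the
analytic second derivative. Whether the published standard errors were
observed- or expected-information based is not stated there; observed
information reproduces the published 0.070 (Kevlar) and 0.083 (guinea
pigs) at printed precision, which settles the choice for this package.
No standard error is attached to $\hat a$: minima of samples are not
asymptotically normal.

**Model comparison** uses $\mathrm{AIC} = 2k - 2\ell$ and
$\mathrm{BIC} = k\log n - 2\ell$ with $k = 1$ for the HL-TEXPD and the
truncated-exponential baseline (the rate is the only free parameter; the
threshold is pinned to an order statistic). This is the only convention
consistent with the published tables — e.g. $247.35 = 2 + 2 \times 122.675$
and $229.83 = \log 23 + 2 \times 113.345$. One published BIC (205.33 for
the guinea-pig fit) is inconsistent with the definition, which gives
209.33; the package always computes BIC from the definition. The
exponential baseline uses its closed-form MLE $n/\sum x_i$, the truncated
exponential $\hat a = \min x_i$ and rate $n/\sum(x_i - \hat a)$.

```{r}
compare_models(load_dataset("bearings23")$values)
```

## The Monte-Carlo design

`run_sim_cell()` emulates the estimator's operating conditions: `reps`
samples of size $n$ drawn by inverse transform
(`qhltexp(runif(n), a, theta)` under R's Mersenne-Twister, seedable and
reproducible), each refitted exactly as real data are fitted — including
re-estimating $\hat a$ as the per-replicate minimum. The defaults mirror
the published design: $\theta \in \{0.5, 0.3, 0.05\}$,
$n \in \{20, 50, 100, 200\}$, 1000 replicates per cell, nominal 99%
intervals. The true threshold is fixed at $a = 0$; the source study never
states it, and re-estimating the minimum each replicate is what reproduces
the positive small-sample bias pattern of its table (at
$\theta = 0.5, n = 200$ the average estimate here is $\approx 0.505$
against a published 0.50456).

Aggregation per cell: bias $= \mathrm{mean}(\hat\theta) - \theta$;
MSE $= \mathrm{mean}\{(\hat\theta-\theta)^2\}$, which identically equals
empirical variance plus squared bias; MRE
$= \mathrm{mean}(|\hat\theta-\theta|/\theta)$ — the absolute value is
deliberate: without it the printed MRE magnitudes
($\approx 0.798\,\mathrm{RMSE}/\theta$, the mean absolute deviation of a
near-normal estimator) are unobtainable. Coverage is the fraction of
per-replicate Wald intervals
$\hat\theta \pm z_{\varepsilon/2}\,\mathrm{SE}(\hat\theta)$ containing the
truth. The source's printed interval formula divides the standard error
by $\sqrt{1000}$; an interval that narrow cannot produce its own printed
coverage values (24%–99% for a nominal 99%), so the standard Wald
construction is used instead and coverage at $n = 200$ is asserted only
to lie in $[0.95, 1]$. The printed per-cell "(S.E.)" column (values like
0.00001) matches no standard estimator-summary definition and is not
reproduced. Per-cell seeds in `run_sim_grid()` are drawn once from the
master seed via `sample.int()`, so grids are byte-reproducible.

What the generator does *not* emulate: censoring, ties from coarse
measurement rounding, covariates, or model misspecification. A passing
simulation therefore certifies the estimator under its own model, not
robustness on real data.

## Descriptive conventions

`describe_sample()` uses linear-interpolation quantiles with plotting
position $(k-1)/(n-1)$ (R's default type 7), standard deviation with the
$n-1$ denominator, and moment-ratio shape statistics
$m_3/m_2^{3/2}$ and $m_4/m_2^2$ (kurtosis non-excess, no small-sample
correction) with $m_k = n^{-1}\sum(x_i-\bar x)^k$. These conventions
reproduce every cell of the published descriptive tables for the three
bundled datasets to one unit in the last printed digit; the tables
demonstrably mix rounding with truncation (their 1.979 skewness cell is
the truncation of 1.9796, their 37.479 SD cell of 37.4795), which is why
the test suite asserts full-ulp rather than half-ulp agreement with
printed figures.

The three bundled samples are stored verbatim to full printed precision,
including two places where the printed listings drop a comma between
adjacent values (read as separate values, restoring the stated sample
sizes of 72 and 23) and one value (48.80) that differs from some
historical versions of the ball-bearing data; the printed listings are
canonical here, with no typo correction. The Kevlar minimum is kept as
listed, 0.0251, although the fitted-threshold tables print it as 0.025.

## Diagnostics

`ttt_curve()` implements the scaled total-time-on-test transform
$T_i = \{\sum_{j\le i} x_{(j)} + (n-i)x_{(i)}\}/\sum_j x_{(j)}$ against
$u_i = i/n$, with $T_0 = 0$: concave curves indicate increasing failure
rate, the diagonal a constant rate. The source figures never print the
formula; this is the standard transform. Plotting positions follow common
defaults — $i/n$ for the empirical cdf and P-P pairs, $(i-0.5)/n$ for Q-Q
— since the corresponding figures are qualitative. Rendering is left to
the user (the tested artifact is the numeric series); no shape
classification into bathtub categories is attempted.

```{r}
head(ttt_curve(load_dataset("bearings23")$values))
```

## Numerical choices

* Quadrature (`hltexp_moment()`, and the unit-mass and entropy checks)
  uses `stats::integrate()`; the moment integrand $\sim u^p e^{-u}$ is
  integrated on $[0, 40 + 10p]$, where the truncated tail is below
  $10^{-12}$.
* Densities and cdfs evaluate $e^{-\theta(x-a)}$ once; the survival
  function is computed directly as $2e^{-z}/(1+e^{-z})$ rather than
  $1 - G$, so it underflows gracefully to 0 instead of losing precision
  in the subtraction. Log-sums use `log1p()`.
* In the general composition, where the base cdf is within $10^{-15}$ of
  1 the density returns its limit 0 rather than evaluating $0/0$.
* Degenerate inputs fail loudly: all-equal samples have no score root
  (error), `p` outside $[0,1]$ is a domain error, hazard below the
  threshold is a domain error; `qhltexp(1)` returns `Inf`.
* Evaluators are pure functions; nothing is cached — the samples this
  package targets are tiny, and the full test suite (including two
  1000-replicate simulation cells) runs in seconds.

Problem sizes used by the checks shipped with the package: distributional
properties on grids of 50–1000 points and samples up to $10^5$ draws;
estimator recovery at $n = 5\,000$–$50\,000$; simulation assertions at
300–1000 replicates. These sizes were chosen so each Monte-Carlo check has
standard error at least threefold smaller than the band it asserts.

## Known limitations

* No censored or weighted likelihoods; all observations are exact failure
  times.
* The threshold estimator $\hat a = \min x_i$ is superefficient but
  biased upward at small $n$; its sampling variability is not quantified.
* The hazard is confined to $[\theta/2, \theta)$: data with decreasing or
  bathtub failure rates (which the TTT plot will reveal) call for a
  different family.
* Only the exponential and truncated-exponential baselines are
  implemented for comparison; other published competitor rows are
  literature context, not reimplementation targets.
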