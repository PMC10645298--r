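# hltexp

Maximum-likelihood modelling of threshold lifetimes with the half
logistic-truncated exponential distribution (HL-TEXPD).

Reliability and survival samples often live above a hard lower bound — a
bearing cannot fail before its first revolutions, an infected animal
cannot die before inoculation. `hltexp` implements a two-parameter
lifetime law on $[a, \infty)$ built for such data: a half-logistic
generator composed with the cumulative hazard of a left-truncated
exponential base, giving

$$g(x) = \frac{2\theta e^{-\theta(x-a)}}{\{1+e^{-\theta(x-a)}\}^2},
\qquad
G(x) = \frac{1-e^{-\theta(x-a)}}{1+e^{-\theta(x-a)}},
\qquad x \ge a,$$

with threshold $a$ and rate $\theta$. Its hazard rises monotonically from
$\theta/2$ to $\theta$, making it a natural candidate for
increasing-failure-rate data. The package is aimed at reliability
engineers and biostatisticians fitting small univariate lifetime samples.

It provides:

* `dhltexp()`, `phltexp()`, `qhltexp()`, `rhltexp()`, `hhltexp()` — the
  distribution, with closed-form quantiles and seedable inverse-transform
  sampling; `hltexp_moment()`, `hltexp_moments()`, `hltexp_entropy()` for
  moments (quadrature and closed form) and Shannon entropy.
* The general truncated-family composition behind it
  (`truncated_exponential_base()`, `half_logistic_generator()`,
  `composed_cdf()`, `composed_pdf()`).
* `fit_hltexp()` — MLE with the threshold at the sample minimum and the
  rate solved from the score equation, observed-information standard
  errors; `fit_exponential()` / `fit_texp()` baselines and
  `compare_models()` for AIC/BIC ranking.
* `run_sim_cell()` / `run_sim_grid()` — Monte-Carlo evaluation of the
  estimator (bias, MSE, mean relative error, Wald coverage).
* `load_dataset()` — three classical samples bundled verbatim: `kevlar76`
  (fatigue fractures of Kevlar 373/epoxy), `guinea72` (guinea-pig
  survival times), `bearings23` (ball-bearing revolutions to failure) —
  plus `describe_sample()` and TTT / Q-Q / P-P / ecdf diagnostics.
* A command-line wrapper (`inst/cli/hltexp-cli.R`) with
  `fit`, `compare`, `simulate`, `describe` and `ttt` subcommands.

## Worked example

```r
library(hltexp)

bearings <- load_dataset("bearings23")$values
fit_hltexp(bearings)
#> HL-TEXPD fit, 23 observations
#>       a   theta
#> 17.8800  0.0262
#> loglik -113.3446  AIC 228.6892  BIC 229.8247  SE 0.0045

compare_models(bearings)
#>         model    loglik a_hat  theta_hat          se      aic      bic
#> 1    HL-TEXPD -113.3446 17.88 0.02622207 0.004486967 228.6892 229.8247
#> 2       TEXPD -114.8987 17.88 0.01839647 0.003835929 231.7974 232.9329
#> 3 Exponential -121.4393    NA 0.01384308 0.002886482 244.8786 246.0141
```

The fitted threshold is the smallest observed lifetime (17.88 million
revolutions); the rate estimate 0.0262 per million revolutions implies a
failure rate climbing from 0.0131 toward 0.0262 as bearings age, a median
life of `qhltexp(0.5, 17.88, 0.0262)` ≈ 59.8, and the lowest AIC/BIC of
the three candidates, so the HL-TEXPD is preferred over both exponential
baselines for these data.

A Monte-Carlo cell summarising the estimator at $\theta = 0.5$,
$n = 200$, 1000 replicates:

```r
run_sim_cell(theta_true = 0.5, n = 200, reps = 1000, seed = 1)[
  , c("avg_estimate", "bias", "mse", "mre", "coverage")]
#>   avg_estimate    bias     mse     mre coverage
#> 1      0.50505 0.00505 0.00097 0.04948    0.993
```

The average estimate is within half a percent of the truth, the MSE is
about $10^{-3}$, and 99.3% of nominal-99% Wald intervals cover it.

Diagnostics for failure-rate shape:

```r
ttt <- ttt_curve(bearings)   # concave => increasing failure rate
f   <- fit_hltexp(bearings)
qq  <- qq_points(f, bearings)
pp  <- pp_points(f, bearings)
plot(ttt$u, ttt$ttt, type = "l"); abline(0, 1, lty = 2)
```

From the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hltexp-cli.R", package="hltexp"))')" \
  compare --dataset kevlar76 --format json
```

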