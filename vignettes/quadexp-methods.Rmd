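---
title: "The quadratic exponential lifetime distribution: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The quadratic exponential lifetime distribution: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadexp)
```

## The model

The package implements the two-parameter quadratic exponential
distribution on $x > 0$,

$$f(x;\alpha,\beta) \;=\; \frac{\beta^3\,(\alpha + \beta x + x^2)}
  {\beta^2 + \alpha\beta^2 + 2}\, e^{-\beta x},
  \qquad \alpha,\beta > 0,$$

with CDF $F(x) = 1 - e^{-\beta x}\bigl(1 + (\beta^2x^2 +
(\beta^3+2\beta)x)/D\bigr)$, where $D = \beta^2+\alpha\beta^2+2$
throughout.  $\alpha$ is a dimensionless shape parameter, $\beta$ a
rate (units of $1/x$).  Expanding the quadratic factor shows the law is
a three-component gamma mixture with common rate $\beta$:

$$f = \tfrac{\alpha\beta^2}{D}\,\mathrm{Gamma}(1,\beta)
    + \tfrac{\beta^2}{D}\,\mathrm{Gamma}(2,\beta)
    + \tfrac{2}{D}\,\mathrm{Gamma}(3,\beta).$$

`rquadexp()` samples from this mixture exactly, which is $O(1)$ per
draw and avoids root finding; inversion through `qquadexp()` is kept as
a cross-check path in the tests.  The survival function is always
evaluated from its explicit closed form, never as $1-F$, so
`pquadexp(..., lower.tail = FALSE)` stays accurate deep in the tail
(checked at $x = 200$, where $S \sim 10^{-83}$).

The quantile function has no closed form (the usual Lambert-W trick
does not apply to a quadratic polynomial factor), so `qquadexp()` uses
a bracketed, safeguarded Newton iteration on the CDF: the bracket is
expanded geometrically until it contains the target probability, Newton
steps are clipped into the current bracket, and iteration stops at
$|F(x)-u| \le 10^{-13}$.

### Shapes

The density derivative factorizes as $f'(x) \propto -(\beta x^2 +
(\beta^2-2)x + \beta(\alpha-1))e^{-\beta x}$, giving a positive mode
$\hat x = (\sqrt{\Delta} - \beta^2 + 2)/(2\beta)$ with $\Delta =
\beta^4 - 4\alpha\beta^2 + 4$ whenever $\Delta > 0$ and
$\sqrt{\Delta} > \beta^2 - 2$; otherwise the density decreases from
$x = 0$.  In the decreasing case `quadexp_shape()` reports mode
*location* 0 and the density value $f(0) = \alpha\beta^3/D$
separately — a mode is a location, and the value sometimes quoted as
the "mode" in the decreasing case is in fact $f(0)$.

The hazard derivative has the sign of $L(x) = 2\beta x^2 +
(2\beta^2+4)x + \beta(\beta^2+2-2\alpha)$.  Because the leading
coefficient of $L$ is positive, the hazard can only be increasing
(no positive root of $L$) or bathtub-shaped (one positive root, i.e.
$-\beta^4+4\alpha\beta^2+4 > 0$ and $\beta^2 + 2 <
\sqrt{-\beta^4+4\alpha\beta^2+4}$); a hazard that decreases on the
whole half-line is impossible in this family.  Statements of a
three-way increasing/decreasing/bathtub classification circulate for
this model; the "decreasing" branch corresponds to $L$ having two
negative roots, where $L > 0$ on $x>0$ and the hazard is in fact
increasing.  `quadexp_hazard_shape()` classifies by the sign pattern of
$L$, which the finite-difference oracle in the test suite confirms on
randomized parameters.  A claim that the mean always lies below the
mode also fails numerically (at $\alpha=\beta=1$ the mean is 2.25 and
the mode is 1), so no such ordering is assumed anywhere.

## Derived measures

Raw moments come from
$E[X^r] = [\Gamma(r+3) + \beta^2\Gamma(r+2) +
\alpha\beta^2\Gamma(r+1)]/(\beta^r D)$; the variance is computed as
$E[X^2]-E[X]^2$ (displayed "variance formulas" for this family tend to
be garbled, and the quadrature oracle arbitrates).  Skewness and
kurtosis are reported in two conventions, because published tables for
this family use raw-moment ratios $E[X^3]/\mathrm{Var}^{3/2}$ and
$E[X^4]/\mathrm{Var}^2$ where most readers expect standardized central
moments: both are returned, labelled `*_raw` and plain.

Other choices worth recording:

* **MGF.** Implemented as the compact antiderivative
  $C[\alpha/(\beta-s) + \beta/(\beta-s)^2 + 2/(\beta-s)^3]$, $s<\beta$,
  verified against quadrature.
* **Mean residual life / mean waiting time.** Built from the standard
  definitions $\mathrm{MRL}(t) = (E[X]-T_1(t))/S(t) - t$ and
  $\mathrm{MWT}(t) = t - T_1(t)/F(t)$ using the package's own
  incomplete moment $T_1$; displayed closed forms for these quantities
  in the source literature do not type-check and were not used.
* **Limited expected value.** $E[X\wedge u] = T_1(u) + uS(u)$, in the
  closed form $[2\beta^2+\alpha\beta^2+6 - e^{-\beta u}(\beta^2u^2 +
  (\beta^3+4\beta)u + 2\beta^2+\alpha\beta^2+6)]/(\beta D)$.  This is
  the correct recombination of the partial-moment expression; a
  commonly printed final display for this quantity is internally
  inconsistent (it evaluates to $-0.60$ at $\alpha=\beta=u=1$ where the
  true value is $0.87$) and the identity $E[X\wedge u] = T_1(u)+uS(u)$
  plus the layer decomposition $E[X\wedge u] + \int_u^\infty S = E[X]$
  are enforced in the tests instead.
* **Mean excess.** Two deliberately separate routes.  The *integral*
  form $e(x) = \int_x^\infty S(u)du / S(x)$ is the definition; it tends
  to $1/\beta$.  The *closed* product form tabulated alongside this
  distribution reproduces those published tables to all printed digits
  but is **not** equal to the definition (it grows like $x^4$), so
  `quadexp_mean_excess()` has no default `form`: callers must choose,
  and the documentation marks the closed form as a
  table-reproduction device, not a mean excess.
* **Rényi entropy.** For integer $s\ge 2$ the binomial double sum is
  used with the integrand read as $e^{-s\beta x}$ (a stray symbol in
  circulating versions of the series is a typo for $\beta$); for any
  other $s>0$, $s\ne1$, quadrature.  Both routes agree to $10^{-8}$
  where both apply.
* **Fuzzy reliability.** Triangular membership with knots
  $t_1 < t_2$; at cut level $\lambda$ the crisp lifetime is
  $x(\lambda) = t_1 + \lambda(t_2-t_1)$ and $R_F = S(t_1) -
  S(x(\lambda))$.  $R_F$ is 0 at $\lambda=0$, increasing in $\lambda$
  and $t_2$, bounded by $S(t_1)$.  Antitonicity in $t_1$ holds in the
  moderate-rate, knots-below-the-bulk regime of the published
  comparisons (and is tested there); it is not a theorem for arbitrary
  knot placements, since moving $t_1$ also moves $x(\lambda)$.
* **Risk measures.** VaR is the quantile; TVaR and the tail variance
  use the closed forms (both verified against conditional-moment
  quadrature to $10^{-7}$ relative); `quadexp_risk()` bundles them with
  the integral mean excess and the limited expected value at the VaR.

## The fifteen estimators

All methods are objective functions over $(\alpha,\beta)$, minimized by
a shared dispatcher (`quadexp_objective()` / `fitquadexp()`):
maximum likelihood; Anderson–Darling (AD) and its right-tail, left-tail
and left-tail second-order variants; Cramér–von Mises; ordinary and
weighted least squares on the probability scale; Kolmogorov minimum
distance; maximum product of spacings (MPS); and five further spacings
criteria (absolute, absolute-log, squared, squared-log and Linex
distances between consecutive fitted-CDF spacings and their ideal value
$1/(n+1)$).  Conventions:

* MPS is a maximization; the dispatcher stores the negated mean
  log-spacing so that every method minimizes.
* The AD family pairs the $i$-th order statistic with index $n+1-i$ in
  its survival term (an off-by-one index that would leave the sample
  range circulates in print).
* The left-tail second-order criterion is implemented as
  $2\sum\ln F_i + n^{-1}\sum(2i-1)/F_i$, which is exactly
  $n\int (F_n - u)^2/u^2\,du$ (the test suite verifies this identity
  numerically against the step-function integral); the variant with a
  multiplicative $F_i$ instead of $1/F_i$ is unbounded below and is
  available behind `adsoe_printed = TRUE` for fidelity experiments
  only.
* CDF values are clipped to $[10^{-300}, 1-10^{-16}]$ inside
  logarithms; spacings are floored at $10^{-300}$.  Exact ties
  (dataset III contains one) are separated deterministically by
  multiples of $10^{-9}\,\bar x$ before spacings are formed.
* `fitquadexp()` optimizes over $(\log\alpha,\log\beta)$ by Nelder–Mead
  (tolerance $10^{-10}$, up to 5000 evaluations) from a deterministic
  multi-start: $\alpha$ on a coarse grid with $\beta$ solved from the
  mean equation (the mean is monotone in $\beta$ at fixed $\alpha$),
  candidates ranked by the objective.  Standard errors for maximum
  likelihood are observed-information (inverse negative Hessian); a
  non-positive-definite Hessian — which genuinely occurs when the
  likelihood optimum sits on the $\alpha=0$ boundary, as for bundled
  dataset III — yields `NA` standard errors with a warning rather than
  fabricated numbers.

A structural fact that shapes everything downstream: **$\alpha$ is
weakly identified.**  As $\alpha\to\infty$ the family collapses to the
exponential distribution with rate $\beta$, so samples that happen to
look exponential push $\hat\alpha$ to the boundary at infinity.  At
$(\alpha,\beta) = (1.5, 2.5)$ this happens for roughly 8% of samples of
size 25 and under 1% at size 400.  Consequently the sampling
distribution of $\hat\alpha$ is heavy-tailed under *any* faithful
optimizer, and moments of $\hat\alpha$ reported by simulation studies
are partly a property of where the optimizer stops.

## The Monte Carlo engine

`quadexp_sim_study()` draws `reps` samples (one per replicate, shared
across all methods so columns are comparable), fits every method, and
accumulates six metrics: coordinatewise mean absolute bias, MSE and
mean relative error, plus the CDF discrepancies
$D_{abs}$ (mean absolute difference between true and fitted CDF at the
sample points), $D_{max}$ (mean of the per-replicate maxima) and the
average scaled absolute error ASAE, where the fitted quantile at
plotting position $j/(n+1)$ is compared with the $j$-th order statistic
and the absolute differences are *averaged over $j$* before scaling by
the sample range — without the inner average the quantity would grow
with $n$, while the published magnitudes are $O(1)$.

With `init_at_truth = TRUE` (the default) each fit is a single
`optim()` BFGS run started at the true parameters, which is the
protocol this kind of estimator-comparison study conventionally uses.
Two consequences are documented deliberately:

* On the non-smooth Kolmogorov max-objective, a quasi-Newton line
  search stalls close to its starting point.  This reproduces the
  published behaviour in which the Kolmogorov method appears to have
  a several-fold smaller bias than every other method (about 0.06
  versus 0.37–0.51 for $\hat\alpha$ at $n=400$): the "win" is an
  optimizer-stall artifact of the truth-start protocol, not a
  statistical property of the minimum-KS estimator.  A thorough
  Nelder–Mead minimization of the same objective yields a bias an
  order of magnitude larger.  The engine reproduces the protocol and
  this vignette records why.
* A BFGS line search fed non-finite numerical gradients (possible when
  clipped CDF values sit at the floor) can return a point worse than
  its start; the engine guards against this by never returning a point
  with a higher objective than the starting value, and counts such
  replicates as non-converged rather than dropping them (dropping
  failures would understate bias).

With `init_at_truth = FALSE` the engine uses the robust multi-start
fitter instead; this is the right choice for method comparison on an
equal, data-driven footing, at several times the cost.

`rank_estimators()` ranks each metric ascending with average ranks on
ties, sums per-metric ranks and ranks the sums, mirroring the usual
presentation of such studies (fractional ranks appear exactly when two
methods tie on a metric).

Replicate counts: the replicate count is configurable; the package's
own checks use $M=300$ for the sample-size-trend assertion — enough
that the heavy $\hat\alpha$ tail described above averages out — $M=120$
for the Kolmogorov-bias spot check, and $M=1000$ in the acceptance
script, with $n$ ranging over 25–1000.  Under a fixed seed the engine
is bit-reproducible.

## Goodness of fit and model comparison

`gof_report()` computes $-2\log L$, AIC $=-2\log L+2k$, HQIC
$=-2\log L + 2k\ln\ln n$, and the KS, Cramér–von Mises and
Anderson–Darling statistics from the probability-integral transforms
of the sorted sample.  P-values use the **asymptotic simple-hypothesis
null laws evaluated at the estimated parameters** — no Lilliefors-type
correction and no bootstrap.  That convention is what published
comparison tables for this family use (e.g. $\sqrt{30}\times 0.0828 =
0.4533$ under the Kolmogorov limit law gives $p = 0.9863$ exactly);
p-values so computed are optimistic as absolute error rates when
parameters are estimated, but are comparable across models fitted to
the same data, which is how the comparison table uses them.  The KS
p-value switches between the theta-function series (small $t$) and the
alternating tail series (large $t$) at $t=1$, where the two agree to
$10^{-9}$; CVM and AD upper-tail probabilities come from Imhof
characteristic-function inversion of their weighted-$\chi^2$ limit laws
(2000 weights, truncation absorbed as its mean), which matches
independent references to $10^{-6}$.

Competitor families are Burr type X, the exponential, the
Nadarajah–Haghighi extension of the exponential, an XLindley variant,
and its reciprocal ("modified XLindley").  The latter two deserve a
note: the XLindley form used here is the equal-weight
Exp/Gamma(2) mixture $f(x;\theta) = (\theta/2)(1+\theta x)
e^{-\theta x}$, and the modified XLindley is the law of $1/X$ under
that family.  These are the forms that reproduce the published
real-data comparison tables for this distribution to all printed
decimals (the better-known Chouia–Zeghdoudi XLindley does not); both
are normalization-checked by quadrature in the tests.  All six families
are fitted by maximum likelihood (closed form for the exponential,
golden-section/Brent search for one-parameter families, multi-start
Nelder–Mead on the log scale for two-parameter ones) and
`compare_models()` returns one row per family sorted by AIC, flagging
degenerate-information fits instead of failing on them.

## What the synthetic data does and does not show

The generator *is* the model: i.i.d. draws from the exact gamma
mixture.  Tests built on it validate internal consistency — closed
forms against quadrature, estimators against the truth, the engine's
metrics against their definitions.  They do not show robustness to
model misspecification, censoring (no censored-likelihood support is
provided), covariates, or dependent data; and the real-data
comparisons bundled with the package involve three specific small
samples (n = 23–50), not a survey of lifetime data at large.

## Numerical choices

Quadrature: `stats::integrate` with relative tolerance $10^{-12}$.
Quantiles: bracketed Newton, $|F-u|\le 10^{-13}$.  Boundary case
$\Delta_h = 0$ in the hazard classification resolves to "increasing"
(the derivative touches zero without changing sign).  Degenerate
objective values (non-finite, from clipped logs) are replaced by a
large penalty inside optimizers.  All seeds are explicit arguments;
nothing draws from an ambient RNG state except where documented
(`fitquadexp` is fully deterministic, including its tie-breaking rule).
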