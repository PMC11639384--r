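# quadexp

Tools for the **two-parameter quadratic exponential distribution**, a
lifetime model on the positive half-line with density

$$f(x;\alpha,\beta) = \frac{\beta^3\,(\alpha + \beta x + x^2)}
  {\beta^2 + \alpha\beta^2 + 2}\; e^{-\beta x},
  \qquad x, \alpha, \beta > 0 .$$

It is an exact three-component gamma mixture (shapes 1, 2, 3, common
rate $\beta$), has closed-form CDF, survival and hazard, and exhibits
increasing or bathtub-shaped hazards — which makes it a convenient
drop-in competitor to Lindley-type and Burr-type families for
survival, reliability and insurance-loss data.

The package is aimed at practitioners fitting parametric lifetime
models and at anyone studying how the choice of estimation criterion
affects such fits.  It provides:

* `dquadexp` / `pquadexp` / `qquadexp` / `rquadexp` / `hquadexp`, plus
  analytic shape classifiers for the density and the hazard;
* closed-form moments and derived measures with quadrature-verified
  implementations: mean residual life, Lorenz/Bonferroni curves, Rényi
  entropy, fuzzy reliability under a λ-cut, and the actuarial set
  (VaR, TVaR, tail variance, mean excess, limited expected value);
* **fifteen estimation methods** behind one interface
  (`fitquadexp`): maximum likelihood, maximum product of spacings,
  Kolmogorov minimum distance, Cramér–von Mises, ordinary/weighted
  least squares, four Anderson–Darling variants and five further
  spacings criteria;
* a Monte Carlo engine (`quadexp_sim_study`, `rank_estimators`) that
  benchmarks the estimators on six metrics and ranks them;
* a goodness-of-fit suite (`fit_family`, `gof_report`,
  `compare_models`) with KS/CVM/AD statistics, asymptotic p-values,
  AIC and HQIC, against Burr X, exponential, Nadarajah–Haghighi,
  XLindley and reciprocal-XLindley competitors, plus three bundled
  benchmark datasets (`quadexp_dataset("I")`, `"II"`, `"III"`).

A thin command-line front end lives in `exec/quadexp`
(`fit`, `compare`, `simulate`, `measure`, `quantile`, `rvs`).

## Worked example

Fit the model to the bundled 30-observation relief-time dataset and
compare it against five competitor families:

```r
library(quadexp)
x <- quadexp_dataset("I")

fitquadexp(x, "mle")
#> Quadratic exponential fit (MLE, n = 30)
#>   alpha = 0.0234561   beta = 1.57612
#>   se(alpha) = 0.2517   se(beta) = 0.1941
#>   objective = 79.4691   logLik = -39.7345   converged: TRUE

compare_models(x)[, c("family", "neg2loglik", "aic", "hqic", "ks", "ks_p")]
#>     family neg2loglik   aic  hqic      ks   ks_p
#>    quadexp      79.47 83.47 84.37 0.08276 0.9863
#>   xlindley      83.13 85.13 85.57 0.14818 0.5253
#>      burrx      81.15 85.15 86.04 0.10911 0.8674
#>     expext      82.31 86.31 87.20 0.11310 0.8375
#>        exp      86.01 88.01 88.46 0.18448 0.2590
#>  mxlindley      93.88 95.88 96.33 0.14600 0.5446
```

The quadratic exponential attains the lowest AIC/HQIC and the smallest
KS distance with the highest p-value: on these data it beats all five
competitors.  (The p-values are asymptotic simple-hypothesis values
evaluated at the estimated parameters — comparable across rows, not
exact error rates; see the methods vignette.)

Derived quantities at the fitted parameters:

```r
f <- fitquadexp(x, "mle")
st <- quadexp_stats(f$alpha, f$beta)
#> mean 1.5402  sd 1.0421  cv 0.6766
quadexp_risk(0.95, f$alpha, f$beta)
#> VaR95 3.5474  TVaR95 4.3660  TV95 0.6287
quadexp_hazard_shape(f$alpha, f$beta)
#> [1] "increasing"
```

So a 95th-percentile "claim" under this fit is 3.55, the expected claim
*given* the 95% level is exceeded is 4.37, and the hazard rises
monotonically toward its limit $\beta = 1.576$.

Benchmark the estimators themselves on synthetic data:

```r
res <- quadexp_sim_study(alpha = 1.5, beta = 2.5, n = 100, reps = 100,
                         seed = 1)
rank_estimators(res)[, c("method", "bias_alpha", "bias_beta",
                         "rank_sum", "overall_rank")]
```

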