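## Goodness-of-fit statistics, asymptotic p-values and the
## model-comparison table.
##
## KS, Cramer-von Mises and Anderson-Darling statistics are computed
## from the fitted probability-integral transforms u_i = F(x_(i)).
## P-values use the asymptotic simple-hypothesis null distributions
## evaluated at the estimated parameters (no Lilliefors-type
## correction): the Kolmogorov series for KS, and numerical inversion
## of the characteristic function (Imhof's method) for the
## weighted-chi-square limits of CVM and AD.

#' Asymptotic Kolmogorov-Smirnov p-value
#'
#' Two-sided p-value of the one-sample KS statistic under the simple
#' hypothesis, from the Kolmogorov limit distribution of
#' \eqn{t = \sqrt{n} D_n}.  For `t < 1` the theta-function series
#' \eqn{P(T \le t) = (\sqrt{2\pi}/t)\sum_j \exp(-(2j-1)^2\pi^2/(8t^2))}
#' is used; for `t >= 1` the alternating tail series
#' \eqn{p = 2\sum_j (-1)^{j-1} e^{-2j^2t^2}}.  The two expansions agree
#' to machine precision near the switch point.
#'
#' @param stat observed KS statistic \eqn{D_n}.
#' @param n sample size.
#' @return The p-value.
#' @export
pvalue_ks <- function(stat, n) {
  t <- sqrt(n) * stat
  if (t <= 0) return(1)
  j <- 1:100
  p <- if (t < 1) {
    1 - sqrt(2 * pi) / t * sum(exp(-(2 * j - 1)^2 * pi^2 / (8 * t^2)))
  } else {
    2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  }
  min(max(p, 0), 1)
}

# Imhof inversion: P(Q > q) for Q = sum_j lam_j Z_j^2.  The series is
# truncated; the dropped components are absorbed as their mean (their
# variance is O(N^-3) and negligible), i.e. q is shifted by the tail
# sum of the weights before inverting.
.imhof_p <- function(q, lam, tail_mean = 0) {
  q <- q - tail_mean
  th <- function(u) 0.5 * colSums(atan(outer(lam, u))) - q * u / 2
  rho <- function(u) exp(0.25 * colSums(log1p(outer(lam^2, u^2))))
  f <- function(u) sin(th(u)) / (u * rho(u))
  v <- stats::integrate(f, 0, Inf, rel.tol = 1e-10,
                        subdivisions = 2000L)$value
  min(max(0.5 + v / pi, 0), 1)
}

#' Asymptotic Cramer-von Mises and Anderson-Darling p-values
#'
#' Upper-tail probabilities of the asymptotic null laws
#' \eqn{W^2 = \sum_j Z_j^2/(j^2\pi^2)} (CVM) and
#' \eqn{A^2 = \sum_j Z_j^2/(j(j+1))} (AD), by Imhof's
#' characteristic-function inversion with 2000 weights.
#'
#' @param stat observed statistic.
#' @return The p-value.
#' @export
pvalue_cvm <- function(stat)
  .imhof_p(stat, 1 / (pi^2 * (1:2000)^2),
           tail_mean = (pi^2 / 6 - sum(1 / (1:2000)^2)) / pi^2)

#' @rdname pvalue_cvm
#' @export
pvalue_ad <- function(stat)
  .imhof_p(stat, 1 / ((1:2000) * (2:2001)), tail_mean = 1 / 2001)

#' Goodness-of-fit report for a fitted model
#'
#' Computes \eqn{-2\log L}, AIC \eqn{= -2\log L + 2k}, HQIC
#' \eqn{= -2\log L + 2k\ln\ln n}, and the KS, CVM and AD statistics
#' with asymptotic p-values, from the probability-integral transforms
#' of the sorted sample under the fitted CDF:
#' \deqn{KS = \max_i \max(i/n - u_i,\ u_i - (i-1)/n), \quad
#'   CVM = \frac{1}{12n} + \sum_i\left(u_i - \frac{2i-1}{2n}\right)^2,}
#' \deqn{AD = -n - \frac{1}{n}\sum_i (2i-1)[\ln u_i +
#'   \ln(1 - u_{n+1-i})].}
#'
#' @param x positive sample.
#' @param fit a fitted model from [fit_family()] (or a compatible list
#'   with `family`, `params`, `k`, `loglik`).
#' @return A list with `family`, `params`, `neg2loglik`, `aic`, `hqic`,
#'   `ks`, `ks_p`, `cvm`, `cvm_p`, `ad`, `ad_p`.
#' @export
gof_report <- function(x, fit) {
  if (length(x) == 0 || any(x <= 0)) stop("sample must be positive, nonempty")
  fam <- .families()[[fit$family]]
  n <- length(x)
  u <- .clipF(fam$cdf(sort(x), fit$params))
  i <- seq_len(n)
  ks <- max(pmax(i / n - u, u - (i - 1) / n))
  cvm <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  ad <- -n - mean((2 * i - 1) * (log(u) + log1p(-rev(u))))
  n2ll <- -2 * fit$loglik
  list(family = fit$family, params = fit$params,
       neg2loglik = n2ll,
       aic = n2ll + 2 * fit$k,
       hqic = n2ll + 2 * fit$k * log(log(n)),
       ks = ks, ks_p = pvalue_ks(ks, n),
       cvm = cvm, cvm_p = pvalue_cvm(cvm),
       ad = ad, ad_p = pvalue_ad(ad))
}

#' Compare lifetime models on one sample
#'
#' Fits each family by maximum likelihood, computes its goodness-of-fit
#' report and returns the table sorted by AIC (columns mirror the usual
#' presentation: -2logL, AIC, HQIC, KS, p(KS), CVM, p(CVM), AD, p(AD)).
#' A family whose fit fails is flagged in the `note` column and does
#' not affect the others.
#'
#' @param x positive sample.
#' @param families families to include, see [fit_family()].
#' @return A `data.frame`, one row per family, sorted by AIC.
#' @examples
#' compare_models(quadexp_dataset("I"))
#' @export
compare_models <- function(x, families = c("quadexp", "burrx", "exp",
                                           "xlindley", "mxlindley",
                                           "expext")) {
  families <- match.arg(families, names(.families()), several.ok = TRUE)
  stopifnot(length(families) >= 2)
  rows <- lapply(families, function(fm) {
    f <- tryCatch(suppressWarnings(fit_family(x, fm)),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(data.frame(family = fm, par1 = NA, par2 = NA,
                        neg2loglik = NA, aic = NA, hqic = NA, ks = NA,
                        ks_p = NA, cvm = NA, cvm_p = NA, ad = NA,
                        ad_p = NA, note = "fit failed"))
    }
    g <- gof_report(x, f)
    data.frame(family = fm,
               par1 = f$params[1],
               par2 = if (f$k == 2) f$params[2] else NA_real_,
               neg2loglik = g$neg2loglik, aic = g$aic, hqic = g$hqic,
               ks = g$ks, ks_p = g$ks_p, cvm = g$cvm, cvm_p = g$cvm_p,
               ad = g$ad, ad_p = g$ad_p,
               note = if (any(is.na(f$se))) "degenerate information" else "")
  })
  out <- do.call(rbind, rows)
  out[order(out$aic), , drop = FALSE]
}

#' Bundled example datasets
#'
#' Three positive-valued samples commonly used to benchmark lifetime
#' models: `"I"` (n = 30), `"II"` (n = 50) and `"III"` (n = 23,
#' geological failure stresses with ties).  Stored as plain-text files
#' under `inst/extdata/`.
#'
#' @param id `"I"`, `"II"` or `"III"`.
#' @return Numeric vector of observations.
#' @examples
#' length(quadexp_dataset("I"))
#' @export
quadexp_dataset <- function(id = c("I", "II", "III")) {
  id <- match.arg(id)
  path <- system.file("extdata", paste0("dataset_", id, ".txt"),
                      package = "quadexp", mustWork = TRUE)
  read_sample(path)
}
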