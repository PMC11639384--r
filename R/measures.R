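## Derived measures: moments, MGF, incomplete moments, residual life,
## inequality curves, entropy, fuzzy reliability, actuarial risk measures.
## Every closed form here has a quadrature counterpart in the test suite.

# upper incomplete gamma Gamma(a, x) = integral_x^Inf t^(a-1) e^-t dt
.uigamma <- function(a, x) gamma(a) * stats::pgamma(x, a, lower.tail = FALSE)

# adaptive quadrature of f over (lo, hi); used for the "integral" routes
.qe_quad <- function(f, lo, hi, rel.tol = 1e-12) {
  stats::integrate(f, lo, hi, rel.tol = rel.tol, subdivisions = 500L)$value
}

#' Raw moments
#'
#' \eqn{E[X^r] = [\Gamma(r+3) + \beta^2\Gamma(r+2) +
#' \alpha\beta^2\Gamma(r+1)] / (\beta^r D)} with
#' \eqn{D = \beta^2 + \alpha\beta^2 + 2}.
#'
#' @param order nonnegative moment order `r`.
#' @inheritParams quadexp_mixture_weights
#' @return The raw moment \eqn{E[X^r]}.
#' @examples
#' mquadexp(1, 1, 1)  # 2.25
#' @export
mquadexp <- function(order, alpha, beta) {
  .check_ab(alpha, beta)
  if (any(order < 0)) stop("'order' must be nonnegative")
  (gamma(order + 3) + beta^2 * gamma(order + 2) +
     alpha * beta^2 * gamma(order + 1)) / (beta^order * .qe_D(alpha, beta))
}

#' Moment summary
#'
#' Mean, variance, standard deviation, coefficient of variation,
#' skewness and kurtosis.  Two skewness/kurtosis conventions are
#' reported: the standardized central-moment versions (`skewness`,
#' `kurtosis`) and the raw-moment ratios \eqn{E[X^3]/Var^{3/2}} and
#' \eqn{E[X^4]/Var^2} (`skewness_raw`, `kurtosis_raw`) that some authors
#' tabulate in place of the standardized ones.  The variance is computed
#' as \eqn{E[X^2] - E[X]^2}.
#'
#' @inheritParams quadexp_mixture_weights
#' @return A list with elements `mean`, `variance`, `sd`, `cv`,
#'   `skewness`, `kurtosis`, `skewness_raw`, `kurtosis_raw`.
#' @export
quadexp_stats <- function(alpha, beta) {
  .check_ab(alpha, beta)
  D <- .qe_D(alpha, beta)
  m1 <- (2 * beta^2 + alpha * beta^2 + 6) / (beta * D)  # closed form
  m2 <- mquadexp(2, alpha, beta)
  m3 <- mquadexp(3, alpha, beta)
  m4 <- mquadexp(4, alpha, beta)
  v <- m2 - m1^2
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  list(mean = m1, variance = v, sd = sqrt(v), cv = sqrt(v) / m1,
       skewness = mu3 / v^1.5, kurtosis = mu4 / v^2,
       skewness_raw = m3 / v^1.5, kurtosis_raw = m4 / v^2)
}

#' Moment generating function
#'
#' \eqn{M(s) = C[\alpha/(\beta-s) + \beta/(\beta-s)^2 + 2/(\beta-s)^3]},
#' defined for `s < beta`.
#'
#' @param s argument of the MGF, `s < beta`.
#' @inheritParams quadexp_mixture_weights
#' @export
mgfquadexp <- function(s, alpha, beta) {
  .check_ab(alpha, beta)
  if (any(s >= beta)) stop("the MGF requires s < beta")
  .qe_C(alpha, beta) *
    (alpha / (beta - s) + beta / (beta - s)^2 + 2 / (beta - s)^3)
}

#' Incomplete moments
#'
#' \eqn{T_r(s) = \int_0^s x^r f(x)\,dx}, via lower incomplete gamma
#' functions.
#'
#' @param order positive integer moment order `r`.
#' @param limit upper integration limit `s >= 0`.
#' @inheritParams quadexp_mixture_weights
#' @export
quadexp_inc_moment <- function(order, limit, alpha, beta) {
  .check_ab(alpha, beta)
  if (any(limit < 0)) stop("'limit' must be nonnegative")
  r <- order
  lg <- function(a) gamma(a) * stats::pgamma(limit * beta, a)  # Gamma(a)-Gamma(a,s*beta)
  (lg(r + 3) + beta^2 * lg(r + 2) + alpha * beta^2 * lg(r + 1)) /
    (beta^r * .qe_D(alpha, beta))
}

#' Mean residual life and mean waiting time
#'
#' `quadexp_mrl` is the expected remaining lifetime given survival to
#' `t`: \eqn{(E[X] - T_1(t))/S(t) - t}.  `quadexp_mwt` is the mean
#' waiting (inactivity) time given failure before `t`:
#' \eqn{t - T_1(t)/F(t)}.
#'
#' @param t positive threshold.
#' @inheritParams quadexp_mixture_weights
#' @export
quadexp_mrl <- function(t, alpha, beta) {
  .check_ab(alpha, beta)
  if (any(t <= 0)) stop("'t' must be positive")
  m1 <- quadexp_stats(alpha, beta)$mean
  (m1 - quadexp_inc_moment(1, t, alpha, beta)) /
    pquadexp(t, alpha, beta, lower.tail = FALSE) - t
}

#' @rdname quadexp_mrl
#' @export
quadexp_mwt <- function(t, alpha, beta) {
  .check_ab(alpha, beta)
  if (any(t <= 0)) stop("'t' must be positive")
  t - quadexp_inc_moment(1, t, alpha, beta) / pquadexp(t, alpha, beta)
}

#' Lorenz and Bonferroni curves
#'
#' \eqn{L(u) = T_1(Q(u))/E[X]} and \eqn{B(u) = L(u)/u} for
#' `u` in (0, 1).
#'
#' @param u probability level in (0, 1).
#' @inheritParams quadexp_mixture_weights
#' @export
quadexp_lorenz <- function(u, alpha, beta) {
  .check_ab(alpha, beta)
  xq <- qquadexp(u, alpha, beta)
  quadexp_inc_moment(1, xq, alpha, beta) / quadexp_stats(alpha, beta)$mean
}

#' @rdname quadexp_lorenz
#' @export
quadexp_bonferroni <- function(u, alpha, beta) {
  quadexp_lorenz(u, alpha, beta) / u
}

#' Renyi entropy
#'
#' \eqn{I_R(s) = (1-s)^{-1}\log \int_0^\infty f^s(x)\,dx}.  For integer
#' `s >= 2` a finite double-sum closed form is available from the
#' binomial expansion of \eqn{(\alpha + \beta x + x^2)^s}; for any other
#' admissible `s` (`s > 0`, `s != 1`) the integral is evaluated by
#' adaptive quadrature.  The two routes agree to high accuracy where
#' both apply.
#'
#' @param s entropy order; `method = "series"` requires integer
#'   `s >= 2`.
#' @param method `"auto"` (series when available), `"series"` or
#'   `"quadrature"`.
#' @inheritParams quadexp_mixture_weights
#' @export
quadexp_renyi <- function(s, alpha, beta,
                          method = c("auto", "series", "quadrature")) {
  .check_ab(alpha, beta)
  method <- match.arg(method)
  if (length(s) != 1L || !is.finite(s) || s <= 0 || s == 1)
    stop("'s' must be positive and different from 1")
  is_int <- s >= 2 && s == round(s)
  if (method == "auto") method <- if (is_int) "series" else "quadrature"
  if (method == "series") {
    if (!is_int) stop("the series form requires integer s >= 2")
    tot <- 0
    for (i in 0:s) for (j in 0:i) {
      tot <- tot + choose(s, i) * choose(i, j) * alpha^j * beta^(i - j) *
        gamma(2 * s - j + 1 - i) * (s * beta)^(j - 2 * s + i - 1)
    }
    # choose(s,i)*choose(i,j) = s!/((s-i)! i!) * i!/((i-j)! j!)
    log(.qe_C(alpha, beta)^s * tot) / (1 - s)
  } else {
    v <- .qe_quad(function(x) dquadexp(x, alpha, beta)^s, 0, Inf)
    log(v) / (1 - s)
  }
}

#' Fuzzy reliability under a lambda-cut
#'
#' Reliability evaluated through a triangular membership function with
#' knots `t1 < t2`: the crisp lifetime at cut level `lambda` is
#' \eqn{x(\lambda) = t_1 + \lambda(t_2 - t_1)} and the fuzzy reliability
#' is \eqn{R_F = S(t_1) - S(x(\lambda))}.  It is 0 at `lambda = 0`,
#' increases with `lambda` and `t2`, decreases as `t1` grows, and is
#' bounded above by \eqn{S(t_1)}.
#'
#' @param t1,t2 membership-function knots, `0 <= t1 < t2`.
#' @param lambda cut level(s) in `[0, 1]`.
#' @inheritParams quadexp_mixture_weights
#' @export
quadexp_fuzzy_rel <- function(t1, t2, lambda, alpha, beta) {
  .check_ab(alpha, beta)
  if (length(t1) != 1L || length(t2) != 1L || t1 < 0 || t2 <= t1)
    stop("knots must satisfy 0 <= t1 < t2")
  if (any(lambda < 0) || any(lambda > 1))
    stop("'lambda' must lie in [0, 1]")
  xl <- t1 + lambda * (t2 - t1)
  pquadexp(t1, alpha, beta, lower.tail = FALSE) -
    pquadexp(xl, alpha, beta, lower.tail = FALSE)
}

#' Mean excess function
#'
#' Expected exceedance over a threshold `x` given survival to it.  Two
#' forms are exposed and they are **not** equivalent:
#' * `form = "integral"`: the defining integral
#'   \eqn{e(x) = \int_x^\infty S(u)\,du / S(x)}, evaluated by adaptive
#'   quadrature; it tends to \eqn{1/\beta} as \eqn{x \to \infty}.
#' * `form = "closed"`: the product expression
#'   \eqn{(\beta^2x^2 + (\beta^3+2\beta)x + D)(\beta^2x^2 +
#'   (\beta^3+4\beta)x + 2\beta^2 + \alpha\beta^2 + 6) / (\beta D^2)}
#'   tabulated alongside this distribution in the literature; it grows
#'   like \eqn{x^4} and therefore disagrees with the integral definition
#'   everywhere except by coincidence.  It is provided for comparison
#'   with published tables and should not be used as a mean excess.
#'
#' `form` has no default: the caller must choose explicitly.
#'
#' @param x positive threshold.
#' @param form `"closed"` or `"integral"` (see Details).
#' @inheritParams quadexp_mixture_weights
#' @export
quadexp_mean_excess <- function(x, alpha, beta, form) {
  .check_ab(alpha, beta)
  if (missing(form)) stop("'form' must be given: \"closed\" or \"integral\"")
  form <- match.arg(form, c("closed", "integral"))
  if (any(x <= 0)) stop("'x' must be positive")
  D <- .qe_D(alpha, beta)
  if (form == "closed") {
    (x^2 * beta^2 + 2 * x * beta + beta^2 + x * beta^3 + alpha * beta^2 + 2) *
      (x^2 * beta^2 + 4 * x * beta + 2 * beta^2 + x * beta^3 +
         alpha * beta^2 + 6) / (beta * D^2)
  } else {
    vapply(x, function(xi) {
      .qe_quad(function(u) pquadexp(u, alpha, beta, lower.tail = FALSE),
               xi, Inf) / pquadexp(xi, alpha, beta, lower.tail = FALSE)
    }, numeric(1))
  }
}

#' Limited expected value
#'
#' \eqn{E[X \wedge u] = T_1(u) + u S(u)}, in closed form:
#' \deqn{E[X \wedge u] = \frac{2\beta^2 + \alpha\beta^2 + 6 -
#'   e^{-\beta u}\left(\beta^2 u^2 + (\beta^3 + 4\beta)u + 2\beta^2 +
#'   \alpha\beta^2 + 6\right)}{\beta D}.}
#'
#' @param limit positive policy limit `u`.
#' @inheritParams quadexp_mixture_weights
#' @export
levquadexp <- function(limit, alpha, beta) {
  .check_ab(alpha, beta)
  if (any(limit <= 0)) stop("'limit' must be positive")
  u <- limit
  D <- .qe_D(alpha, beta)
  (2 * beta^2 + alpha * beta^2 + 6 -
     exp(-beta * u) * (beta^2 * u^2 + (beta^3 + 4 * beta) * u +
                         2 * beta^2 + alpha * beta^2 + 6)) / (beta * D)
}

#' Tail value at risk and tail variance
#'
#' `quadexp_tvar` is the conditional expectation beyond the
#' `level`-quantile (value at risk), from its closed form; and
#' `quadexp_tail_variance` the conditional variance beyond it,
#' \eqn{TV = E[X^2 \mid X > VaR] - TVaR^2}.
#'
#' @param level probability level in (0, 1).
#' @inheritParams quadexp_mixture_weights
#' @export
quadexp_tvar <- function(level, alpha, beta) {
  .check_ab(alpha, beta)
  v <- qquadexp(level, alpha, beta)
  b <- beta; a <- alpha
  exp(-v * b) / ((1 - level) * b * .qe_D(a, b)) *
    (3 * b^2 * v^2 + b^4 * v^2 + b^3 * v^3 + 6 * b * v + 2 * b^3 * v +
       a * b^3 * v + a * b^2 + 2 * b^2 + 6)
}

#' @rdname quadexp_tvar
#' @export
quadexp_tail_variance <- function(level, alpha, beta) {
  .check_ab(alpha, beta)
  v <- qquadexp(level, alpha, beta)
  b <- beta; a <- alpha
  e2 <- exp(-b * v) / ((1 - level) * b^2 * .qe_D(a, b)) *
    (12 * v^2 * b^2 + 3 * v^2 * b^4 + 4 * v^3 * b^3 + v^3 * b^5 +
       v^4 * b^4 + 24 * v * b + 6 * b^2 + 6 * v * b^3 + 2 * a * b^2 +
       v^2 * a * b^4 + 2 * v * a * b^3 + 24)
  e2 - quadexp_tvar(level, alpha, beta)^2
}

#' Risk report at a level
#'
#' Bundles the actuarial measures at one probability level: value at
#' risk (the quantile), tail value at risk, tail variance, the mean
#' excess at the VaR (integral definition) and the limited expected
#' value at the VaR.
#'
#' @inheritParams quadexp_tvar
#' @return A list with elements `level`, `var`, `tvar`, `tv`,
#'   `mean_excess`, `limited_ev`.
#' @export
quadexp_risk <- function(level, alpha, beta) {
  .check_ab(alpha, beta)
  if (length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)")
  v <- qquadexp(level, alpha, beta)
  list(level = level, var = v,
       tvar = quadexp_tvar(level, alpha, beta),
       tv = quadexp_tail_variance(level, alpha, beta),
       mean_excess = quadexp_mean_excess(v, alpha, beta, form = "integral"),
       limited_ev = levquadexp(v, alpha, beta))
}

#' Likelihood-ratio order between two parameter pairs
#'
#' Sufficient conditions for \eqn{Z_1 \le_{lr} Z_2} when
#' \eqn{Z_i \sim} quadexp\eqn{(\alpha_i, \beta_i)}:
#' \eqn{\alpha_1 \ge \alpha_2}, \eqn{\beta_1 \ge \beta_2} and
#' \eqn{\alpha_1\beta_2 \ge \alpha_2\beta_1}.  When they hold the
#' density ratio \eqn{f_1/f_2} is nonincreasing, which implies the
#' hazard-rate and the usual stochastic order.
#'
#' @param alpha1,beta1,alpha2,beta2 two valid parameter pairs.
#' @return `TRUE` if the sufficient conditions hold.
#' @export
quadexp_lr_order <- function(alpha1, beta1, alpha2, beta2) {
  .check_ab(alpha1, beta1); .check_ab(alpha2, beta2)
  alpha1 >= alpha2 && beta1 >= beta2 && alpha1 * beta2 >= alpha2 * beta1
}
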