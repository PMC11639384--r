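## Competitor lifetime families for the model-comparison suite.
##
## All are standard one- or two-parameter positive distributions:
## Burr type X, exponential, the Nadarajah-Haghighi extension of the
## exponential, an XLindley variant (the equal-weight Exp/Gamma(2)
## mixture f(x) = (t/2)(1 + t x) e^{-t x}), and its reciprocal
## ("modified XLindley": the law of 1/X when X follows the XLindley
## variant).  The XLindley forms here are the ones that reproduce the
## published comparison tables for this distribution; they are
## normalization-checked by quadrature in the test suite.

#' Burr type X distribution
#'
#' CDF \eqn{(1 - e^{-(\theta x)^2})^\lambda} on `x > 0`.
#'
#' @param x,q nonnegative quantiles.
#' @param lambda,theta positive shape parameters.
#' @param log logical; return log-density.
#' @export
dburrx <- function(x, lambda, theta, log = FALSE) {
  stopifnot(lambda > 0, theta > 0)
  .check_x(x)
  t2 <- (theta * x)^2
  # log(1 - e^{-t}) via expm1; for t below double underflow use the
  # asymptote log t = 2 log(theta x) so tiny x cannot produce Inf * 0
  lg <- ifelse(t2 > 1e-280, log(-expm1(-t2)), 2 * log(theta * x))
  lf <- log(2 * lambda) + 2 * log(theta) + log(x) - t2 + (lambda - 1) * lg
  lf[x == 0] <- -Inf    # f ~ x^(2*lambda - 1) -> 0 at the origin
  if (log) lf else exp(lf)
}

#' @rdname dburrx
#' @export
pburrx <- function(q, lambda, theta) {
  stopifnot(lambda > 0, theta > 0)
  .check_x(q, "q")
  (-expm1(-(theta * q)^2))^lambda
}

#' Extension of the exponential distribution (Nadarajah-Haghighi)
#'
#' CDF \eqn{1 - \exp(1 - (1 + \theta x)^\alpha)} on `x > 0`.
#'
#' @param x,q nonnegative quantiles.
#' @param alpha,theta positive shape and rate parameters.
#' @param log logical; return log-density.
#' @export
dexpext <- function(x, alpha, theta, log = FALSE) {
  stopifnot(alpha > 0, theta > 0)
  .check_x(x)
  lf <- log(alpha) + log(theta) + (alpha - 1) * log1p(theta * x) +
    1 - (1 + theta * x)^alpha
  if (log) lf else exp(lf)
}

#' @rdname dexpext
#' @export
pexpext <- function(q, alpha, theta) {
  stopifnot(alpha > 0, theta > 0)
  .check_x(q, "q")
  1 - exp(1 - (1 + theta * q)^alpha)
}

#' XLindley variant (equal-weight Exp/Gamma(2) mixture)
#'
#' Density \eqn{(\theta/2)(1 + \theta x)e^{-\theta x}}, CDF
#' \eqn{1 - e^{-\theta x}(2 + \theta x)/2}.
#'
#' @param x,q nonnegative quantiles.
#' @param theta positive rate parameter.
#' @param log logical; return log-density.
#' @export
dxlindley <- function(x, theta, log = FALSE) {
  stopifnot(theta > 0)
  .check_x(x)
  lf <- log(theta / 2) + log1p(theta * x) - theta * x
  if (log) lf else exp(lf)
}

#' @rdname dxlindley
#' @export
pxlindley <- function(q, theta) {
  stopifnot(theta > 0)
  .check_x(q, "q")
  1 - exp(-theta * q) * (2 + theta * q) / 2
}

#' Modified XLindley (reciprocal XLindley variant)
#'
#' The law of `1/X` when `X` follows [dxlindley()]: density
#' \eqn{(\delta/(2x^2))(1 + \delta/x)e^{-\delta/x}}, CDF
#' \eqn{e^{-\delta/x}(2 + \delta/x)/2} on `x > 0`.
#'
#' @param x,q positive quantiles.
#' @param delta positive parameter.
#' @param log logical; return log-density.
#' @export
dmxlindley <- function(x, delta, log = FALSE) {
  stopifnot(delta > 0)
  if (any(x <= 0) || any(!is.finite(x))) stop("'x' must be positive")
  lf <- log(delta / 2) - 2 * log(x) + log1p(delta / x) - delta / x
  if (log) lf else exp(lf)
}

#' @rdname dmxlindley
#' @export
pmxlindley <- function(q, delta) {
  stopifnot(delta > 0)
  if (any(q < 0) || any(!is.finite(q))) stop("'q' must be nonnegative")
  out <- numeric(length(q))
  pos <- q > 0
  out[pos] <- exp(-delta / q[pos]) * (2 + delta / q[pos]) / 2
  out
}

## ---- family registry and maximum likelihood fits ------------------------

.families <- function() list(
  quadexp = list(
    k = 2,
    nll = function(p, x) -quadexp_loglik(x, p[1], p[2]),
    cdf = function(q, p) pquadexp(q, p[1], p[2]),
    pdf = function(x, p) dquadexp(x, p[1], p[2])),
  burrx = list(
    k = 2,
    nll = function(p, x) -sum(dburrx(x, p[1], p[2], log = TRUE)),
    cdf = function(q, p) pburrx(q, p[1], p[2]),
    pdf = function(x, p) dburrx(x, p[1], p[2])),
  exp = list(
    k = 1,
    nll = function(p, x) -sum(stats::dexp(x, p, log = TRUE)),
    cdf = function(q, p) stats::pexp(q, p),
    pdf = function(x, p) stats::dexp(x, p)),
  xlindley = list(
    k = 1,
    nll = function(p, x) -sum(dxlindley(x, p, log = TRUE)),
    cdf = function(q, p) pxlindley(q, p),
    pdf = function(x, p) dxlindley(x, p)),
  mxlindley = list(
    k = 1,
    nll = function(p, x) -sum(dmxlindley(x, p, log = TRUE)),
    cdf = function(q, p) pmxlindley(q, p),
    pdf = function(x, p) dmxlindley(x, p)),
  expext = list(
    k = 2,
    nll = function(p, x) -sum(dexpext(x, p[1], p[2], log = TRUE)),
    cdf = function(q, p) pexpext(q, p[1], p[2]),
    pdf = function(x, p) dexpext(x, p[1], p[2])))

#' Maximum likelihood fit of one comparison family
#'
#' @param x positive sample.
#' @param family one of `"quadexp"`, `"burrx"`, `"exp"`, `"xlindley"`,
#'   `"mxlindley"`, `"expext"`.
#' @return A list with `family`, `params`, `se` (observed-information
#'   standard errors, `NA` where the Hessian degenerates), `k`,
#'   `loglik`.
#' @examples
#' fit_family(quadexp_dataset("I"), "exp")  # rate = n / sum(x)
#' @export
fit_family <- function(x, family) {
  family <- match.arg(family, names(.families()))
  if (any(x <= 0) || any(!is.finite(x))) stop("data must be positive")
  fam <- .families()[[family]]
  m <- mean(x)
  if (family == "quadexp") {
    f <- fitquadexp(x, "mle")
    p <- c(f$alpha, f$beta); se <- unname(f$se)
  } else if (family == "exp") {
    p <- 1 / m                     # closed-form MLE n / sum(x)
    se <- p / sqrt(length(x))
  } else if (fam$k == 1) {
    o <- stats::optimize(function(lt) fam$nll(exp(lt), x), c(-14, 14),
                         tol = 1e-12)
    p <- exp(o$minimum)
    se <- .num_se(function(q) fam$nll(q, x), p)
  } else {
    starts <- list(c(1, 1 / m), c(0.5, 2 / m), c(2, 0.5 / m), c(1, 1))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        stats::optim(log(s), function(lp) {
          v <- fam$nll(exp(lp), x); if (!is.finite(v)) 1e10 else v
        }, control = list(maxit = 5000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    p <- exp(best$par)
    se <- .num_se(function(q) fam$nll(q, x), p)
  }
  list(family = family, params = p, se = se, k = fam$k,
       loglik = -fam$nll(p, x))
}

# observed-information SEs for an arbitrary negative log-likelihood
.num_se <- function(nll, p) {
  H <- tryCatch(stats::optimHess(p, nll), error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) return(rep(NA_real_, length(p)))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(diag(V) <= 0)) return(rep(NA_real_, length(p)))
  sqrt(diag(V))
}
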