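test_that("raw moments match the gamma closed form and quadrature", {
  expect_equal(mquadexp(0, 3, 0.4), 1)
  expect_equal(mquadexp(1, 1, 1), 2.25)  # (Gamma(4)+Gamma(3)+Gamma(2))/4
  pars <- rand_params(8, seed = 2L, range = c(0.1, 10))
  for (k in seq_len(nrow(pars))) {
    a <- pars$alpha[k]; b <- pars$beta[k]
    for (r in 1:4) {
      mq <- oracle_int(function(x) x^r * dquadexp(x, a, b))
      expect_equal(mquadexp(r, a, b), mq, tolerance = 1e-9)
    }
  }
  expect_error(mquadexp(-1, 1, 1), "nonnegative")
})

test_that("summary statistics are mutually consistent", {
  st <- quadexp_stats(1, 1)
  expect_equal(st$mean, 2.25)
  expect_equal(quadexp_stats(0.5, 0.1)$mean, 6.025 / 0.2015, tolerance = 1e-12)
  pars <- rand_params(6, seed = 13L)
  for (k in seq_len(nrow(pars))) {
    a <- pars$alpha[k]; b <- pars$beta[k]
    st <- quadexp_stats(a, b)
    expect_equal(st$mean, mquadexp(1, a, b), tolerance = 1e-12)
    expect_equal(st$variance, mquadexp(2, a, b) - mquadexp(1, a, b)^2)
    expect_equal(st$cv, st$sd / st$mean)
    expect_equal(st$skewness_raw, mquadexp(3, a, b) / st$variance^1.5)
    expect_equal(st$kurtosis_raw, mquadexp(4, a, b) / st$variance^2)
    expect_gt(st$variance, 0)
  }
})

test_that("mgf matches quadrature and differentiates to the mean", {
  expect_equal(mgfquadexp(0, 1.7, 0.9), 1, tolerance = 1e-14)
  for (p in list(c(1, 1), c(0.3, 2.5))) {
    a <- p[1]; b <- p[2]
    for (s in c(-1, 0.3 * b)) {
      # integrand assembled on the log scale so the tail cannot overflow
      expect_equal(mgfquadexp(s, a, b),
                   oracle_int(function(x)
                     exp(s * x + dquadexp(x, a, b, log = TRUE))),
                   tolerance = 1e-9)
    }
    h <- 1e-6 * b
    expect_equal((mgfquadexp(h, a, b) - mgfquadexp(-h, a, b)) / (2 * h),
                 quadexp_stats(a, b)$mean, tolerance = 1e-6)
  }
  expect_error(mgfquadexp(2, 1, 1), "s < beta")
})

test_that("incomplete moments interpolate between 0 and the full moment", {
  expect_equal(quadexp_inc_moment(1, 0, 1, 1), 0)
  expect_equal(quadexp_inc_moment(2, 1e4, 1, 1), mquadexp(2, 1, 1))
  expect_lt(abs(quadexp_inc_moment(1, 2, 1, 1) -
                  oracle_int(function(x) x * dquadexp(x, 1, 1), 0, 2)), 1e-10)
  pars <- rand_params(5, seed = 5L, range = c(0.1, 10))
  for (k in seq_len(nrow(pars))) {
    a <- pars$alpha[k]; b <- pars$beta[k]
    s <- 1.7 / b
    expect_equal(quadexp_inc_moment(2, s, a, b),
                 oracle_int(function(x) x^2 * dquadexp(x, a, b), 0, s),
                 tolerance = 1e-9)
  }
})

test_that("mean residual life and mean waiting time behave correctly", {
  m <- quadexp_stats(1, 1)$mean
  expect_equal(quadexp_mrl(1e-9, 1, 1), m, tolerance = 1e-6)
  mrl5 <- quadexp_mrl(5, 1, 1)
  byq <- oracle_int(function(u) pquadexp(u, 1, 1, lower.tail = FALSE), 5, Inf) /
    pquadexp(5, 1, 1, lower.tail = FALSE)
  expect_lt(abs(mrl5 - byq), 1e-8)
  for (t in c(0.5, 2, 7)) {
    w <- quadexp_mwt(t, 1, 1)
    expect_gt(w, 0); expect_lt(w, t)
  }
  expect_error(quadexp_mrl(0, 1, 1), "positive")
})

test_that("Lorenz curve is below the diagonal, increasing and convex", {
  u <- seq(0.05, 0.95, by = 0.05)
  for (p in list(c(1, 1), c(0.4, 3))) {
    L <- quadexp_lorenz(u, p[1], p[2])
    expect_true(all(L <= u))
    expect_true(all(diff(L) > 0))
    expect_true(all(diff(diff(L)) > -1e-10))  # convex on the grid
    expect_equal(quadexp_bonferroni(u, p[1], p[2]), L / u)
  }
  expect_equal(quadexp_lorenz(0.999999, 1, 1), 1, tolerance = 1e-4)
  q5 <- qquadexp(0.5, 1, 1)
  expect_lt(abs(quadexp_lorenz(0.5, 1, 1) -
                  oracle_int(function(x) x * dquadexp(x, 1, 1), 0, q5) /
                  quadexp_stats(1, 1)$mean), 1e-9)
})

test_that("Renyi entropy series equals the quadrature route", {
  expect_lt(abs(quadexp_renyi(2, 1, 1, "series") -
                  quadexp_renyi(2, 1, 1, "quadrature")), 1e-8)
  expect_lt(abs(quadexp_renyi(3, 0.6, 0.9, "series") -
                  quadexp_renyi(3, 0.6, 0.9, "quadrature")), 1e-8)
  pars <- rand_params(5, seed = 23L, range = c(0.2, 5))
  for (k in seq_len(nrow(pars))) {
    for (s in 2:4) {
      expect_lt(abs(quadexp_renyi(s, pars$alpha[k], pars$beta[k], "series") -
                      quadexp_renyi(s, pars$alpha[k], pars$beta[k],
                                    "quadrature")), 1e-7)
    }
  }
  # non-integer orders go through quadrature and are finite
  expect_true(is.finite(quadexp_renyi(0.5, 1, 1)))
  expect_error(quadexp_renyi(1, 1, 1), "different from 1")
})

test_that("fuzzy reliability is monotone in the cut and the knots", {
  a <- 1; b <- 0.75
  expect_equal(quadexp_fuzzy_rel(1, 2, 0, a, b), 0)
  expect_equal(quadexp_fuzzy_rel(1, 2, 1, a, b),
               pquadexp(1, a, b, lower.tail = FALSE) -
                 pquadexp(2, a, b, lower.tail = FALSE))
  lam <- seq(0, 1, by = 0.1)
  # parameter/knot configurations of the kind used in published fuzzy
  # reliability tables for this family (moderate rates, knots below the
  # bulk of the mass); the t1-antitonicity is a property of this regime,
  # not of arbitrary knot placements
  for (p in list(c(1, 0.75), c(1.2, 1.5))) {
    r <- quadexp_fuzzy_rel(0.5, 3, lam, p[1], p[2])
    expect_true(all(diff(r) > 0))                       # increasing in lambda
    expect_true(all(r <= pquadexp(0.5, p[1], p[2], lower.tail = FALSE)))
    # increasing in t2, decreasing in t1 at fixed lambda
    r_t2 <- sapply(c(1, 2, 4), function(t2)
      quadexp_fuzzy_rel(0.5, t2, 0.55, p[1], p[2]))
    expect_true(all(diff(r_t2) > 0))
    r_t1 <- sapply(c(0.1, 0.5, 1), function(t1)
      quadexp_fuzzy_rel(t1, 3, 0.55, p[1], p[2]))
    expect_true(all(diff(r_t1) < 0))
  }
  expect_error(quadexp_fuzzy_rel(2, 1, 0.5, 1, 1), "t1 < t2")
})

test_that("the two mean-excess forms are both available and distinct", {
  # closed product form reproduces the published table (half a unit in
  # the last printed digit)
  expect_lt(abs(quadexp_mean_excess(0.5, 0.5, 0.5, "closed") - 8.2438), 5e-5)
  expect_lt(abs(quadexp_mean_excess(0.1, 6, 2, "closed") - 0.68797), 5e-6)
  expect_equal(quadexp_mean_excess(1, 1, 1, "closed"), 7.5,
               tolerance = 1e-12)
  # integral definition: quadrature of S over S, tends to 1/beta
  ei <- quadexp_mean_excess(0.5, 0.5, 0.5, "integral")
  direct <- oracle_int(function(u) pquadexp(u, 0.5, 0.5, lower.tail = FALSE),
                       0.5, Inf) / pquadexp(0.5, 0.5, 0.5, lower.tail = FALSE)
  expect_equal(ei, direct, tolerance = 1e-10)
  expect_gt(abs(ei - 8.2438), 1)   # the forms genuinely disagree
  # the integral form tends to 1/beta (slowly, with an O(1/x) correction)
  expect_equal(quadexp_mean_excess(500, 1, 1, "integral"), 1,
               tolerance = 5e-3)
  expect_error(quadexp_mean_excess(1, 1, 1), "form")
})

test_that("limited expected value satisfies its identities", {
  for (p in list(c(1, 1), c(0.5, 2), c(4, 0.3))) {
    a <- p[1]; b <- p[2]
    m <- quadexp_stats(a, b)$mean
    u <- 1.3 / b
    lev <- levquadexp(u, a, b)
    expect_equal(lev, quadexp_inc_moment(1, u, a, b) +
                   u * pquadexp(u, a, b, lower.tail = FALSE),
                 tolerance = 1e-12)
    # layer decomposition E(X ^ u) + int_u^Inf S = E[X]
    tail <- oracle_int(function(t) pquadexp(t, a, b, lower.tail = FALSE),
                       u, Inf)
    expect_lt(abs(lev + tail - m), 1e-9)
    expect_equal(levquadexp(500 / b, a, b), m, tolerance = 1e-10)
    expect_lt(levquadexp(1e-8, a, b), 1e-6)
  }
  expect_error(levquadexp(0, 1, 1), "positive")
})

test_that("tail value at risk and tail variance match conditional moments", {
  for (p in list(c(1, 1), c(0.5, 0.1), c(2, 3))) {
    a <- p[1]; b <- p[2]
    for (lev in c(0.7, 0.9)) {
      v <- qquadexp(lev, a, b)
      tv1 <- quadexp_tvar(lev, a, b)
      expect_gt(tv1, v)
      byq <- oracle_int(function(x) x * dquadexp(x, a, b), v, Inf) / (1 - lev)
      expect_equal(tv1, byq, tolerance = 1e-7)
      tvv <- quadexp_tail_variance(lev, a, b)
      e2 <- oracle_int(function(x) x^2 * dquadexp(x, a, b), v, Inf) / (1 - lev)
      expect_equal(tvv, e2 - byq^2, tolerance = 1e-6)
      expect_gt(tvv, 0)
      # TVaR(p)(1-p) + T1(VaR) = E[X]
      expect_lt(abs(tv1 * (1 - lev) + quadexp_inc_moment(1, v, a, b) -
                      quadexp_stats(a, b)$mean), 1e-9)
    }
  }
  rr <- quadexp_risk(0.9, 1, 1)
  expect_equal(rr$var, qquadexp(0.9, 1, 1))
  expect_gt(rr$tvar, rr$var)
  expect_gt(rr$tv, 0)
})

test_that("likelihood-ratio order conditions imply a monotone ratio", {
  expect_true(quadexp_lr_order(1, 1, 1, 1))
  expect_true(quadexp_lr_order(2, 2, 1, 1))
  lr <- function(t, p1, p2) dquadexp(t, p1[1], p1[2], log = TRUE) -
    dquadexp(t, p2[1], p2[2], log = TRUE)
  tg <- seq(0.01, 30, length = 500)
  expect_true(all(diff(lr(tg, c(2, 2), c(1, 1))) <= 1e-12))
  # randomized condition-satisfying pairs
  set.seed(77)
  good <- 0
  while (good < 30) {
    a2 <- runif(1, 0.1, 4); b2 <- runif(1, 0.1, 3)
    a1 <- a2 * runif(1, 1, 3); b1 <- b2 * runif(1, 1, 3)
    if (!(a1 * b2 >= a2 * b1)) next
    good <- good + 1
    expect_true(quadexp_lr_order(a1, b1, a2, b2))
    tg <- seq(0.01, 20 / min(b1, b2), length = 400)
    expect_true(all(diff(lr(tg, c(a1, b1), c(a2, b2))) <= 1e-10))
  }
})
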