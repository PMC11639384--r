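# Quadrature oracle and randomized parameter draws shared by the tests.

# adaptive quadrature over (lo, hi), independent of the package's
# internal closed forms
oracle_int <- function(f, lo = 0, hi = Inf, rel.tol = 1e-12) {
  integrate(f, lo, hi, rel.tol = rel.tol, subdivisions = 1000L)$value
}

# log-uniform parameter draws on [0.05, 20]^2 under a fixed seed
rand_params <- function(n, seed = 421L, range = c(0.05, 20)) {
  set.seed(seed)
  lr <- log(range)
  data.frame(alpha = exp(runif(n, lr[1], lr[2])),
             beta = exp(runif(n, lr[1], lr[2])))
}

qe_pdf_direct <- function(x, a, b) {
  # term-by-term evaluation of the density, independent of dquadexp's
  # log-scale path
  b^3 / (b^2 + a * b^2 + 2) * (a + b * x + x^2) * exp(-b * x)
}
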