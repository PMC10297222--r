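# Independent numeric oracles used across test files.

# Mixture pmf by adaptive quadrature: integrate dpois(k, phi*y) against the
# density of phi | y_prev. Independent of the closed forms in the package.
quadrature_thinning_pmf <- function(k, y, A, family,
                                    exp_convention = "mean") {
  if (y == 0) return(as.numeric(k == 0))
  if (family == "fixed") return(stats::dpois(k, A * y))
  if (k == 0) {
    # integrate on the probability scale (phi = quantile(u)): the
    # chi-square density's integrable singularity at 0 then causes no
    # trouble, and the k = 0 integrand has no far-tail spike
    qfun <- switch(family,
      uniform = function(u) stats::qunif(u, 0, 2 * A),
      exponential = if (exp_convention == "mean")
        function(u) stats::qexp(u, rate = 1 / A)
      else function(u) stats::qexp(u, rate = A),
      chisquare = function(u) stats::qgamma(u, shape = A / 2, scale = 2))
    f <- function(u) stats::dpois(0, qfun(u) * y)
    return(stats::integrate(f, 0, 1, rel.tol = 1e-11, abs.tol = 1e-13,
                            subdivisions = 1000L)$value)
  }
  # k >= 1: the phi^k factor kills the origin singularity; integrate in phi
  # space, centring the range on the Poisson spike near phi = k/y
  dens <- switch(family,
    uniform = function(p) stats::dunif(p, 0, 2 * A),
    exponential = if (exp_convention == "mean")
      function(p) stats::dexp(p, rate = 1 / A)
    else function(p) stats::dexp(p, rate = A),
    chisquare = function(p) stats::dgamma(p, shape = A / 2, scale = 2))
  f <- function(p) stats::dpois(k, p * y) * dens(p)
  upper <- if (family == "uniform") 2 * A else
    max(10 * A, 4 * (k + 10) / y)
  cut <- min(k / y, upper)
  (stats::integrate(f, 0, cut, rel.tol = 1e-11, abs.tol = 1e-16,
                    subdivisions = 1000L)$value +
     if (cut < upper)
       stats::integrate(f, cut, upper, rel.tol = 1e-11, abs.tol = 1e-16,
                        subdivisions = 1000L)$value else 0)
}

# central finite-difference gradient
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    hp <- h * max(1, abs(x[j]))
    xp <- xm <- x; xp[j] <- xp[j] + hp; xm[j] <- xm[j] - hp
    (f(xp) - f(xm)) / (2 * hp)
  }, numeric(1))
}

theta0_ref <- c(1, -0.6, 1.2)
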