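test_that("conditional intensity mean is the logistic of the link", {
  expect_equal(conditional_phi_mean(0, c(0, 0)), 0.5)
  expect_equal(conditional_phi_mean(2, c(1, -0.6)), 0.450166, tolerance = 1e-6)
  expect_equal(conditional_phi_mean(0, c(1, -0.6)), 0.731059, tolerance = 1e-6)
  # no overflow on extreme link values
  expect_equal(conditional_phi_mean(0, c(700, 0)), 1)
  expect_equal(conditional_phi_mean(0, c(-700, 0)), 0, tolerance = 1e-12)
  expect_error(conditional_phi_mean(1, c(1, 2, 3)), "length")
})

test_that("thinning pmf closed forms match the spot values", {
  expect_equal(thinning_pmf(3, 0, 0.5), 0)
  expect_equal(thinning_pmf(0, 0, 0.5, "chisquare"), 1)
  expect_equal(thinning_pmf(1, 2, 0.45), dpois(1, 0.9))
  expect_equal(thinning_pmf(0, 1, 0.5, "uniform"), 1 - exp(-1),
               tolerance = 1e-9)
  expect_equal(thinning_pmf(0, 1, 0.5, "exponential"), 2 / 3,
               tolerance = 1e-9)
  # chi-square at k = 0 collapses to (1 + 2y)^(-A/2)
  expect_equal(thinning_pmf(0, 1, 0.999, "chisquare"), 3^(-0.999 / 2),
               tolerance = 1e-9)
  expect_error(thinning_pmf(1, 2, 1.2), "0, 1")
  expect_error(thinning_pmf(-1, 2, 0.5), "non-negative")
})

test_that("every closed-form mixture pmf agrees with adaptive quadrature", {
  for (fam in c("fixed", "uniform", "exponential", "chisquare")) {
    for (A in c(0.1, 0.45, 0.9)) {
      for (y in c(1, 5, 20)) {
        ks <- c(0:5, 10, 30)
        closed <- thinning_pmf(ks, y, A, fam)
        quad <- vapply(ks, quadrature_thinning_pmf, numeric(1),
                       y = y, A = A, family = fam)
        expect_equal(closed, quad, tolerance = 1e-8,
                     label = sprintf("family %s, A=%.2f, y=%d", fam, A, y))
      }
    }
  }
})

test_that("rate-convention exponential pmf matches its rate-A mixture", {
  ks <- 0:10
  closed <- thinning_pmf(ks, 3, 0.45, "exponential", exp_convention = "rate")
  quad <- vapply(ks, quadrature_thinning_pmf, numeric(1), y = 3, A = 0.45,
                 family = "exponential", exp_convention = "rate")
  expect_equal(closed, quad, tolerance = 1e-10)
})

test_that("thinned-component mean under the mean convention is A*y", {
  for (fam in c("uniform", "exponential", "chisquare")) {
    ks <- 0:400
    p <- thinning_pmf(ks, 4, 0.45, fam)
    expect_equal(sum(p), 1, tolerance = 1e-8)
    expect_equal(sum(ks * p), 0.45 * 4, tolerance = 1e-6,
                 label = paste("mean for", fam))
  }
})

test_that("transition pmf convolves thinning with innovations and normalises", {
  sp <- odinar_spec()
  th <- theta0_ref
  # thinning of zero is zero: transition from 0 is the innovation pmf
  expect_equal(transition_pmf(0:6, 0, th, sp), dpois(0:6, 1.2))
  expect_equal(transition_pmf(1, 0, th, sp), 1.2 * exp(-1.2))
  for (fam in c("fixed", "uniform", "exponential", "chisquare")) {
    spf <- odinar_spec(fam)
    tot <- sum(transition_pmf(0:200, 5, th, spf))
    expect_equal(tot, 1, tolerance = 1e-10, label = fam)
  }
  spg <- odinar_spec(innovation = "geometric")
  expect_equal(sum(transition_pmf(0:400, 5, th, spg)), 1, tolerance = 1e-10)
})

test_that("conditional mean and variance match the transition distribution", {
  th <- theta0_ref
  expect_equal(conditional_mean(0, th), 1.2)
  expect_equal(conditional_mean(2, th), 0.450166 * 2 + 1.2, tolerance = 1e-6)
  ys <- 0:300
  for (fam in c("fixed", "uniform", "chisquare")) {
    spf <- odinar_spec(fam)
    p <- transition_pmf(ys, 4, th, spf)
    mu <- sum(ys * p)
    v <- sum((ys - mu)^2 * p)
    expect_equal(mu, conditional_mean(4, th), tolerance = 1e-8, label = fam)
    expect_equal(v, conditional_variance(4, th, spf), tolerance = 1e-6,
                 label = fam)
  }
  # variance from the origin is the innovation variance alone
  expect_equal(conditional_variance(0, th, odinar_spec()), 1.2)
  # fixed family: A*y + lambda
  A <- conditional_phi_mean(3, th[1:2])
  expect_equal(conditional_variance(3, th, odinar_spec()), A * 3 + 1.2)
})

test_that("stationarity check warns only for a positive slope", {
  expect_silent(stationarity_check(c(1, -0.6)))
  expect_silent(stationarity_check(c(1, 0)))
  expect_warning(stationarity_check(c(1, 0.1)), "stationary")
})

test_that("custom links reproduce the linear link and check gradients", {
  lk <- link_custom(function(y, beta) beta[1] + beta[2] * y, dim = 2)
  expect_equal(conditional_phi_mean(2, c(1, -0.6), lk),
               conditional_phi_mean(2, c(1, -0.6)))
  # finite-difference gradient of the custom link matches the analytic one
  g_fd <- lk$grad(c(0, 2, 5), c(1, -0.6))
  g_an <- link_linear()$grad(c(0, 2, 5), c(1, -0.6))
  expect_equal(g_fd, g_an, tolerance = 1e-6, ignore_attr = TRUE)
})
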