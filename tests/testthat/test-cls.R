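test_that("estimating function matches -1/2 the gradient of the squared error", {
  th <- theta0_ref
  # residual zero implies a zero vector
  lam_exact <- 3 - conditional_phi_mean(2, th[1:2]) * 2
  expect_equal(mt_vector(3, 2, c(th[1:2], lam_exact)), rep(0, 3),
               ignore_attr = TRUE)
  # against the numeric-differentiation oracle on several transitions
  for (pair in list(c(3, 2), c(0, 1), c(7, 4))) {
    m <- mt_vector(pair[1], pair[2], th)
    st <- function(theta) {
      (pair[1] - conditional_phi_mean(pair[2], theta[1:2]) * pair[2] -
         theta[3])^2
    }
    expect_equal(unname(m), -0.5 * num_grad(st, th), tolerance = 1e-6)
  }
})

test_that("CLS solves the estimating equations and recovers the truth", {
  sp <- odinar_spec()
  y <- odinar_simulate(theta0_ref, sp, n = 2000, seed = 101)
  f <- cls_fit(y)
  expect_s3_class(f, "odinar_fit")
  expect_true(f$converged)
  M <- vapply(2:length(y), function(t)
    mt_vector(y[t], y[t - 1], coef(f)), numeric(3))
  expect_lt(sqrt(sum(rowSums(M)^2)), 1e-6 * (length(y) - 1))
  se <- sqrt(diag(vcov(f)))
  expect_true(all(abs(coef(f) - theta0_ref) < 4 * se))
  expect_error(cls_fit(rep(0L, 50)), "degenerate")
})

test_that("CLS interval estimates are calibrated across replicates", {
  sp <- odinar_spec()
  reps <- 60
  hit <- matrix(FALSE, reps, 3)
  for (r in seq_len(reps)) {
    y <- odinar_simulate(theta0_ref, sp, n = 1200, seed = 500 + r)
    f <- cls_fit(y)
    if (!f$converged || is.null(vcov(f))) next
    se <- sqrt(diag(vcov(f)))
    hit[r, ] <- abs(coef(f) - theta0_ref) <= 1.96 * se
  }
  cov <- colMeans(hit)
  # binomial 3-sigma band around 0.95 at 60 replicates is about +-0.084
  expect_true(all(cov > 0.95 - 0.09))
})

test_that("sandwich pieces match a finite-difference Jacobian oracle", {
  sp <- odinar_spec()
  y <- odinar_simulate(theta0_ref, sp, n = 600, seed = 33)
  f <- cls_fit(y)
  th <- coef(f)
  V <- odinar:::cls_curvature(y, th, link_linear())
  # oracle: -d(mean Mt)/d theta', by central differences
  mbar <- function(theta) {
    M <- vapply(2:length(y), function(t)
      mt_vector(y[t], y[t - 1], theta), numeric(3))
    rowMeans(M)
  }
  J <- vapply(1:3, function(j) {
    h <- 1e-5 * max(1, abs(th[j]))
    tp <- tm <- th; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (mbar(tp) - mbar(tm)) / (2 * h)
  }, numeric(3))
  expect_equal(V, -(J + t(J)) / 2, tolerance = 1e-4, ignore_attr = TRUE)
  S <- sandwich_cov(y, th)
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8))
})

test_that("H statistic vanishes at the CLS fit and defines a monotone test", {
  sp <- odinar_spec()
  y <- odinar_simulate(theta0_ref, sp, n = 500, seed = 71)
  f <- cls_fit(y)
  expect_lt(h_statistic(y, coef(f)), 1e-8)
  tst <- confidence_region_test(y, coef(f), alpha = 0.95)
  expect_false(tst$reject)
  expect_identical(tst$df, 3L)
  # away from the fit the statistic is positive and the quantile convention
  # makes a 0.95-level rejection imply a 0.90-level rejection
  H <- h_statistic(y, theta0_ref + c(0, 0, 0.4))
  expect_gt(H, 0)
  t95 <- confidence_region_test(y, theta0_ref + c(0, 0, 0.4), 0.95)
  t90 <- confidence_region_test(y, theta0_ref + c(0, 0, 0.4), 0.90)
  expect_gt(t95$critical_value, t90$critical_value)
  if (t95$reject) expect_true(t90$reject)
})

test_that("H(theta0) follows its chi-square reference distribution", {
  sp <- odinar_spec()
  H <- vapply(1:400, function(r) {
    y <- odinar_simulate(theta0_ref, sp, n = 1000, seed = 9000 + r)
    h_statistic(y, theta0_ref)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(H, pchisq, df = 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("estimates are invariant to the phi family at matched seeds", {
  # CLS only sees the conditional mean, so uniform vs fixed data of the
  # same length should give estimates differing only by sampling noise
  est <- sapply(c("fixed", "uniform"), function(fam) {
    y <- odinar_simulate(theta0_ref, odinar_spec(fam), n = 2000, seed = 55)
    coef(cls_fit(y))
  })
  expect_lt(max(abs(est[, 1] - est[, 2])), 0.35)
})
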