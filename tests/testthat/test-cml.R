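test_that("negative log-likelihood spot values and structure", {
  sp <- odinar_spec()
  # an all-zero series of n+1 counts contributes n * lambda
  n <- 12
  nl <- negloglik(rep(0L, n + 1), c(1, -0.6, 1.2), sp)
  expect_equal(nl$value, n * 1.2, tolerance = 1e-12)
  expect_length(nl$terms, n)
  expect_equal(nl$value, sum(nl$terms))
  expect_equal(negloglik(c(0L, 1L), c(1, -0.6, 1.2), sp)$value,
               -log(1.2 * exp(-1.2)), tolerance = 1e-12)
  expect_error(negloglik(c(0, 1), c(1, -0.6, -1), sp), "lambda")
})

test_that("vectorised likelihood equals the generic mixture on random triples", {
  set.seed(42)
  for (fam in c("fixed", "uniform", "exponential", "chisquare")) {
    sp <- odinar_spec(fam)
    for (i in 1:25) {
      yprev <- sample(0:12, 1)
      yt <- sample(0:12, 1)
      th <- c(runif(1, -1, 2), runif(1, -1, 0), runif(1, 0.3, 3))
      direct <- -log(transition_pmf(yt, yprev, th, sp))
      viaterms <- negloglik(c(yprev, yt), th, sp)$terms
      expect_equal(viaterms, direct, tolerance = 1e-10,
                   label = paste(fam, yprev, yt))
    }
  }
})

test_that("CML recovers parameters and approaches CLS in large samples", {
  sp <- odinar_spec()
  y <- odinar_simulate(theta0_ref, sp, n = 2000, seed = 303)
  fm <- cml_fit(y)
  expect_true(fm$converged)
  se <- sqrt(diag(vcov(fm)))
  expect_true(all(abs(coef(fm) - theta0_ref) < 4 * se))
  fl <- cls_fit(y)
  expect_lt(abs(coef(fm)["lambda"] - coef(fl)["lambda"]), 0.05)
  # score condition at the optimum
  S <- odinar:::score_matrix(y, coef(fm), sp)
  expect_lt(sqrt(sum(colSums(S)^2)), 1e-3 * nrow(S))
})

test_that("matched-family CML recovery holds for every random family", {
  # scaled-down replication study: T = 800, 40 replicates per family;
  # bias must stay within 3 Monte-Carlo standard errors
  for (fam in c("uniform", "exponential", "chisquare")) {
    sp <- odinar_spec(fam)
    est <- t(vapply(1:40, function(r) {
      y <- odinar_simulate(theta0_ref, sp, n = 800, seed = 4000 + r)
      coef(cml_fit(y))
    }, numeric(3)))
    for (j in 1:3) {
      bias <- mean(est[, j]) - theta0_ref[j]
      se <- sd(est[, j]) / sqrt(nrow(est))
      expect_lt(abs(bias), 3.5 * se,
                label = sprintf("%s, parameter %d", fam, j))
    }
  }
})

test_that("Fisher covariance is PSD and consistent with the Hessian", {
  sp <- odinar_spec()
  y <- odinar_simulate(theta0_ref, sp, n = 2000, seed = 505)
  f <- cml_fit(y)
  E <- fisher_cov(y, coef(f), sp)
  expect_equal(E, t(E))
  ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # observed-information cross-check: numerical Hessian of negll / (T-1)
  nl <- function(th) negloglik(y, th, sp)$value / (length(y) - 1)
  th <- coef(f); p <- length(th)
  H <- matrix(0, p, p)
  h <- 1e-4
  for (i in 1:p) for (j in i:p) {
    ei <- ej <- rep(0, p); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (nl(th + ei + ej) - nl(th + ei - ej) -
         nl(th - ei + ej) + nl(th - ei - ej)) / (4 * h^2)
  }
  ratio <- diag(solve(H)) / diag(E)
  expect_true(all(ratio > 0.85 & ratio < 1.15))
})

test_that("misspecified innovations bias the CML rate downward", {
  # geometric data fitted with a Poisson likelihood (uniform intensity):
  # lambda-hat should sit below the truth, as the robustness study reports
  sim_sp <- odinar_spec("uniform", innovation = "geometric")
  fit_sp <- odinar_spec("uniform", innovation = "poisson")
  lam <- vapply(1:30, function(r) {
    y <- odinar_simulate(theta0_ref, sim_sp, n = 800, seed = 6000 + r)
    coef(cml_fit(y, fit_sp))["lambda"]
  }, numeric(1))
  expect_lt(mean(lam) - 1.2, 0)
  expect_lt(mean(lam) - 1.2, -2 * sd(lam) / sqrt(length(lam)))
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(100, 3, 267)
  expect_equal(ic[["AIC"]], 206)
  expect_equal(ic[["BIC"]] - ic[["AIC"]], 3 * (log(267) - 2))
  expect_equal(information_criteria(50, 0, 100)[["AIC"]], 100)
})
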