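## Probabilistic core: conditional coefficient mean, Poisson-thinning mixture
## pmfs for each coefficient family, one-step transition probability, and
## conditional moments of the chain.

#' Conditional mean of the thinning intensity
#'
#' Computes \eqn{A(y) = \exp(\nu(y;\beta)) / (1 + \exp(\nu(y;\beta)))}, the
#' conditional expectation of the thinning intensity \eqn{\phi_t} given
#' \eqn{Y_{t-1} = y}. Evaluated on the stable branch so that \eqn{|\nu|}
#' up to several hundred does not overflow.
#'
#' @param y_prev non-negative integer (vectorised), the previous count.
#' @param beta coefficient vector of length `link$dim`.
#' @param link an [link_linear()] / [link_custom()] object.
#' @return Values in (0, 1).
#' @examples
#' conditional_phi_mean(2, c(1, -0.6))  # logistic(-0.2)
#' @export
conditional_phi_mean <- function(y_prev, beta, link = link_linear()) {
  if (length(beta) != link$dim)
    stop("beta must have length ", link$dim, call. = FALSE)
  if (any(y_prev < 0)) stop("y_prev must be non-negative", call. = FALSE)
  nu <- link$nu(y_prev, beta)
  # stable logistic: never exponentiate a large positive argument
  ifelse(nu >= 0, 1 / (1 + exp(-nu)), exp(nu) / (1 + exp(nu)))
}

## log pmf of the thinned component (sum of y_prev iid Poisson(phi) given phi,
## phi integrated over its conditional law) -- vectorised over k/y/A jointly.
thinning_lpmf <- function(k, y_prev, A, phi = "fixed",
                          exp_convention = "mean") {
  n <- max(length(k), length(y_prev), length(A))
  k <- rep_len(k, n); y <- rep_len(y_prev, n); A <- rep_len(A, n)
  out <- numeric(n)
  zero <- y == 0
  out[zero] <- ifelse(k[zero] == 0, 0, -Inf)
  if (any(!zero)) {
    k <- k[!zero]; yy <- y[!zero]; A2 <- A[!zero]
    v <- switch(phi,
      fixed = stats::dpois(k, A2 * yy, log = TRUE),
      uniform = {
        # mixture over phi ~ U(0, 2A): gamma(k+1, 2Ay) / (2Ay k!)
        x <- 2 * A2 * yy
        stats::pgamma(x, shape = k + 1, log.p = TRUE) - log(x)
      },
      exponential = {
        if (exp_convention == "mean") {
          # phi ~ Exp(mean A): (Ay)^k / (Ay+1)^(k+1)
          k * log(A2 * yy) - (k + 1) * log1p(A2 * yy)
        } else {
          # printed form: phi ~ Exp(rate A): A y^k / (A+y)^(k+1)
          log(A2) + k * log(yy) - (k + 1) * log(A2 + yy)
        }
      },
      chisquare = {
        # phi ~ chi-square with df A (gamma shape A/2, scale 2)
        k * log(yy) - lgamma(k + 1) - (A2 / 2) * log(2) - lgamma(A2 / 2) +
          lgamma(k + A2 / 2) - (k + A2 / 2) * log(yy + 0.5)
      },
      stop("unknown phi family: ", phi, call. = FALSE))
    out[!zero] <- v
  }
  out
}

#' Probability mass function of the thinned component
#'
#' Probability that \eqn{\phi_t \ominus Y_{t-1}} equals `k` given
#' \eqn{Y_{t-1} = } `y_prev` and a conditional intensity mean `A`, with
#' \eqn{\phi_t} integrated over the chosen conditional family. Conditional
#' on \eqn{\phi} the thinned sum is Poisson(\eqn{\phi \, y_{t-1}}); the
#' closed forms here are the exact mixtures (Poisson, uniform-incomplete
#' gamma, geometric-type, and negative-binomial-type kernels).
#'
#' @param k non-negative integer, value of the thinned component.
#' @param y_prev non-negative integer, the previous count.
#' @param A conditional mean of the intensity, in (0, 1).
#' @param phi coefficient family, see [odinar_spec()].
#' @param exp_convention `"mean"` or `"rate"` (exponential family only).
#' @return Probabilities (vectorised over `k`).
#' @examples
#' thinning_pmf(1, 2, 0.45)            # dpois(1, 0.9)
#' thinning_pmf(0, 1, 0.5, "uniform")  # (1 - exp(-1))
#' @export
thinning_pmf <- function(k, y_prev, A, phi = "fixed",
                         exp_convention = "mean") {
  phi <- match.arg(phi, PHI_FAMILIES)
  if (any(k < 0) || any(k != floor(k)))
    stop("k must be a non-negative integer", call. = FALSE)
  if (any(y_prev < 0) || any(y_prev != floor(y_prev)))
    stop("y_prev must be a non-negative integer", call. = FALSE)
  if (any(A <= 0) || any(A >= 1))
    stop("A must lie in (0, 1)", call. = FALSE)
  exp(thinning_lpmf(k, y_prev, A, phi, exp_convention))
}

## innovation log pmf, mean lambda
innov_lpmf <- function(z, lambda, innovation = "poisson") {
  out <- rep(-Inf, length(z))
  ok <- z >= 0
  if (innovation == "poisson") {
    out[ok] <- stats::dpois(z[ok], lambda, log = TRUE)
  } else {
    out[ok] <- stats::dgeom(z[ok], prob = 1 / (1 + lambda), log = TRUE)
  }
  out
}

#' One-step transition probability
#'
#' \eqn{P(Y_t = y \mid Y_{t-1} = y_{prev})} for the observation-driven
#' INAR(1) chain: the convolution of the thinned-component mixture pmf with
#' the innovation pmf, summed over the split \eqn{k + z = y}.
#'
#' @param y_t non-negative integer (vectorised), current count.
#' @param y_prev non-negative integer, previous count.
#' @param theta parameter vector `c(beta, lambda)`.
#' @param spec an [odinar_spec()].
#' @return Transition probabilities.
#' @examples
#' sp <- odinar_spec()
#' transition_pmf(1, 0, c(1, -0.6, 1.2), sp)  # dpois(1, 1.2)
#' @export
transition_pmf <- function(y_t, y_prev, theta, spec = odinar_spec()) {
  stopifnot(inherits(spec, "odinar_spec"))
  th <- split_theta(theta, spec$link)
  if (th$lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (any(y_t < 0) || y_prev < 0) stop("counts must be non-negative",
                                       call. = FALSE)
  A <- conditional_phi_mean(y_prev, th$beta, spec$link)
  vapply(y_t, function(yt) {
    k <- 0:yt
    lt <- thinning_lpmf(k, y_prev, A, spec$phi, spec$exp_convention)
    lz <- innov_lpmf(yt - k, th$lambda, spec$innovation)
    sum(exp(lt + lz))
  }, numeric(1))
}

#' Conditional mean and variance of the next count
#'
#' `conditional_mean()` returns \eqn{E(Y_t \mid Y_{t-1}) = A(Y_{t-1})
#' Y_{t-1} + \lambda}, the regression function that conditional least
#' squares targets. `conditional_variance()` returns the total-variance
#' decomposition \eqn{A y + y^2 \mathrm{Var}(\phi \mid y) + \sigma^2_Z}
#' (diagnostic use).
#'
#' @inheritParams transition_pmf
#' @param link an `odinar_link` (for `conditional_mean`).
#' @return Real scalar (vectorised over `y_prev`).
#' @examples
#' conditional_mean(2, c(1, -0.6, 1.2))
#' @export
conditional_mean <- function(y_prev, theta, link = link_linear()) {
  th <- split_theta(theta, link)
  conditional_phi_mean(y_prev, th$beta, link) * y_prev + th$lambda
}

#' @rdname conditional_mean
#' @export
conditional_variance <- function(y_prev, theta, spec = odinar_spec()) {
  th <- split_theta(theta, spec$link)
  A <- conditional_phi_mean(y_prev, th$beta, spec$link)
  vphi <- switch(spec$phi,
    fixed = 0,
    uniform = A^2 / 3,                      # Var U(0, 2A)
    exponential = if (spec$exp_convention == "mean") A^2 else 1 / A^2,
    chisquare = 2 * A)                      # Var chi2(df = A)
  vz <- switch(spec$innovation,
    poisson = th$lambda,
    geometric = th$lambda * (1 + th$lambda))
  A * y_prev + y_prev^2 * vphi + vz
}

#' Warn when the linear link violates the ergodicity condition
#'
#' For the linear link, long-run stability of the chain requires the
#' conditional intensity mean to be bounded away from 1, which fails when
#' the slope is positive (the intensity grows with the previous count).
#' Emits a warning, never an error.
#'
#' @param beta coefficient vector.
#' @param link an `odinar_link`.
#' @return Invisibly, `TRUE` when the condition holds.
#' @export
stationarity_check <- function(beta, link = link_linear()) {
  ok <- TRUE
  if (identical(link$family, "linear") && beta[2L] > 0) {
    ok <- FALSE
    warning("beta1 > 0: the thinning intensity increases with the previous ",
            "count and the chain need not be stationary/ergodic",
            call. = FALSE)
  }
  invisible(ok)
}
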