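#' Link specification for the thinning intensity
#'
#' The thinning intensity at time t has conditional mean
#' \eqn{A_t = \mathrm{logistic}(\nu(Y_{t-1}; \beta))}. The link function
#' \eqn{\nu} is linear by default, \eqn{\nu(y; \beta) = \beta_0 + \beta_1 y},
#' which is the form used throughout the simulation studies. A custom link
#' may be supplied as an R function of `(y, beta)` together with its
#' parameter dimension and, optionally, an analytic gradient in `beta`.
#'
#' @param nu for [link_custom()], a function `nu(y, beta)` returning a real
#'   scalar (vectorised over `y`).
#' @param dim positive integer, the length of `beta`.
#' @param grad optional function `grad(y, beta)` returning the length-`dim`
#'   gradient of `nu` in `beta` (a `dim` x `length(y)` matrix for vector
#'   `y`). When omitted, central finite differences are used.
#' @return An object of class `odinar_link`.
#' @examples
#' lk <- link_linear()
#' lk$nu(2, c(1, -0.6))  # 1 - 1.2
#' @export
link_linear <- function() {
  structure(list(
    family = "linear", dim = 2L,
    nu = function(y, beta) beta[1L] + beta[2L] * y,
    grad = function(y, beta) rbind(rep(1, length(y)), y),
    hess = function(y, beta) matrix(0, 2L, 2L)
  ), class = "odinar_link")
}

#' @rdname link_linear
#' @export
link_custom <- function(nu, dim, grad = NULL) {
  stopifnot(is.function(nu), is.numeric(dim), dim >= 1)
  dim <- as.integer(dim)
  if (is.null(grad)) {
    grad <- function(y, beta) {
      vapply(seq_len(dim), function(j) {
        h <- 1e-6 * max(1, abs(beta[j]))
        bp <- bm <- beta; bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
        (nu(y, bp) - nu(y, bm)) / (2 * h)
      }, numeric(length(y)))
    }
    grad_wrap <- function(y, beta) t(matrix(grad(y, beta), nrow = length(y)))
    structure(list(family = "custom", dim = dim, nu = nu, grad = grad_wrap,
                   hess = NULL), class = "odinar_link")
  } else {
    structure(list(family = "custom", dim = dim, nu = nu, grad = grad,
                   hess = NULL), class = "odinar_link")
  }
}

PHI_FAMILIES <- c("fixed", "uniform", "exponential", "chisquare")
INNOV_FAMILIES <- c("poisson", "geometric")

#' Model specification for the observation-driven INAR(1) process
#'
#' Describes the full generative model \eqn{Y_t = \phi_t \ominus Y_{t-1} +
#' Z_t}: the conditional distribution of the thinning intensity
#' \eqn{\phi_t \mid Y_{t-1}} (point mass, uniform, exponential or chi-square,
#' each with conditional mean \eqn{A_t}), the innovation family for
#' \eqn{Z_t} (Poisson or mean-\eqn{\lambda} geometric), and the link.
#'
#' For the exponential family two parameterisations are supported:
#' `exp_convention = "mean"` (the default) takes \eqn{\phi_t} exponential
#' with mean \eqn{A_t}, consistent with the stated conditional expectation;
#' `"rate"` takes rate \eqn{A_t} (mean \eqn{1/A_t}), matching a printed
#' closed-form likelihood that circulates for this model. Simulator and
#' likelihood always share the chosen convention.
#'
#' @param phi one of `"fixed"`, `"uniform"`, `"exponential"`, `"chisquare"`.
#' @param innovation one of `"poisson"`, `"geometric"`; both have mean
#'   `lambda`.
#' @param link an `odinar_link`, default [link_linear()].
#' @param exp_convention `"mean"` or `"rate"`; exponential family only.
#' @return An object of class `odinar_spec`.
#' @examples
#' odinar_spec("chisquare")
#' @export
odinar_spec <- function(phi = "fixed", innovation = "poisson",
                        link = link_linear(), exp_convention = "mean") {
  phi <- match.arg(phi, PHI_FAMILIES)
  innovation <- match.arg(innovation, INNOV_FAMILIES)
  exp_convention <- match.arg(exp_convention, c("mean", "rate"))
  stopifnot(inherits(link, "odinar_link"))
  structure(list(phi = phi, innovation = innovation, link = link,
                 exp_convention = exp_convention),
            class = "odinar_spec")
}

#' @export
print.odinar_spec <- function(x, ...) {
  cat("Observation-driven INAR(1) specification\n")
  cat("  phi | y_prev :", x$phi,
      if (x$phi == "exponential") sprintf("(%s convention)", x$exp_convention)
      else "", "\n")
  cat("  innovations  :", x$innovation, "(mean lambda)\n")
  cat("  link         :", x$link$family, sprintf("(l = %d)", x$link$dim), "\n")
  invisible(x)
}

## split theta = (beta, lambda); validate dimensions
split_theta <- function(theta, link) {
  l <- link$dim
  if (length(theta) != l + 1L)
    stop("theta must have length ", l + 1L, " (beta of length ", l,
         " plus lambda)", call. = FALSE)
  if (!all(is.finite(theta)))
    stop("theta must be finite", call. = FALSE)
  list(beta = theta[seq_len(l)], lambda = theta[l + 1L])
}

theta_names <- function(link) {
  c(paste0("beta", seq_len(link$dim) - 1L), "lambda")
}

check_series <- function(y, min_len = 2L) {
  if (!is.numeric(y) || length(y) < min_len)
    stop("series must be numeric with at least ", min_len, " observations",
         call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    stop("series must contain non-negative integers", call. = FALSE)
  as.integer(y)
}
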