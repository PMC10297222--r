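## Trajectory generation from the data-generating process: per step draw the
## intensity phi_t given Y_{t-1}, then the thinned component as
## Poisson(phi_t * Y_{t-1}) (exact in distribution for the sum of Y_{t-1}
## iid Poisson(phi_t) draws), then add the innovation.

#' Draw a thinning intensity given the previous count
#'
#' Samples \eqn{\phi_t \mid Y_{t-1}} under the chosen family, each with
#' conditional mean \eqn{A(Y_{t-1})} (under the default exponential
#' convention): point mass at A, uniform on (0, 2A), exponential with mean
#' A, or chi-square with df A (gamma shape A/2, scale 2).
#'
#' @param y_prev previous count.
#' @param theta parameter vector `c(beta, lambda)`.
#' @param spec an [odinar_spec()].
#' @param n number of draws.
#' @return Non-negative numeric draws.
#' @export
draw_phi <- function(y_prev, theta, spec = odinar_spec(), n = 1L) {
  th <- split_theta(theta, spec$link)
  A <- conditional_phi_mean(y_prev, th$beta, spec$link)
  switch(spec$phi,
    fixed = rep(A, n),
    uniform = stats::runif(n, 0, 2 * A),
    exponential = if (spec$exp_convention == "mean")
      stats::rexp(n, rate = 1 / A) else stats::rexp(n, rate = A),
    chisquare = stats::rgamma(n, shape = A / 2, scale = 2))
}

#' Simulate an observation-driven INAR(1) series
#'
#' Generates a trajectory of the process \eqn{Y_t = \phi_t \ominus Y_{t-1}
#' + Z_t}. The first `burn_in` steps are discarded so that the chain
#' forgets its initial state (it does so geometrically when the linear-link
#' slope is non-positive). Identical seeds give identical series.
#'
#' @param theta parameter vector `c(beta, lambda)`.
#' @param spec an [odinar_spec()].
#' @param n length of the returned series.
#' @param burn_in number of initial steps to discard (default 500).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param y0 initial count (default 0).
#' @return Integer vector of length `n`.
#' @examples
#' y <- odinar_simulate(c(1, -0.6, 1.2), odinar_spec(), n = 200, seed = 1)
#' mean(y)
#' @export
odinar_simulate <- function(theta, spec = odinar_spec(), n, burn_in = 500L,
                            seed = NULL, y0 = 0L) {
  stopifnot(inherits(spec, "odinar_spec"), n >= 1, burn_in >= 0, y0 >= 0)
  th <- split_theta(theta, spec$link)
  if (th$lambda <= 0) stop("lambda must be positive", call. = FALSE)
  stationarity_check(th$beta, spec$link)
  if (!is.null(seed)) set.seed(seed)
  total <- n + burn_in
  # innovations drawn up front in one vectorised call
  z <- switch(spec$innovation,
    poisson = stats::rpois(total, th$lambda),
    geometric = stats::rgeom(total, prob = 1 / (1 + th$lambda)))
  y <- integer(total)
  prev <- as.integer(y0)
  fixed <- spec$phi == "fixed"
  for (t in seq_len(total)) {
    if (prev > 0L) {
      phi <- if (fixed) conditional_phi_mean(prev, th$beta, spec$link)
             else draw_phi(prev, theta, spec)
      y[t] <- stats::rpois(1L, phi * prev) + z[t]
    } else {
      y[t] <- z[t]
    }
    prev <- y[t]
  }
  y[(burn_in + 1L):total]
}
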