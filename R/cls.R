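## Conditional least squares: estimating functions, profile-lambda
## minimisation, sandwich asymptotics, and the estimating-equation
## chi-square statistic for interval estimation.

## estimating-function matrix M, rows t = 2..T, columns (beta..., lambda)
## M_ti = u_t * A(1-A) * dnu/dbeta_i * y_{t-1} (i <= l), M_t(l+1) = u_t
mt_matrix <- function(y, theta, link = link_linear()) {
  th <- split_theta(theta, link)
  Tn <- length(y)
  yp <- y[-Tn]; yc <- y[-1L]
  A <- conditional_phi_mean(yp, th$beta, link)
  u <- yc - A * yp - th$lambda
  G <- link$grad(yp, th$beta)              # l x (T-1)
  w <- A * (1 - A) * yp
  M <- cbind(t(G * rep(u * w, each = link$dim)), u)
  colnames(M) <- theta_names(link)
  M
}

#' Conditional least squares estimating function at one transition
#'
#' The vector \eqn{M_t(\theta) = -\tfrac12 \partial S_t/\partial\theta} of
#' first-order conditions of the squared one-step prediction error
#' \eqn{S_t = (Y_t - A(Y_{t-1})Y_{t-1} - \lambda)^2}: component \eqn{i \le
#' \ell} is \eqn{u_t A(1-A) (\partial\nu/\partial\beta_i) Y_{t-1}}, and the
#' last component is the residual \eqn{u_t} itself.
#'
#' @param y_t,y_prev the transition pair of counts.
#' @param theta parameter vector `c(beta, lambda)`.
#' @param link an `odinar_link`.
#' @return Numeric vector of length `link$dim + 1`.
#' @examples
#' mt_vector(3, 2, c(1, -0.6, 1.2))
#' @export
mt_vector <- function(y_t, y_prev, theta, link = link_linear()) {
  drop(mt_matrix(c(y_prev, y_t), theta, link))
}

## residuals r_t(beta) = y_t - A(y_{t-1}) y_{t-1}; lambda profiles out as
## their mean, leaving S(beta) = sum((r - mean r)^2)
cls_objective <- function(beta, y, link) {
  Tn <- length(y)
  yp <- y[-Tn]
  A <- conditional_phi_mean(yp, beta, link)
  r <- y[-1L] - A * yp
  sum((r - mean(r))^2)
}

cls_gradient <- function(beta, y, link) {
  Tn <- length(y)
  yp <- y[-Tn]
  A <- conditional_phi_mean(yp, beta, link)
  r <- y[-1L] - A * yp
  u <- r - mean(r)
  G <- link$grad(yp, beta)
  as.numeric(-2 * (G %*% (u * A * (1 - A) * yp)))
}

cls_starts <- function(link) {
  l <- link$dim
  base <- rep(0, l)
  out <- list(base)
  for (j in seq_len(min(l, 2L))) {
    e <- base; e[j] <- 1; out <- c(out, list(e))
    e <- base; e[j] <- -1; out <- c(out, list(e))
  }
  out[seq_len(5L)]
}

#' Fit by conditional least squares
#'
#' Minimises the sum of squared one-step prediction errors
#' \eqn{S(\theta) = \sum_{t \ge 2} (Y_t - A(Y_{t-1}) Y_{t-1} - \lambda)^2}.
#' \eqn{\lambda} is profiled out in closed form (the mean of the partial
#' residuals), and the remaining criterion is minimised over \eqn{\beta} by
#' BFGS with the analytic gradient from five starting points. The
#' asymptotic covariance is the sandwich \eqn{V^{-1} W V^{-1}} with
#' \eqn{W} the mean outer product of the estimating functions and \eqn{V}
#' the mean curvature of the conditional-mean regression.
#'
#' @param y a count series (non-negative integers, length at least
#'   `link$dim + 2`).
#' @param link an `odinar_link`.
#' @return A list of class `odinar_fit` (method `"cls"`).
#' @seealso [odinar()] for the user-facing front end.
#' @export
cls_fit <- function(y, link = link_linear()) {
  y <- check_series(y, min_len = link$dim + 2L)
  if (all(y == 0L))
    stop("degenerate series: all counts are zero; CLS fit is undefined",
         call. = FALSE)
  best <- NULL
  for (b0 in cls_starts(link)) {
    o <- tryCatch(
      stats::optim(b0, cls_objective, cls_gradient, y = y, link = link,
                   method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  l <- link$dim
  if (is.null(best)) {
    theta <- c(rep(NA_real_, l), NA_real_)
    names(theta) <- theta_names(link)
    return(new_odinar_fit(theta, method = "cls", cov = NULL,
                          converged = FALSE, value = NA_real_, y = y,
                          spec = NULL, link = link))
  }
  beta <- best$par
  Tn <- length(y)
  yp <- y[-Tn]
  lambda <- mean(y[-1L] - conditional_phi_mean(yp, beta, link) * yp)
  theta <- c(beta, lambda)
  names(theta) <- theta_names(link)
  gn <- sqrt(sum(cls_gradient(beta, y, link)^2))
  converged <- is.finite(gn) && gn <= 1e-6 * (Tn - 1)
  cov <- tryCatch(sandwich_cov(y, theta, link), error = function(e) NULL)
  new_odinar_fit(theta, method = "cls", cov = cov, converged = converged,
                 value = best$value, y = y, spec = NULL, link = link)
}

## curvature pieces of m(theta) = A(y_prev) y_prev + lambda for the sandwich
cls_curvature <- function(y, theta, link) {
  th <- split_theta(theta, link)
  l <- link$dim
  Tn <- length(y)
  yp <- y[-Tn]
  A <- conditional_phi_mean(yp, th$beta, link)
  u <- y[-1L] - A * yp - th$lambda
  G <- link$grad(yp, th$beta)          # l x (T-1)
  d1 <- A * (1 - A)
  d2 <- A * (1 - A) * (1 - 2 * A)      # second derivative of logistic in nu
  p <- l + 1L
  V <- matrix(0, p, p)
  for (t in seq_along(yp)) {
    g <- c(d1[t] * G[, t] * yp[t], 1)                       # grad of m_t
    H <- matrix(0, p, p)
    Hbb <- d2[t] * yp[t] * tcrossprod(G[, t])
    if (!is.null(link$hess))
      Hbb <- Hbb + d1[t] * yp[t] * link$hess(yp[t], th$beta)
    H[seq_len(l), seq_len(l)] <- Hbb
    V <- V + tcrossprod(g) - u[t] * H
  }
  V / (Tn - 1)
}

#' Sandwich covariance of the CLS estimator
#'
#' Estimates the asymptotic covariance of \eqn{\sqrt{T}(\hat\theta_{CLS} -
#' \theta_0)} as \eqn{\hat V^{-1} \hat W \hat V^{-1}}, with \eqn{\hat W}
#' the sample mean of \eqn{M_t M_t'} and \eqn{\hat V} the sample mean of
#' the conditional-mean curvature term (gradient outer product minus
#' residual-weighted Hessian). Sample moments divide by the number of
#' usable transitions, T-1.
#'
#' @inheritParams cls_fit
#' @param theta parameter vector at which to evaluate (normally the CLS
#'   estimate).
#' @return A symmetric `(l+1) x (l+1)` matrix on the \eqn{\sqrt{T}} scale;
#'   divide by T for per-sample standard errors.
#' @export
sandwich_cov <- function(y, theta, link = link_linear()) {
  y <- check_series(y)
  M <- mt_matrix(y, theta, link)
  W <- crossprod(M) / nrow(M)
  V <- cls_curvature(y, theta, link)
  Vi <- tryCatch(solve(V), error = function(e) {
    j <- which.min(abs(diag(V)))
    stop("singular curvature matrix V (near-degenerate in component '",
         theta_names(link)[j], "')", call. = FALSE)
  })
  S <- Vi %*% W %*% t(Vi)
  dimnames(S) <- list(theta_names(link), theta_names(link))
  (S + t(S)) / 2
}

#' Estimating-equation chi-square statistic
#'
#' \eqn{H(\theta) = (\sum_t M_t)' (\sum_t M_t M_t')^{-1} (\sum_t M_t)},
#' summed over usable transitions. At the true parameter \eqn{H
#' \rightarrow_d \chi^2_{\ell+1}}, which yields confidence regions
#' \eqn{\{\theta : H(\theta) \le C_\alpha\}} without any optimisation; at
#' the CLS estimate \eqn{H = 0} because the estimating equations are
#' exactly solved (just-identified case).
#'
#' @inheritParams sandwich_cov
#' @return Non-negative scalar.
#' @export
h_statistic <- function(y, theta, link = link_linear()) {
  y <- check_series(y)
  M <- mt_matrix(y, theta, link)
  s <- colSums(M)
  Q <- crossprod(M)
  z <- tryCatch(solve(Q, s), error = function(e)
    stop("singular moment matrix in H(theta)", call. = FALSE))
  max(0, sum(s * z))
}

#' Confidence-region membership test based on H(theta)
#'
#' Tests whether `theta` lies in the level-`alpha` confidence region
#' \eqn{\{\theta : H(\theta) \le C_\alpha\}}, where \eqn{C_\alpha} is the
#' `alpha`-quantile of \eqn{\chi^2_{\ell+1}} (so `alpha` is the nominal
#' coverage, e.g. 0.95).
#'
#' @inheritParams sandwich_cov
#' @param alpha nominal coverage level in (0, 1).
#' @return An `odinar_test` list: statistic, df, critical value, p-value
#'   and rejection flag.
#' @export
confidence_region_test <- function(y, theta, alpha = 0.95,
                                   link = link_linear()) {
  stopifnot(alpha > 0, alpha < 1)
  H <- h_statistic(y, theta, link)
  df <- link$dim + 1L
  crit <- stats::qchisq(alpha, df)
  new_odinar_test(statistic = H, df = df, level = alpha,
                  critical_value = crit,
                  p_value = stats::pchisq(H, df, lower.tail = FALSE),
                  reject = H > crit,
                  method = "estimating-equation chi-square region")
}

new_odinar_test <- function(statistic, df, level, critical_value, p_value,
                            reject, method, diagnostics = NULL) {
  structure(list(statistic = statistic, df = df, level = level,
                 critical_value = critical_value, p_value = p_value,
                 reject = reject, method = method,
                 diagnostics = diagnostics),
            class = "odinar_test")
}

#' @export
print.odinar_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f on %d df (critical %.4f, level %.3g)\n",
              x$statistic, x$df, x$critical_value, x$level))
  cat(sprintf("  p-value   = %.4g -> %s\n", x$p_value,
              if (x$reject) "reject" else "do not reject"))
  invisible(x)
}
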