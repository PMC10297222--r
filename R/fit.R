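#' Fit an observation-driven INAR(1) model
#'
#' Front end to the two estimators. `method = "cls"` minimises the sum of
#' squared one-step prediction errors and only requires the conditional
#' mean to be correctly specified; it is therefore robust to the
#' distribution of the thinning intensity beyond its mean. `method =
#' "cml"` maximises the conditional likelihood under the full generative
#' specification in `spec` (coefficient family and Poisson or geometric
#' innovations) and is more efficient when that specification is correct.
#'
#' @param y a count series (vector of non-negative integers).
#' @param method `"cls"` or `"cml"`.
#' @param spec an [odinar_spec()]; for `"cls"` only its link is used.
#' @return An object of class `odinar_fit` with methods `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `residuals`, `simulate`, and
#'   (for CML) `logLik`/`AIC`/`BIC`.
#' @examples
#' y <- odinar_simulate(c(1, -0.6, 1.2), odinar_spec(), n = 500, seed = 42)
#' fit <- odinar(y, method = "cls")
#' summary(fit)
#' @export
odinar <- function(y, method = c("cls", "cml"), spec = odinar_spec()) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "odinar_spec"))
  if (method == "cls") cls_fit(y, spec$link) else cml_fit(y, spec)
}

new_odinar_fit <- function(theta, method, cov, converged, value, y, spec,
                           link) {
  Tn <- length(y)
  structure(list(coefficients = theta, method = method, cov = cov,
                 converged = converged, value = value, series = y,
                 n_used = Tn - 1L, T_len = Tn, spec = spec, link = link),
            class = "odinar_fit")
}

#' @export
coef.odinar_fit <- function(object, ...) object$coefficients

#' Per-sample covariance of the parameter estimates
#'
#' The estimators are asymptotically normal on the \eqn{\sqrt{T}} scale;
#' `vcov` rescales the stored asymptotic covariance by `1/T` so that
#' `sqrt(diag(vcov(fit)))` are the reported standard errors.
#' @param object an `odinar_fit`.
#' @param ... unused.
#' @export
vcov.odinar_fit <- function(object, ...) {
  if (is.null(object$cov)) return(NULL)
  object$cov / object$T_len
}

#' @export
print.odinar_fit <- function(x, ...) {
  cat(sprintf("Observation-driven INAR(1) fit (%s), T = %d\n",
              toupper(x$method), x$T_len))
  if (!is.null(x$spec) && x$method == "cml")
    cat(sprintf("  phi family: %s, innovations: %s\n", x$spec$phi,
                x$spec$innovation))
  print(round(x$coefficients, 4))
  if (!x$converged) cat("  (optimiser did not converge)\n")
  invisible(x)
}

#' @export
summary.odinar_fit <- function(object, ...) {
  V <- vcov(object)
  se <- if (is.null(V)) rep(NA_real_, length(coef(object))) else
    sqrt(pmax(diag(V), 0))
  z <- coef(object) / se
  tab <- cbind(Estimate = coef(object), `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.odinar_fit"
  out
}

#' @export
print.summary.odinar_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Observation-driven INAR(1) fit by %s, T = %d (%d transitions)\n",
              toupper(f$method), f$T_len, f$n_used))
  if (!is.null(f$spec) && f$method == "cml")
    cat(sprintf("phi family: %s, innovations: %s\n", f$spec$phi,
                f$spec$innovation))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (f$method == "cml") {
    ic <- information_criteria(f$value, length(coef(f)), f$T_len)
    cat(sprintf("negLogLik %.3f  AIC %.3f  BIC %.3f\n", f$value,
                ic["AIC"], ic["BIC"]))
  } else {
    cat(sprintf("residual sum of squares %.3f\n", f$value))
  }
  if (!f$converged) cat("warning: optimiser did not converge\n")
  invisible(x)
}

#' @export
predict.odinar_fit <- function(object, newdata = NULL, ...) {
  y <- if (is.null(newdata)) object$series else check_series(newdata)
  conditional_mean(y[-length(y)], coef(object), object$link)
}

#' @export
residuals.odinar_fit <- function(object, ...) {
  y <- object$series
  y[-1L] - predict(object)
}

#' @export
logLik.odinar_fit <- function(object, ...) {
  if (object$method != "cml")
    stop("logLik is only defined for CML fits", call. = FALSE)
  structure(-object$value, df = length(coef(object)), nobs = object$T_len,
            class = "logLik")
}

#' @export
simulate.odinar_fit <- function(object, nsim = 1L, seed = NULL, n = NULL,
                                ...) {
  spec <- if (is.null(object$spec)) odinar_spec(link = object$link) else
    object$spec
  if (is.null(n)) n <- object$T_len
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, odinar_simulate(coef(object), spec, n = n),
                   simplify = FALSE)
  if (nsim == 1L) out[[1L]] else out
}

#' @export
plot.odinar_fit <- function(x, ...) {
  y <- x$series
  graphics::plot(seq_along(y), y, type = "h",
                 xlab = "t", ylab = "count",
                 main = sprintf("Count series with one-step %s fit",
                                toupper(x$method)), ...)
  graphics::lines(2:length(y), predict(x), col = 2, lwd = 1.5)
  invisible(x)
}
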