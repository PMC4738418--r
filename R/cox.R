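#' Single-covariate Cox proportional hazards fit
#'
#' Newton-Raphson maximisation of the Cox partial likelihood with the Efron
#' correction for tied event times, for one covariate. This is the workhorse
#' behind the D statistic, the calibration slope and \eqn{\rho^2_{OXS}}; it is
#' implemented in compiled code because the resampling engine calls it tens of
#' thousands of times.
#'
#' @param x numeric covariate vector.
#' @param time follow-up times (years, non-negative).
#' @param event event indicators, 0/1.
#' @param max_iter maximum Newton-Raphson iterations before the fit is
#'   flagged non-converged.
#' @return An object of class `cox_fit`: a list with `beta`, `se_beta`
#'   (from the observed information), `loglik` (at the fitted `beta`),
#'   `loglik_null` (at beta = 0), `converged` and `iter`. Fits that diverge
#'   (|beta| > 20) or exhaust `max_iter` have `converged = FALSE` and are
#'   treated as missing by downstream measures.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); t <- rexp(50, exp(0.5 * x)); e <- as.integer(t < 2)
#' cox_fit_single(x, pmin(t, 2), e)
#' @export
cox_fit_single <- function(x, time, event, max_iter = 50L) {
  n <- length(x)
  if (length(time) != n || length(event) != n)
    stop("x, time and event must have equal length")
  if (n < 2L) stop("need at least 2 subjects")
  if (any(time < 0)) stop("negative follow-up times")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  if (sum(event) < 1L) stop("need at least one event")
  fit <- cox_fit1_cpp(as.numeric(x), as.numeric(time), event,
                      max_iter = max_iter)
  if (identical(fit$error, "constant covariate") ||
      identical(fit$error, "no information"))
    stop("covariate is constant among subjects at risk: no information")
  structure(
    list(beta = fit$beta, se_beta = fit$se, loglik = fit$loglik,
         loglik_null = fit$loglik_null, converged = fit$converged,
         iter = fit$iter),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Single-covariate Cox fit: beta = %.4f (se %.4f), %s in %d iter\n",
              x$beta, x$se_beta,
              if (x$converged) "converged" else "NOT converged", x$iter))
  invisible(x)
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimator of \eqn{G(t) = P(C > t)} obtained by reversing the
#' roles of events and censorings, i.e. fitted to \eqn{(t_i, 1 - \delta_i)}.
#' Used as the inverse-probability-of-censoring weight in the Brier score.
#'
#' @inheritParams cox_fit_single
#' @return An object of class `step_function`: a list with increasing `knots`
#'   and right-continuous `values` starting from 1.
#' @seealso [eval_step()] to evaluate it, [brier_score()].
#' @export
km_censoring <- function(time, event) {
  n <- length(time)
  if (n < 1L) stop("empty data")
  o <- order(time)
  tt <- time[o]
  cens <- 1L - as.integer(event)[o]
  ut <- unique(tt)
  # at risk at ut: subjects with time >= ut
  nrisk <- n - findInterval(ut, tt, left.open = TRUE)
  dcens <- as.numeric(rowsum(cens, tt))
  surv <- cumprod(1 - dcens / nrisk)
  structure(list(knots = ut, values = surv), class = "step_function")
}

#' Evaluate a right-continuous step function
#'
#' @param sf a `step_function` (e.g. from [km_censoring()]).
#' @param t evaluation times.
#' @param left if `TRUE`, return the left limit \eqn{G(t-)} instead of
#'   \eqn{G(t)}; the IPCW convention weights uncensored events by
#'   \eqn{G(t_i-)}.
#' @return numeric vector of values (1 before the first knot).
#' @export
eval_step <- function(sf, t, left = FALSE) {
  idx <- findInterval(t, sf$knots, left.open = left)
  c(1, sf$values)[idx + 1L]
}

#' @export
print.step_function <- function(x, ...) {
  cat(sprintf("Step function with %d knots; last value %.4f\n",
              length(x$knots), x$values[length(x$values)]))
  invisible(x)
}
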