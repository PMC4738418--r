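#' @noRd
measure_estimate <- function(name, estimate, se = NA_real_, level = 0.95) {
  z <- z_crit(level)
  structure(
    list(name = name, estimate = estimate, se = se,
         ci_low = if (is.na(se)) NA_real_ else estimate - z * se,
         ci_high = if (is.na(se)) NA_real_ else estimate + z * se,
         level = level),
    class = "measure_estimate")
}

#' @export
print.measure_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f", x$name, x$estimate))
  if (!is.na(x$se))
    cat(sprintf(" (se %.4f, %d%% CI %.4f to %.4f)",
                x$se, round(100 * x$level), x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Harrell's c-index for censored survival data
#'
#' Probability that, of a randomly chosen usable pair, the subject with the
#' higher prognostic index fails earlier. Pairs are usable when the shorter
#' observed time ends in an event (or when an event ties with a censoring
#' time, in which case the event is taken to precede); pairs tied on the
#' prediction count 1/2. Estimate and standard error are taken from
#' [survival::concordance()], oriented so that values above 0.5 mean higher
#' predictions go with earlier events.
#'
#' @param pi prognostic index (linear predictor) vector; higher = higher risk.
#' @inheritParams cox_fit_single
#' @param level confidence level for the Wald interval.
#' @return a `measure_estimate` named `c_index`.
#' @export
harrell_c <- function(pi, time, event, level = 0.95) {
  n <- length(pi)
  if (length(time) != n || length(event) != n)
    stop("pi, time and event must have equal length")
  fit <- survival::concordancefit(survival::Surv(time, event), pi,
                                  reverse = TRUE)
  counts <- fit$count
  usable <- counts[["concordant"]] + counts[["discordant"]] +
    counts[["tied.x"]]
  if (usable <= 0) stop("no usable pairs for the c-index")
  measure_estimate("c_index", unname(fit$concordance),
                   sqrt(unname(fit$var)), level)
}

#' Normal order scores of a prognostic index
#'
#' Ranks the prognostic index, maps ranks to expected standard normal order
#' statistics via the Blom approximation
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}, averages scores within tied groups,
#' and divides by \eqn{\kappa = \sqrt{8/\pi} \approx 1.596}. Fitting the
#' result as the single covariate of a Cox model yields the D statistic.
#'
#' @param pi prognostic index vector, length >= 2.
#' @return numeric vector of kappa-scaled scores summing to zero.
#' @export
normal_order_scores <- function(pi) {
  n <- length(pi)
  if (n < 2L) stop("need at least 2 values")
  blom <- qnorm((seq_len(n) - 0.375) / (n + 0.25)) / KAPPA
  o <- order(pi)
  out <- numeric(n)
  if (anyDuplicated(pi)) {
    grp <- cumsum(c(TRUE, diff(pi[o]) != 0))
    means <- as.numeric(rowsum(blom, grp)) / tabulate(grp)
    out[o] <- means[grp]
  } else {
    out[o] <- blom
  }
  out
}

#' Royston-Sauerbrei D statistic
#'
#' Prognostic separation on the log hazard ratio scale: the coefficient of the
#' kappa-scaled normal order scores of the prognostic index in a
#' single-covariate Cox model. The model-based standard error is the Cox
#' standard error of that coefficient.
#'
#' @inheritParams harrell_c
#' @return a `measure_estimate` named `d_stat`; `NA` estimate if the Cox fit
#'   diverged (flagged, treated as missing downstream).
#' @export
d_statistic <- function(pi, time, event, level = 0.95) {
  z <- normal_order_scores(pi)
  fit <- cox_fit_single(z, time, event)
  if (!fit$converged) return(measure_estimate("d_stat", NA_real_, NA_real_, level))
  measure_estimate("d_stat", fit$beta, fit$se_beta, level)
}

#' Explained variation from the D statistic
#'
#' Deterministic transform
#' \deqn{R^2_D = \frac{D^2/\kappa^2}{\sigma^2 + D^2/\kappa^2}}
#' with \eqn{\kappa^2 = 8/\pi} and \eqn{\sigma^2 = \pi^2/6 \approx 1.645}.
#'
#' @param d D statistic value(s).
#' @return \eqn{R^2_D} in `[0, 1)`, vectorised over `d`.
#' @export
r2_from_d <- function(d) {
  u <- d^2 / KAPPA^2
  u / (SIGMA2 + u)
}

# Delta-method standard error of R2_D from the D statistic's standard error:
# dR2/dD = 2 D sigma^2 / kappa^2 / (sigma^2 + D^2/kappa^2)^2.
#' @noRd
r2_se_delta <- function(d, se_d) {
  abs(2 * d * SIGMA2 / KAPPA^2 / (SIGMA2 + d^2 / KAPPA^2)^2) * se_d
}

#' @noRd
rho2_from_loglik <- function(k, loglik, loglik_null) {
  1 - exp(-(2 / k) * (loglik - loglik_null))
}

#' Explained randomness of O'Quigley, Xu and Stare
#'
#' \deqn{\rho^2_{OXS} = 1 - \exp\{-\tfrac{2}{k}(l_\beta - l_0)\}}
#' where \eqn{k} is the number of events and \eqn{l_\beta, l_0} are the log
#' partial likelihoods of the single-covariate Cox model on the prognostic
#' index and of the null model. The Cox model is refitted on the validation
#' data (rather than evaluated at slope 1). The standard error is a
#' nonparametric bootstrap (rows resampled with replacement); degenerate
#' bootstrap replicates are skipped and counted.
#'
#' @inheritParams harrell_c
#' @param bootstrap_reps bootstrap replications for the standard error
#'   (0 = no standard error).
#' @return a `measure_estimate` named `rho2_oxs`, with attribute
#'   `boot_skipped` when a bootstrap was run.
#' @export
explained_randomness <- function(pi, time, event, bootstrap_reps = 200L,
                                 level = 0.95) {
  fit <- cox_fit_single(pi, time, event)
  if (!fit$converged)
    return(measure_estimate("rho2_oxs", NA_real_, NA_real_, level))
  k <- sum(event)
  est <- rho2_from_loglik(k, fit$loglik, fit$loglik_null)
  se <- NA_real_
  skipped <- NA_integer_
  if (bootstrap_reps > 0L) {
    bm <- cox_boot_cpp(as.numeric(pi), as.numeric(time), as.integer(event),
                       as.integer(bootstrap_reps))
    rho_b <- rho2_from_loglik(bm[, 4L], bm[, 3L], 0)
    ok <- is.finite(rho_b)
    skipped <- sum(!ok)
    if (sum(ok) >= 2L) se <- sd(rho_b[ok])
  }
  out <- measure_estimate("rho2_oxs", est, se, level)
  attr(out, "boot_skipped") <- skipped
  out
}

#' IPCW Brier score at a fixed horizon
#'
#' Inverse-probability-of-censoring weighted Brier score at horizon `t`:
#' \deqn{BS(t) = \frac{1}{n}\sum_i \left[
#'   \frac{\hat S(t|X_i)^2\, I(t_i \le t, \delta_i = 1)}{\hat G(t_i-)} +
#'   \frac{(1-\hat S(t|X_i))^2\, I(t_i > t)}{\hat G(t)} \right]}
#' with \eqn{\hat S(t|X_i) = 1 - } `risk10` and \eqn{\hat G} the Kaplan-Meier
#' estimate of the censoring distribution ([km_censoring()]). By IPCW
#' convention the first term weights by the left limit \eqn{\hat G(t_i-)};
#' set `g_left = FALSE` to use \eqn{\hat G(t_i)} literally.
#'
#' @param risk10 predicted event probabilities by the horizon, in (0, 1).
#' @inheritParams explained_randomness
#' @param t horizon in years (default 10).
#' @param g_left weight uncensored events by the left limit of G (default).
#' @return a `measure_estimate` named `brier`, with attribute `boot_skipped`
#'   when a bootstrap was run.
#' @export
brier_score <- function(risk10, time, event, t = 10, bootstrap_reps = 200L,
                        g_left = TRUE, level = 0.95) {
  n <- length(risk10)
  if (length(time) != n || length(event) != n)
    stop("risk10, time and event must have equal length")
  if (any(risk10 <= 0 | risk10 >= 1)) stop("risk10 must lie in (0, 1)")
  event <- as.integer(event)
  bs_once <- function(risk, tt, ev) {
    G <- km_censoring(tt, ev)
    Gt <- eval_step(G, t)
    if (Gt <= 0)
      stop(sprintf("censoring survival G(t) is 0 at horizon t = %g", t))
    S <- 1 - risk
    had_event <- ev == 1L & tt <= t
    still_in <- tt > t
    w1 <- ifelse(had_event, 1 / eval_step(G, tt, left = g_left), 0)
    w2 <- ifelse(still_in, 1 / Gt, 0)
    mean(S^2 * w1 + (1 - S)^2 * w2)
  }
  est <- bs_once(risk10, time, event)
  se <- NA_real_
  skipped <- NA_integer_
  if (bootstrap_reps > 0L) {
    reps <- vapply(seq_len(bootstrap_reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(bs_once(risk10[idx], time[idx], event[idx]),
               error = function(e) NA_real_)
    }, numeric(1))
    ok <- is.finite(reps)
    skipped <- sum(!ok)
    if (sum(ok) >= 2L) se <- sd(reps[ok])
  }
  out <- measure_estimate("brier", est, se, level)
  attr(out, "boot_skipped") <- skipped
  out
}

#' Calibration slope
#'
#' Coefficient of the prognostic index fitted as the only covariate of a Cox
#' model on the validation data. A slope below 1 means the published
#' coefficients are too extreme for the validation population (predictions
#' too spread out); above 1, too conservative.
#'
#' @inheritParams harrell_c
#' @return a `measure_estimate` named `cal_slope`; `NA` if the fit diverged.
#' @export
calibration_slope <- function(pi, time, event, level = 0.95) {
  fit <- cox_fit_single(pi, time, event)
  if (!fit$converged)
    return(measure_estimate("cal_slope", NA_real_, NA_real_, level))
  measure_estimate("cal_slope", fit$beta, fit$se_beta, level)
}

#' Smoothed calibration curve at a fixed horizon
#'
#' Relates predicted 10-year risk to observed event probability at the
#' horizon. The observed probability is estimated by a Cox model on a natural
#' cubic spline basis (default 4 df) of the complementary log-log of the
#' predicted risk, with the observed probability at `t` read off the fitted
#' survival curve for each grid point. This is a deliberately simple stand-in
#' for adaptive hazard regression ("hare"-style) smoothing. If the spline fit
#' fails or is degenerate the estimator falls back to risk-decile
#' Kaplan-Meier points and says so via a message (never silently).
#'
#' @inheritParams brier_score
#' @param grid predicted-risk grid; default 40 equally spaced points spanning
#'   the observed risk range.
#' @param df spline degrees of freedom.
#' @return data.frame with columns `predicted`, `observed`, and attribute
#'   `method` (`"spline"` or `"decile_km"`); class `calibration_curve`.
#' @export
calibration_curve <- function(risk10, time, event, t = 10, grid = NULL,
                              df = 4L) {
  if (length(unique(risk10)) < 2L)
    stop("need at least 2 distinct predicted risks")
  if (any(risk10 <= 0 | risk10 >= 1)) stop("risk10 must lie in (0, 1)")
  G <- km_censoring(time, event)
  if (eval_step(G, t) <= 0)
    stop(sprintf("censoring survival G(t) is 0 at horizon t = %g", t))
  if (is.null(grid))
    grid <- seq(min(risk10), max(risk10), length.out = 40L)
  cl <- log(-log(1 - risk10))
  dat <- data.frame(time = time, event = as.integer(event), cl = cl)
  res <- tryCatch({
    fit <- survival::coxph(survival::Surv(time, event) ~ splines::ns(cl, df = df),
                           data = dat)
    nd <- data.frame(cl = log(-log(1 - grid)))
    sf <- survival::survfit(fit, newdata = nd)
    surv_t <- summary(sf, times = t, extend = TRUE)$surv
    obs <- 1 - as.numeric(surv_t)
    if (any(!is.finite(obs))) stop("non-finite fitted probabilities")
    list(predicted = grid, observed = obs, method = "spline")
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(res)) {
    message("calibration_curve: spline fit degenerate, ",
            "falling back to risk-decile Kaplan-Meier points")
    res <- decile_km_curve(risk10, time, event, t)
  }
  structure(data.frame(predicted = res$predicted, observed = res$observed),
            method = res$method, class = c("calibration_curve", "data.frame"))
}

#' @noRd
decile_km_curve <- function(risk10, time, event, t) {
  br <- unique(quantile(risk10, probs = seq(0, 1, by = 0.1)))
  g <- cut(risk10, breaks = br, include.lowest = TRUE)
  pred <- tapply(risk10, g, mean)
  obs <- vapply(levels(g), function(lev) {
    sel <- g == lev
    if (!any(sel) || sum(event[sel]) == 0L) return(NA_real_)
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    s <- summary(sf, times = t, extend = TRUE)$surv
    1 - as.numeric(s)
  }, numeric(1))
  keep <- is.finite(pred) & is.finite(obs)
  list(predicted = as.numeric(pred[keep]), observed = as.numeric(obs[keep]),
       method = "decile_km")
}

#' All six validation measures for one sample
#'
#' Computes the c-index, D statistic, \eqn{R^2_D}, \eqn{\rho^2_{OXS}}, IPCW
#' Brier score at `t_horizon`, and calibration slope on one cohort, each with
#' a standard error where defined (model-based for D, \eqn{R^2_D} via the
#' delta method, and the slope; concordance-based for the c-index; bootstrap
#' for \eqn{\rho^2_{OXS}} and the Brier score when `bootstrap_reps > 0`).
#' Measures whose fit fails or diverges are returned as `NA` rather than
#' dropped.
#'
#' @param cohort a [cohort] (or data.frame with columns `time`, `event`,
#'   `pi`, `risk10`).
#' @param t_horizon risk horizon in years.
#' @param bootstrap_reps bootstrap replications for the rho2/Brier standard
#'   errors; 0 disables them.
#' @param level confidence level.
#' @return a `measure_set`: data.frame with one row per measure and columns
#'   `name`, `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
validation_measures <- function(cohort, t_horizon = 10, bootstrap_reps = 200L,
                                level = 0.95) {
  stopifnot(all(c("time", "event", "pi", "risk10") %in% names(cohort)))
  grab <- function(expr) {
    m <- tryCatch(expr, error = function(e) NULL)
    if (is.null(m)) list(estimate = NA_real_, se = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_)
    else m
  }
  ti <- cohort$time; ev <- cohort$event
  cidx <- grab(harrell_c(cohort$pi, ti, ev, level))
  dst <- grab(d_statistic(cohort$pi, ti, ev, level))
  r2 <- if (is.na(dst$estimate)) {
    list(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
         ci_high = NA_real_)
  } else {
    measure_estimate("r2_d", r2_from_d(dst$estimate),
                     r2_se_delta(dst$estimate, dst$se), level)
  }
  rho <- grab(explained_randomness(cohort$pi, ti, ev, bootstrap_reps, level))
  bri <- grab(brier_score(cohort$risk10, ti, ev, t_horizon, bootstrap_reps,
                          level = level))
  slp <- grab(calibration_slope(cohort$pi, ti, ev, level))
  rows <- list(c_index = cidx, d_stat = dst, r2_d = r2, rho2_oxs = rho,
               brier = bri, cal_slope = slp)
  out <- data.frame(
    name = names(rows),
    estimate = vapply(rows, function(r) r$estimate, numeric(1)),
    se = vapply(rows, function(r) r$se, numeric(1)),
    ci_low = vapply(rows, function(r) r$ci_low, numeric(1)),
    ci_high = vapply(rows, function(r) r$ci_high, numeric(1)),
    row.names = NULL)
  class(out) <- c("measure_set", "data.frame")
  out
}
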