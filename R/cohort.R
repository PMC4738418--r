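#' Covariate specification for the synthetic population
#'
#' Multivariate normal covariates with a common (exchangeable) pairwise
#' correlation, standing in for the 7-13 clinical predictors of a typical
#' cardiovascular risk model. The implied covariance must be positive
#' definite, which for an exchangeable correlation in `[0, 1)` always holds.
#'
#' @param n_covariates number of predictors.
#' @param correlation common pairwise correlation, in `[0, 1)`.
#' @param scales per-covariate standard deviations (recycled).
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(n_covariates = 8L, correlation = 0.2, scales = 1) {
  k <- as.integer(n_covariates)
  if (k < 1L) stop("n_covariates must be >= 1")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  scales <- rep_len(as.numeric(scales), k)
  if (any(scales <= 0)) stop("scales must be positive")
  R <- matrix(correlation, k, k); diag(R) <- 1
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("implied covariance is not positive definite")
  structure(list(n_covariates = k, correlation = correlation,
                 scales = scales),
            class = "covariate_spec")
}

#' True data-generating model
#'
#' Weibull proportional-hazards outcome with exponential dropout and
#' administrative censoring: event times
#' \eqn{T = (-\log U / (\lambda e^{PI}))^{1/\gamma}}, observed time the
#' minimum of \eqn{T}, the dropout time and the administrative horizon. The
#' defaults emulate a mid-1990s to late-2000s primary-care registry with
#' 10-year risk predictions, 15 years of maximum follow-up and a low event
#' fraction.
#'
#' @param beta_true true log-hazard coefficients.
#' @param baseline_shape Weibull shape \eqn{\gamma > 0}.
#' @param baseline_rate Weibull rate \eqn{\lambda > 0} (calibrate with
#'   [calibrate_event_rate()]).
#' @param censor_rate exponential dropout rate per year, >= 0.
#' @param admin_horizon administrative censoring time in years (may be `Inf`).
#' @param target_event_fraction desired overall event fraction in (0, 1).
#' @return an object of class `true_data_model`.
#' @export
true_data_model <- function(beta_true = rep(0.24, 8L), baseline_shape = 1.1,
                            baseline_rate = 0.0015, censor_rate = 0.04,
                            admin_horizon = 15, target_event_fraction = 0.054) {
  if (baseline_shape <= 0) stop("baseline_shape must be positive")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (censor_rate < 0) stop("censor_rate must be non-negative")
  if (admin_horizon <= 0) stop("admin_horizon must be positive")
  if (target_event_fraction <= 0 || target_event_fraction >= 1)
    stop("target_event_fraction must lie in (0, 1)")
  structure(list(beta_true = as.numeric(beta_true),
                 baseline_shape = baseline_shape,
                 baseline_rate = baseline_rate,
                 censor_rate = censor_rate,
                 admin_horizon = admin_horizon,
                 target_event_fraction = target_event_fraction),
            class = "true_data_model")
}

# Baseline survival at time t (PI = 0) under the Weibull model.
#' @noRd
baseline_survival <- function(model, t) {
  exp(-model$baseline_rate * t^model$baseline_shape)
}

#' Published prognostic model to be validated
#'
#' A linear-predictor rule \eqn{PI(x) = \beta_{model} \cdot x} plus a baseline
#' 10-year survival \eqn{S_0(10)}, giving predicted risk
#' \eqn{r(x) = 1 - S_0(10)^{\exp(PI(x) + shift)}}.
#'
#' @param beta_model model coefficients.
#' @param s0_10 baseline survival probability at 10 years, in (0, 1).
#' @param intercept_shift optional shift of the linear predictor inside the
#'   risk formula only, inducing miscalibration-in-the-large (default 0).
#' @return an object of class `prognostic_model`.
#' @export
prognostic_model <- function(beta_model, s0_10, intercept_shift = 0) {
  if (s0_10 <= 0 || s0_10 >= 1) stop("s0_10 must lie in (0, 1)")
  structure(list(beta_model = as.numeric(beta_model), s0_10 = s0_10,
                 intercept_shift = intercept_shift),
            class = "prognostic_model")
}

#' Derive an imperfect published model from the truth
#'
#' Emulates imperfect transportability: the published coefficients are the
#' true ones scaled by `shrinkage` plus independent normal perturbations.
#' Because the data are generated from the truth, a model built with
#' `shrinkage = g` has a true calibration slope of about `1/g` in the
#' population; `shrinkage = 1, noise_sd = 0` reproduces the truth exactly
#' (self-validation).
#'
#' @param truth a [true_data_model].
#' @param shrinkage positive multiplier of the true coefficients.
#' @param noise_sd standard deviation of per-coefficient perturbations.
#' @param s0_10 baseline 10-year survival of the published model; defaults to
#'   the truth's own baseline survival at 10 years.
#' @param seed RNG seed for the perturbations (required if `noise_sd > 0`).
#' @param intercept_shift see [prognostic_model()].
#' @return a [prognostic_model].
#' @export
make_validation_model <- function(truth, shrinkage = 1, noise_sd = 0,
                                  s0_10 = NULL, seed = NULL,
                                  intercept_shift = 0) {
  if (shrinkage <= 0) stop("shrinkage must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  k <- length(truth$beta_true)
  pert <- numeric(k)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    set.seed(seed)
    pert <- rnorm(k, 0, noise_sd)
  }
  if (is.null(s0_10)) s0_10 <- baseline_survival(truth, 10)
  prognostic_model(shrinkage * truth$beta_true + pert, s0_10,
                   intercept_shift)
}

#' Generate a synthetic validation population
#'
#' Draws covariates, generates Weibull proportional-hazards event times under
#' the true model, applies exponential dropout and administrative censoring,
#' and attaches the published model's prognostic index and predicted 10-year
#' risk to every row. Deterministic given `seed`.
#'
#' @param spec a [covariate_spec].
#' @param model a [true_data_model].
#' @param n population size, >= 2.
#' @param seed integer RNG seed (required).
#' @param published_model the [prognostic_model] under validation; default
#'   `NULL` uses the truth itself (self-validation).
#' @return a `cohort`: data.frame with columns `id`, `time` (years), `event`
#'   (0/1), `pi`, `risk10`.
#' @export
generate_population <- function(spec, model, n, seed,
                                published_model = NULL) {
  stopifnot(inherits(spec, "covariate_spec"),
            inherits(model, "true_data_model"))
  if (n < 2L) stop("n must be >= 2")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (length(model$beta_true) != spec$n_covariates)
    stop("length of beta_true must match n_covariates")
  if (is.null(published_model))
    published_model <- prognostic_model(model$beta_true,
                                        baseline_survival(model, 10))
  set.seed(seed)
  lat <- generate_latents(spec, model, n)
  times <- (lat$A / model$baseline_rate)^(1 / model$baseline_shape)
  obs <- pmin(times, lat$C)
  event <- as.integer(times <= lat$C)
  pi_mod <- drop(lat$X %*% published_model$beta_model)
  risk10 <- 1 - published_model$s0_10 ^
    exp(pi_mod + published_model$intercept_shift)
  out <- data.frame(id = seq_len(n), time = obs, event = event,
                    pi = pi_mod, risk10 = risk10)
  class(out) <- c("cohort", "data.frame")
  out
}

# Latent draws shared by generation and event-rate calibration. A is the
# rescaled exponential deviate -log(U) * exp(-PI_true); C the censoring time
# min(dropout, horizon). Event iff (A/lambda)^(1/gamma) <= C, i.e.
# lambda >= A / C^gamma.
#' @noRd
generate_latents <- function(spec, model, n) {
  k <- spec$n_covariates
  R <- matrix(spec$correlation, k, k); diag(R) <- 1
  L <- chol(R)
  X <- matrix(rnorm(n * k), n, k) %*% L
  X <- sweep(X, 2L, spec$scales, `*`)
  pi_true <- drop(X %*% model$beta_true)
  A <- -log(runif(n)) * exp(-pi_true)
  C <- if (model$censor_rate > 0) rexp(n, model$censor_rate) else
    rep(Inf, n)
  C <- pmin(C, model$admin_horizon)
  list(X = X, pi_true = pi_true, A = A, C = C)
}

#' Calibrate the baseline rate to a target event fraction
#'
#' Bisection on the log baseline rate so that the event fraction of a pilot
#' population (same latent draws at every bisection step, so the fraction is
#' monotone in the rate) matches `model$target_event_fraction` within 0.1
#' percentage points. If the target is unreachable (for example no censoring
#' mechanism at all, where every subject is an event regardless of the rate),
#' a warning reports the achievable bounds and the nearer boundary is
#' returned.
#'
#' @inheritParams generate_population
#' @param n_pilot pilot population size; use the final population size.
#' @param tol tolerance on the event fraction (default 0.001 = 0.1 pp).
#' @return the [true_data_model] with `baseline_rate` replaced; attributes
#'   `achieved_fraction` and `calibration_converged`.
#' @export
calibrate_event_rate <- function(spec, model, n_pilot, seed, tol = 1e-3) {
  stopifnot(inherits(spec, "covariate_spec"),
            inherits(model, "true_data_model"))
  if (missing(seed) || is.null(seed)) stop("seed is required")
  target <- model$target_event_fraction
  set.seed(seed)
  lat <- generate_latents(spec, model, n_pilot)
  thr <- lat$A / lat$C^model$baseline_shape  # event iff lambda >= thr
  frac <- function(loglam) mean(thr <= exp(loglam))
  lo <- log(model$baseline_rate) - 25
  hi <- log(model$baseline_rate) + 25
  flo <- frac(lo); fhi <- frac(hi)
  if (flo > target || fhi < target) {
    warning(sprintf(paste0("target event fraction %.4f unreachable; ",
                           "achievable range [%.4f, %.4f] over the rate ",
                           "bracket - returning boundary"),
                    target, flo, fhi))
    best <- if (abs(flo - target) < abs(fhi - target)) lo else hi
    out <- model
    out$baseline_rate <- exp(best)
    attr(out, "achieved_fraction") <- frac(best)
    attr(out, "calibration_converged") <- FALSE
    return(out)
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- frac(mid)
    if (abs(fm - target) <= tol) break
    if (fm < target) lo <- mid else hi <- mid
  }
  out <- model
  out$baseline_rate <- exp(mid)
  attr(out, "achieved_fraction") <- fm
  attr(out, "calibration_converged") <- abs(fm - target) <= tol
  if (!attr(out, "calibration_converged"))
    warning(sprintf("bisection stopped at fraction %.4f for target %.4f",
                    fm, target))
  out
}

#' True performance of the published model on the full population
#'
#' Computes all six validation measures once on the whole population; the
#' result is the truth \eqn{\theta} that resampled estimates are evaluated
#' against. For stable values use a population with at least ~10^4 events
#' (the shipped default of 200,000 subjects at ~5% events gives ~10,800).
#' Bootstrap standard errors are not needed for \eqn{\theta} and are off.
#'
#' @param population a `cohort`.
#' @param t_horizon risk horizon in years.
#' @return a `measure_set` (see [validation_measures()]).
#' @export
true_performance <- function(population, t_horizon = 10) {
  ev <- population$event
  if (sum(ev) < 1L || sum(1 - ev) < 1L)
    stop("population must contain at least one event and one non-event")
  validation_measures(population, t_horizon = t_horizon, bootstrap_reps = 0L)
}

#' Read / write a cohort as delimited text
#'
#' CSV with header `id,time,event,pi,risk10`; times in years, `event` 0/1.
#'
#' @param cohort a `cohort` data.frame.
#' @param path file path.
#' @return `read_cohort` returns a `cohort`; `write_cohort` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(c("id", "time", "event", "pi", "risk10") %in% names(cohort)))
  write.csv(cohort[, c("id", "time", "event", "pi", "risk10")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path)
  need <- c("id", "time", "event", "pi", "risk10")
  if (!all(need %in% names(out)))
    stop("cohort file must have columns ", paste(need, collapse = ", "))
  if (any(out$time < 0)) stop("negative follow-up times in cohort file")
  if (!all(out$event %in% c(0L, 1L))) stop("event must be 0/1")
  out <- out[, need]
  class(out) <- c("cohort", "data.frame")
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects, %d events (%.2f%%), median follow-up %.2f years\n",
              nrow(x), sum(x$event), 100 * mean(x$event), median(x$time)))
  invisible(x)
}
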