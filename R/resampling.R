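#' Scenario specification for the resampling engine
#'
#' One scenario = one fixed number of events. The study grid of the design is
#' 5, 10, 25, 50, 75, 100, 150, 200, 300, 400, 500 and 1000 events with
#' B = 10,000 replicates; the shipped desk-scale defaults reduce B to 2,000
#' (see the methods vignette).
#'
#' @param events number of events per replicate, >= 1.
#' @param replicates number of Monte-Carlo replicates B, >= 1.
#' @param seed integer RNG seed for the scenario (required).
#' @param bootstrap_reps bootstrap replications inside each replicate for the
#'   rho2/Brier standard errors; 0 disables them (the D statistic, R2_D,
#'   c-index and slope keep their model-based standard errors).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(events, replicates = 2000L, seed,
                          bootstrap_reps = 200L) {
  if (events < 1L) stop("events must be >= 1")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  structure(list(events = as.integer(events),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 bootstrap_reps = as.integer(bootstrap_reps)),
            class = "scenario_spec")
}

#' Draw one sample with a fixed number of events
#'
#' Stratified sampling with replacement by outcome: exactly `events` rows from
#' the event stratum and `round(events * (1 - p) / p)` rows from the
#' non-event stratum, where `p` is the population event fraction — so every
#' sample reproduces the population's event proportion. Rounding is R's
#' round-half-to-even.
#'
#' @param population a `cohort`.
#' @param events number of events in the sample.
#' @return a `cohort` of `events + round(events * (1-p)/p)` rows. Uses the
#'   current RNG state.
#' @export
draw_fixed_event_sample <- function(population, events) {
  ev_idx <- which(population$event == 1L)
  ne_idx <- which(population$event == 0L)
  if (length(ev_idx) == 0L) stop("population has no events")
  if (length(ne_idx) == 0L) stop("population has no non-events")
  p <- length(ev_idx) / nrow(population)
  n_ne <- n_nonevents(events, p)
  idx <- c(sample(ev_idx, events, replace = TRUE),
           sample(ne_idx, n_ne, replace = TRUE))
  out <- population[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}

#' @rdname draw_fixed_event_sample
#' @param p population event fraction.
#' @export
n_nonevents <- function(events, p) as.integer(round(events * (1 - p) / p))

#' Run one resampling scenario
#'
#' Draws `spec$replicates` fixed-event samples from the population and
#' computes all six measures (with standard errors) on each. Replicates whose
#' fit for a measure fails or diverges get `NA` for that measure and are
#' counted in `missing`, never dropped silently. Per-replicate seeds are
#' drawn up front from the scenario seed, so any single replicate can be
#' reproduced in isolation.
#'
#' @param population a `cohort`.
#' @param spec a [scenario_spec].
#' @param t_horizon risk horizon in years.
#' @param level confidence level for the Wald intervals.
#' @param out_file optional CSV path; replicate rows are appended in chunks
#'   so memory stays bounded for very large B.
#' @param chunk_size rows per flush when streaming to `out_file`.
#' @return an object of class `scenario_result`: list with `spec`,
#'   `estimates` (data.frame, one row per replicate with `<measure>` and
#'   `<measure>_se` columns), `missing` (named counts) and `rep_seeds`.
#' @export
run_scenario <- function(population, spec, t_horizon = 10, level = 0.95,
                         out_file = NULL, chunk_size = 500L) {
  stopifnot(inherits(spec, "scenario_spec"))
  B <- spec$replicates
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, B)
  measures <- c("c_index", "d_stat", "r2_d", "rho2_oxs", "brier", "cal_slope")
  cols <- as.vector(rbind(measures, paste0(measures, "_se")))
  est <- matrix(NA_real_, B, length(cols), dimnames = list(NULL, cols))
  tv <- population$time
  ev <- as.integer(population$event)
  pv <- population$pi
  rv <- population$risk10
  ev_idx <- which(ev == 1L)
  ne_idx <- which(ev == 0L)
  if (length(ev_idx) == 0L || length(ne_idx) == 0L)
    stop("population must contain events and non-events")
  p <- length(ev_idx) / length(ev)
  n_ne <- n_nonevents(spec$events, p)
  if (!is.null(out_file) && file.exists(out_file)) file.remove(out_file)
  flushed <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- c(sample(ev_idx, spec$events, replace = TRUE),
             sample(ne_idx, n_ne, replace = TRUE))
    est[b, ] <- replicate_measures(pv[idx], rv[idx], tv[idx], ev[idx],
                                   t_horizon, spec$bootstrap_reps, level)
    if (!is.null(out_file) && (b %% chunk_size == 0L || b == B)) {
      block <- data.frame(replicate = (flushed + 1L):b,
                          est[(flushed + 1L):b, , drop = FALSE])
      suppressWarnings(write.table(block, out_file, sep = ",",
                                   row.names = FALSE, col.names = flushed == 0L,
                                   append = flushed > 0L))
      flushed <- b
    }
  }
  estimates <- data.frame(replicate = seq_len(B), est)
  missing <- vapply(measures, function(m) sum(is.na(estimates[[m]])),
                    integer(1))
  structure(list(spec = spec, estimates = estimates, missing = missing,
                 rep_seeds = rep_seeds),
            class = "scenario_result")
}

# One replicate: all six measures as a flat numeric vector
# (estimate, se) x (c_index, d_stat, r2_d, rho2_oxs, brier, cal_slope).
#' @noRd
replicate_measures <- function(pi, risk10, time, event, t_horizon,
                               bootstrap_reps, level) {
  out <- rep(NA_real_, 12L)
  cfit <- tryCatch(harrell_c(pi, time, event, level), error = function(e) NULL)
  if (!is.null(cfit)) out[1:2] <- c(cfit$estimate, cfit$se)
  dfit <- tryCatch(cox_fit_single(normal_order_scores(pi), time, event),
                   error = function(e) NULL)
  if (!is.null(dfit) && dfit$converged) {
    out[3:4] <- c(dfit$beta, dfit$se_beta)
    out[5:6] <- c(r2_from_d(dfit$beta), r2_se_delta(dfit$beta, dfit$se_beta))
  }
  pfit <- tryCatch(cox_fit_single(pi, time, event), error = function(e) NULL)
  if (!is.null(pfit) && pfit$converged) {
    k <- sum(event)
    out[7] <- rho2_from_loglik(k, pfit$loglik, pfit$loglik_null)
    out[11:12] <- c(pfit$beta, pfit$se_beta)
    if (bootstrap_reps > 0L) {
      bm <- cox_boot_cpp(as.numeric(pi), as.numeric(time), event,
                         bootstrap_reps)
      rho_b <- rho2_from_loglik(bm[, 4L], bm[, 3L], 0)
      ok <- is.finite(rho_b)
      if (sum(ok) >= 2L) out[8] <- sd(rho_b[ok])
    }
  }
  bfit <- tryCatch(brier_score(risk10, time, event, t_horizon,
                               bootstrap_reps, level = level),
                   error = function(e) NULL)
  if (!is.null(bfit)) out[9:10] <- c(bfit$estimate, bfit$se)
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario: %d events, B = %d (seed %d)\n",
              x$spec$events, x$spec$replicates, x$spec$seed))
  cat("Missing replicates per measure:\n")
  print(x$missing)
  invisible(x)
}

#' Run the full event-size grid
#'
#' Maps [run_scenario()] over a grid of event counts with independent
#' per-scenario seeds derived from one master seed. A scenario that errors is
#' isolated: its slot holds a `scenario_error` condition object, and the
#' remaining scenarios still run.
#'
#' @inheritParams run_scenario
#' @param events_grid integer vector of event counts.
#' @param replicates Monte-Carlo replicates per scenario.
#' @param seed master seed.
#' @param bootstrap_reps see [scenario_spec()].
#' @param out_dir optional directory; each scenario streams to
#'   `scenario_<events>.csv` inside it.
#' @param verbose log per-scenario progress to stderr.
#' @return named list of `scenario_result` (names `"events_<k>"`).
#' @export
run_grid <- function(population, events_grid, replicates = 2000L, seed,
                     bootstrap_reps = 0L, t_horizon = 10, level = 0.95,
                     out_dir = NULL, verbose = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  scen_seeds <- sample.int(.Machine$integer.max, length(events_grid))
  out <- vector("list", length(events_grid))
  names(out) <- paste0("events_", events_grid)
  for (i in seq_along(events_grid)) {
    if (verbose)
      message(sprintf("scenario %d/%d: events = %d",
                      i, length(events_grid), events_grid[i]))
    sp <- scenario_spec(events_grid[i], replicates, scen_seeds[i],
                        bootstrap_reps)
    of <- if (is.null(out_dir)) NULL else
      file.path(out_dir, sprintf("scenario_%d.csv", events_grid[i]))
    out[[i]] <- tryCatch(
      run_scenario(population, sp, t_horizon, level, out_file = of),
      error = function(e) structure(e, class = c("scenario_error",
                                                 class(e))))
    if (verbose && inherits(out[[i]], "scenario_result"))
      message(sprintf("  missing: %s",
                      paste(out[[i]]$missing, collapse = "/")))
  }
  out
}

#' Model-based vs empirical vs bootstrap standard errors of D and R2_D
#'
#' For each event count: `n_sim` fixed-event samples are drawn; on each, the
#' D statistic with its model-based (Cox) standard error, the delta-method
#' standard error of R2_D, and nonparametric bootstrap standard errors of
#' both (rows resampled with replacement, normal order scores recomputed per
#' resample). The empirical standard error is the SD of the `n_sim` point
#' estimates. Coverage of the 95% Wald interval around the true value is
#' reported under the model-based and the bootstrap standard error, together
#' with the acceptable coverage band \eqn{p \pm 2\sqrt{p(1-p)/n}}.
#'
#' @inheritParams run_grid
#' @param theta a `measure_set` of true values (from [true_performance()]).
#' @param n_sim simulation replicates per event count.
#' @param bootstrap_reps bootstrap replications per replicate.
#' @param stratified resample the bootstrap within outcome strata instead of
#'   plain rows (default `FALSE`: plain nonparametric bootstrap).
#' @return data.frame with one row per event count x measure: mean
#'   model-based SE, empirical SE, mean bootstrap SE, coverage under each,
#'   the acceptable band, and missingness counts.
#' @export
se_comparison_study <- function(population, events_grid, theta,
                                n_sim = 1000L, bootstrap_reps = 500L, seed,
                                level = 0.95, stratified = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  th <- as.data.frame(theta)
  theta_d <- th$estimate[th$name == "d_stat"]
  theta_r2 <- th$estimate[th$name == "r2_d"]
  tv <- population$time
  ev <- as.integer(population$event)
  pv <- population$pi
  ev_idx <- which(ev == 1L); ne_idx <- which(ev == 0L)
  p <- length(ev_idx) / length(ev)
  z <- z_crit(level)
  set.seed(seed)
  grid_seeds <- sample.int(.Machine$integer.max, length(events_grid))
  rows <- list()
  for (g in seq_along(events_grid)) {
    events <- events_grid[g]
    n_ne <- n_nonevents(events, p)
    n_tot <- events + n_ne
    blom <- qnorm((seq_len(n_tot) - 0.375) / (n_tot + 0.25)) / KAPPA
    set.seed(grid_seeds[g])
    sim_seeds <- sample.int(.Machine$integer.max, n_sim)
    d_hat <- se_model <- se_boot_d <- se_boot_r2 <- rep(NA_real_, n_sim)
    for (i in seq_len(n_sim)) {
      set.seed(sim_seeds[i])
      idx <- c(sample(ev_idx, events, replace = TRUE),
               sample(ne_idx, n_ne, replace = TRUE))
      sp <- pv[idx]; st <- tv[idx]; se_ <- ev[idx]
      fit <- tryCatch(cox_fit_single(normal_order_scores(sp), st, se_),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      d_hat[i] <- fit$beta
      se_model[i] <- fit$se_beta
      db <- if (stratified)
        d_boot_stratified(sp, st, se_, blom, bootstrap_reps)
      else
        d_boot_cpp(sp, st, se_, blom, bootstrap_reps)[, 1L]
      db <- db[is.finite(db)]
      if (length(db) >= 2L) {
        se_boot_d[i] <- sd(db)
        se_boot_r2[i] <- sd(r2_from_d(db))
      }
    }
    ok <- is.finite(d_hat)
    n_used <- sum(ok)
    band <- 2 * sqrt(level * (1 - level) / n_used)
    r2_hat <- r2_from_d(d_hat)
    se_model_r2 <- r2_se_delta(d_hat, se_model)
    covg <- function(est, se, truth)
      mean(abs(est - truth) <= z * se, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      events = events, measure = "d_stat",
      model_se_mean = mean(se_model[ok]),
      empirical_se = sd(d_hat[ok]),
      boot_se_mean = mean(se_boot_d[ok], na.rm = TRUE),
      coverage_model = covg(d_hat, se_model, theta_d),
      coverage_boot = covg(d_hat, se_boot_d, theta_d),
      coverage_low = level - band, coverage_high = level + band,
      n_used = n_used, n_missing = n_sim - n_used)
    rows[[length(rows) + 1L]] <- data.frame(
      events = events, measure = "r2_d",
      model_se_mean = mean(se_model_r2[ok]),
      empirical_se = sd(r2_hat[ok]),
      boot_se_mean = mean(se_boot_r2[ok], na.rm = TRUE),
      coverage_model = covg(r2_hat, se_model_r2, theta_r2),
      coverage_boot = covg(r2_hat, se_boot_r2, theta_r2),
      coverage_low = level - band, coverage_high = level + band,
      n_used = n_used, n_missing = n_sim - n_used)
  }
  do.call(rbind, rows)
}

# Stratified-bootstrap fallback for the D statistic (R implementation; the
# plain bootstrap goes through compiled code).
#' @noRd
d_boot_stratified <- function(pi, time, event, blom, nboot) {
  ev_i <- which(event == 1L); ne_i <- which(event == 0L)
  vapply(seq_len(nboot), function(b) {
    idx <- c(sample(ev_i, length(ev_i), replace = TRUE),
             sample(ne_i, length(ne_i), replace = TRUE))
    fit <- tryCatch(cox_fit_single(normal_order_scores(pi[idx]), time[idx],
                                   event[idx]),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) NA_real_ else fit$beta
  }, numeric(1))
}
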