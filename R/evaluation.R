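#' Monte-Carlo evaluation quantities
#'
#' The simulation-study summaries applied to the B replicate estimates of one
#' measure at one event count: percent bias, standardized bias, root mean
#' square error, coverage of the Wald confidence interval with its acceptable
#' band, mean confidence-interval width, and tolerance-band proportions.
#' Missing replicates are excluded with counts reported; `B` in the
#' acceptable-band formula is the non-missing count.
#'
#' @param estimates numeric vector of replicate estimates (NAs allowed).
#' @param theta true value of the measure.
#' @name evaluation-metrics
NULL

#' @describeIn evaluation-metrics
#'   `100 * (mean(estimates) - theta) / theta`; the relative magnitude of the
#'   raw bias to the true value. Undefined (NA with a warning) when
#'   `theta = 0`. `use_median` replaces the mean by the median.
#' @param use_median summarise replicates by the median instead of the mean.
#' @export
percent_bias <- function(estimates, theta, use_median = FALSE) {
  if (theta == 0) {
    warning("percent bias undefined for theta = 0")
    return(NA_real_)
  }
  centre <- if (use_median) median(estimates, na.rm = TRUE) else
    mean(estimates, na.rm = TRUE)
  100 * (centre - theta) / theta
}

#' @describeIn evaluation-metrics
#'   `100 * (mean(estimates) - theta) / sd(estimates)`; the raw bias as a
#'   percentage of the empirical standard error (sample SD of the replicate
#'   estimates). -25 means the mean estimate lies a quarter of a standard
#'   error below the truth. Undefined when the replicates do not vary.
#' @export
standardized_bias <- function(estimates, theta, use_median = FALSE) {
  x <- estimates[!is.na(estimates)]
  if (length(x) < 2L) {
    warning("standardized bias needs at least 2 estimates")
    return(NA_real_)
  }
  s <- sd(x)
  if (s == 0) {
    warning("standardized bias undefined: zero empirical standard error")
    return(NA_real_)
  }
  centre <- if (use_median) median(x) else mean(x)
  100 * (centre - theta) / s
}

#' @describeIn evaluation-metrics
#'   `sqrt(mean((estimates - theta)^2))` over non-missing replicates.
#' @export
rmse <- function(estimates, theta) {
  x <- estimates[!is.na(estimates)]
  if (length(x) < 1L) stop("rmse needs at least 1 estimate")
  sqrt(mean((x - theta)^2))
}

#' @describeIn evaluation-metrics
#'   Proportion of replicate Wald intervals `estimate +/- z * se` containing
#'   `theta`, with the acceptable band
#'   `level +/- 2 * sqrt(level * (1 - level) / B)` over the non-missing count.
#'   Returns a list `(coverage, acceptable_low, acceptable_high, n_used,
#'   n_missing)`.
#' @param ses replicate standard errors matched to `estimates`.
#' @param level nominal confidence level.
#' @export
coverage <- function(estimates, ses, theta, level = 0.95) {
  if (length(estimates) != length(ses))
    stop("estimates and ses must be matched")
  ok <- !is.na(estimates) & !is.na(ses)
  n <- sum(ok)
  if (n < 1L)
    return(list(coverage = NA_real_, acceptable_low = NA_real_,
                acceptable_high = NA_real_, n_used = 0L,
                n_missing = length(estimates)))
  z <- z_crit(level)
  hit <- abs(estimates[ok] - theta) <= z * ses[ok]
  band <- 2 * sqrt(level * (1 - level) / n)
  list(coverage = mean(hit), acceptable_low = level - band,
       acceptable_high = level + band, n_used = n,
       n_missing = length(estimates) - n)
}

#' @describeIn evaluation-metrics
#'   Mean Wald interval width `mean(2 * z * ses)` over non-missing standard
#'   errors.
#' @export
mean_ci_width <- function(ses, level = 0.95) {
  s <- ses[!is.na(ses)]
  if (length(s) < 1L) stop("mean_ci_width needs at least 1 standard error")
  mean(2 * z_crit(level) * s)
}

#' @describeIn evaluation-metrics
#'   For each tolerance x (in percent): the fraction of replicates with
#'   `|estimate - theta| <= (x/100) * |theta|`. Undefined when `theta = 0`.
#' @param tolerances tolerances in percent (default 0.5, 2.5, 5, 10).
#' @export
within_tolerance <- function(estimates, theta,
                             tolerances = c(0.5, 2.5, 5, 10)) {
  if (theta == 0) {
    warning("within_tolerance undefined for theta = 0")
    return(stats::setNames(rep(NA_real_, length(tolerances)),
                           paste0("within_", tolerances)))
  }
  x <- estimates[!is.na(estimates)]
  out <- vapply(tolerances,
                function(tl) mean(abs(x - theta) <= (tl / 100) * abs(theta)),
                numeric(1))
  stats::setNames(out, paste0("within_", tolerances))
}

#' Summarise scenario results against the truth
#'
#' Applies all evaluation quantities to every measure of every scenario,
#' producing the long-format table behind the bias / RMSE / coverage /
#' CI-width / tolerance-band displays. Coverage and CI width are left `NA`
#' for measures without a standard error in the replicates (e.g. the Brier
#' score when the in-replicate bootstrap was off).
#'
#' @param results a `scenario_result` or a list of them (from [run_grid()];
#'   `scenario_error` entries are skipped with a warning).
#' @param theta a `measure_set` of true values (from [true_performance()]).
#' @param level nominal confidence level.
#' @param tolerances tolerance bands in percent.
#' @return data.frame (class `evaluation_summary`), one row per measure x
#'   event count.
#' @export
summarize_results <- function(results, theta, level = 0.95,
                              tolerances = c(0.5, 2.5, 5, 10)) {
  if (inherits(results, "scenario_result")) results <- list(results)
  th <- as.data.frame(theta)
  rows <- list()
  for (res in results) {
    if (!inherits(res, "scenario_result")) {
      warning("skipping failed scenario: ", conditionMessage(res))
      next
    }
    est <- res$estimates
    for (m in th$name) {
      tr <- th$estimate[th$name == m]
      x <- est[[m]]
      s <- est[[paste0(m, "_se")]]
      cov <- coverage(x, s, tr, level)
      wt <- suppressWarnings(within_tolerance(x, tr, tolerances))
      has_se <- any(!is.na(s))
      row <- data.frame(
        measure = m, events = res$spec$events,
        n_used = sum(!is.na(x)), n_missing = sum(is.na(x)),
        mean = mean(x, na.rm = TRUE), median = median(x, na.rm = TRUE),
        theta = tr,
        percent_bias = suppressWarnings(percent_bias(x, tr)),
        median_percent_bias = suppressWarnings(percent_bias(x, tr, TRUE)),
        standardized_bias = suppressWarnings(standardized_bias(x, tr)),
        median_standardized_bias =
          suppressWarnings(standardized_bias(x, tr, TRUE)),
        empirical_se = sd(x, na.rm = TRUE),
        rmse = rmse(x, tr),
        coverage = if (has_se) cov$coverage else NA_real_,
        coverage_low = if (has_se) cov$acceptable_low else NA_real_,
        coverage_high = if (has_se) cov$acceptable_high else NA_real_,
        mean_ci_width = if (has_se) mean_ci_width(s, level) else NA_real_)
      for (nm in names(wt)) row[[nm]] <- wt[[nm]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    # empty input -> empty table with the documented header
    nm <- c("measure", "events", "n_used", "n_missing", "mean", "median",
            "theta", "percent_bias", "median_percent_bias",
            "standardized_bias", "median_standardized_bias", "empirical_se",
            "rmse", "coverage", "coverage_low", "coverage_high",
            "mean_ci_width", paste0("within_", tolerances))
    out <- as.data.frame(stats::setNames(
      replicate(length(nm), numeric(0), simplify = FALSE), nm))
    out$measure <- character(0)
    class(out) <- c("evaluation_summary", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("evaluation_summary", "data.frame")
  out
}
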