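test_that("harrell_c handles the limiting cases", {
  # predictions perfectly ordered against event times, no censoring
  t <- c(5, 4, 3, 2, 1)
  expect_equal(harrell_c(1:5, t, rep(1, 5))$estimate, 1.0)
  # all predictions equal
  expect_equal(harrell_c(rep(2, 10), rexp(10), rep(1, 10))$estimate, 0.5)
  # no usable pairs
  expect_error(harrell_c(1:3, c(1, 2, 3), c(0, 0, 0)), "usable")
})

test_that("harrell_c equals exhaustive pair enumeration on censored data", {
  set.seed(303)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    pi_ <- round(rnorm(n), 1)  # rounded: prediction ties occur
    t <- round(rexp(n, exp(0.5 * pi_)), 1)
    e <- rbinom(n, 1, 0.5)
    if (sum(e) == 0) e[1] <- 1
    expect_equal(harrell_c(pi_, t, e)$estimate, brute_force_c(pi_, t, e))
  }
})

test_that("normal_order_scores follow the Blom formula and its symmetries", {
  # n = 2, distinct: +/- qnorm((2 - 3/8)/(2 + 1/4)) / kappa
  kappa <- sqrt(8 / pi)
  s <- normal_order_scores(c(3.2, -1.1))
  expect_equal(s, c(1, -1) * qnorm((2 - 3 / 8) / 2.25) / kappa)
  # sum to zero, with and without ties
  set.seed(9)
  x <- rnorm(100)
  expect_lt(abs(sum(normal_order_scores(x))), 1e-12)
  xt <- sample(round(rnorm(100), 1))
  expect_lt(abs(sum(normal_order_scores(xt))), 1e-12)
  # rank invariance under a monotone transform
  expect_equal(normal_order_scores(exp(x)), normal_order_scores(x))
  # tied groups share the averaged score
  s <- normal_order_scores(c(1, 1, 2))
  expect_equal(s[1], s[2])
  # all tied: all zero
  expect_equal(normal_order_scores(rep(7, 5)), rep(0, 5))
  expect_error(normal_order_scores(1), "at least 2")
})

test_that("d_statistic is rank-based and propagates failures", {
  set.seed(11)
  n <- 120
  pi_ <- rnorm(n)
  t <- rexp(n, exp(pi_)); e <- rbinom(n, 1, 0.7)
  d1 <- d_statistic(pi_, t, e)
  d2 <- d_statistic(100 * exp(pi_), t, e)  # monotone transform
  expect_equal(d1$estimate, d2$estimate)
  expect_equal(d1$se, d2$se)
  expect_true(d1$ci_low <= d1$estimate && d1$estimate <= d1$ci_high)
  expect_error(d_statistic(rep(1, n), t, e), "constant")
})

test_that("r2_from_d is the documented closed form", {
  expect_equal(r2_from_d(0), 0)
  d <- seq(0, 6, by = 0.25)
  r2 <- r2_from_d(d)
  expect_true(all(r2 >= 0 & r2 < 1))
  expect_true(all(diff(r2) > 0))  # monotone in |d|
  expect_equal(r2_from_d(-d), r2)
})

test_that("explained_randomness follows the loglik formula", {
  # l_beta = l_0 -> 0 ; l_beta - l_0 = k/2 -> 1 - exp(-1)
  expect_equal(valsize:::rho2_from_loglik(10, -50, -50), 0)
  expect_equal(valsize:::rho2_from_loglik(10, -45, -50), 1 - exp(-1))
  # monotone in the true effect size
  set.seed(21)
  n <- 600
  x <- rnorm(n)
  rho <- vapply(c(0.2, 0.6, 1.2), function(b) {
    t <- rexp(n, exp(b * x)); e <- rbinom(n, 1, 0.8)
    explained_randomness(x, t, e, bootstrap_reps = 0)$estimate
  }, numeric(1))
  expect_true(all(diff(rho) > 0))
  # near-null effect gives near-zero rho2
  t <- rexp(n); e <- rbinom(n, 1, 0.8)
  expect_lt(abs(explained_randomness(x, t, e, 0)$estimate), 0.02)
  # bootstrap SE is produced and positive
  m <- explained_randomness(x, rexp(n, exp(0.5 * x)), e, bootstrap_reps = 50)
  expect_gt(m$se, 0)
  expect_false(is.na(attr(m, "boot_skipped")))
})

test_that("brier_score reduces to the mean squared error without censoring", {
  set.seed(31)
  n <- 80
  risk <- runif(n, 0.05, 0.95)
  t <- rexp(n, 0.3)
  # everyone followed past the horizon or an observed event: G identically 1
  e <- rep(1L, n)
  bs <- brier_score(risk, t, e, t = max(t) + 1, bootstrap_reps = 0)
  expect_equal(bs$estimate, mean((e - risk)^2))
  # perfect foresight: risks at the boundary of (0,1) matching outcomes
  risk2 <- ifelse(t < 5, 1 - 1e-12, 1e-12)
  e2 <- rep(1L, n)
  expect_lt(brier_score(risk2, t, e2, t = 5, bootstrap_reps = 0)$estimate,
            1e-20)
})

test_that("brier_score matches the 6-row IPCW hand calculation", {
  t <- c(2, 4, 5, 7, 12, 13)
  e <- c(1, 0, 1, 0, 1, 0)
  risk <- c(0.8, 0.3, 0.6, 0.2, 0.5, 0.1)
  # G drops at the censorings 4, 7, 13: G=4/5 then 4/5*2/3; G(10)=8/15
  # terms: .2^2/1 ; 0 ; .4^2/(4/5) ; 0 ; .25/(8/15) ; .01/(8/15)
  hand <- (0.04 + 0.16 / 0.8 + 0.25 * 15 / 8 + 0.01 * 15 / 8) / 6
  bs <- brier_score(risk, t, e, t = 10, bootstrap_reps = 0)
  expect_equal(bs$estimate, hand)
  expect_equal(bs$estimate, 0.12125)
  # with g_left = FALSE the event at 5 is weighted by G(5) = G(4) too: same
  # here since no censoring at an event time, so pick one where it differs
  t2 <- c(2, 4, 4.5, 7, 12, 13)
  b1 <- brier_score(risk, t2, e, t = 10, bootstrap_reps = 0)$estimate
  b2 <- brier_score(risk, t2, e, t = 10, bootstrap_reps = 0,
                    g_left = FALSE)$estimate
  expect_equal(b1, b2)  # no event exactly at a censoring knot either
  expect_error(brier_score(risk, t, e, t = 20, bootstrap_reps = 0), "G\\(t\\)")
})

test_that("calibration_slope scales inversely with a rescaled PI", {
  set.seed(41)
  n <- 400
  pi_ <- rnorm(n)
  t <- rexp(n, exp(pi_)); e <- rbinom(n, 1, 0.6)
  s1 <- calibration_slope(pi_, t, e)
  s2 <- calibration_slope(2 * pi_, t, e)
  expect_equal(s2$estimate, s1$estimate / 2, tolerance = 1e-8)
  expect_error(calibration_slope(rep(0, n), t, e), "constant")
})

test_that("calibration_curve falls back audibly on degenerate data", {
  set.seed(51)
  n <- 40  # too small for a stable 4-df spline fit with 3 events
  risk <- runif(n, 0.01, 0.2)
  t <- rexp(n, 0.02)
  e <- integer(n); e[order(t)[1:3]] <- 1L
  expect_message(
    cc <- calibration_curve(risk, pmin(t, 15), e, t = 10),
    "falling back")
  expect_s3_class(cc, "calibration_curve")
  expect_true(attr(cc, "method") %in% c("decile_km", "spline"))
  expect_error(calibration_curve(rep(0.5, 10), rexp(10), rep(1, 10)),
               "distinct")
})

test_that("validation_measures assembles all six with NA for failed fits", {
  set.seed(61)
  n <- 300
  pi_ <- rnorm(n)
  coh <- data.frame(id = 1:n, time = rexp(n, exp(0.5 * pi_)),
                    event = rbinom(n, 1, 0.5), pi = pi_,
                    risk10 = plogis(pi_))
  ms <- validation_measures(coh, t_horizon = 2, bootstrap_reps = 25)
  expect_equal(ms$name, c("c_index", "d_stat", "r2_d", "rho2_oxs", "brier",
                          "cal_slope"))
  expect_true(all(is.finite(ms$estimate)))
  # r2_d is the deterministic transform of d_stat
  expect_equal(ms$estimate[ms$name == "r2_d"],
               r2_from_d(ms$estimate[ms$name == "d_stat"]))
  # constant PI: cox-based measures missing, c-index 0.5
  coh$pi <- 1
  ms2 <- validation_measures(coh, t_horizon = 2, bootstrap_reps = 0)
  expect_equal(ms2$estimate[ms2$name == "c_index"], 0.5)
  expect_true(all(is.na(ms2$estimate[ms2$name %in%
                                       c("d_stat", "r2_d", "cal_slope")])))
})
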