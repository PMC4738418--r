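test_that("constructors validate their inputs", {
  expect_error(covariate_spec(correlation = 1), "correlation")
  expect_error(covariate_spec(n_covariates = 0), "n_covariates")
  expect_error(true_data_model(baseline_rate = -1), "baseline_rate")
  expect_error(true_data_model(baseline_shape = 0), "baseline_shape")
  expect_error(true_data_model(target_event_fraction = 1.2), "target")
  expect_error(prognostic_model(1, s0_10 = 1), "s0_10")
  spec <- covariate_spec(3, 0.5, scales = c(1, 2, 0.5))
  expect_s3_class(spec, "covariate_spec")
})

test_that("generate_population: censoring mechanics and determinism", {
  spec <- covariate_spec(3)
  model <- true_data_model(beta_true = rep(0.3, 3), censor_rate = 0,
                           admin_horizon = Inf)
  pop <- generate_population(spec, model, 500, seed = 1)
  expect_true(all(pop$event == 1L))  # no censoring mechanism at all
  expect_true(all(pop$time >= 0))
  expect_true(all(pop$risk10 > 0 & pop$risk10 < 1))

  model2 <- true_data_model(beta_true = rep(0.3, 3))
  p1 <- generate_population(spec, model2, 500, seed = 7)
  p2 <- generate_population(spec, model2, 500, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(
    p1, generate_population(spec, model2, 500, seed = 8)))
  # censored rows never exceed the administrative horizon
  expect_true(all(p1$time <= model2$admin_horizon))
  expect_error(generate_population(spec, model2, 500, seed = NULL), "seed")
})

test_that("null-effect population reproduces the baseline Weibull", {
  spec <- covariate_spec(2)
  model <- true_data_model(beta_true = c(0, 0), baseline_rate = 0.01,
                           baseline_shape = 1.3, censor_rate = 0,
                           admin_horizon = Inf)
  pop <- generate_population(spec, model, 5000, seed = 3)
  # Kolmogorov-Smirnov style sup distance against the closed-form CDF
  tt <- sort(pop$time)
  emp <- seq_along(tt) / length(tt)
  theo <- 1 - exp(-model$baseline_rate * tt^model$baseline_shape)
  expect_lt(max(abs(emp - theo)), 1.63 / sqrt(5000))  # 1% KS critical value
})

test_that("calibrate_event_rate hits published event fractions to 0.1 pp", {
  spec <- covariate_spec()
  for (target in c(0.054, 0.0266)) {
    model <- true_data_model(target_event_fraction = target)
    cal <- calibrate_event_rate(spec, model, n_pilot = 5e4, seed = 13)
    pop <- generate_population(spec, cal, 5e4, seed = 13)
    expect_lte(abs(mean(pop$event) - target), 1e-3)
    expect_true(attr(cal, "calibration_converged"))
  }
})

test_that("calibrate_event_rate reports an unreachable target", {
  spec <- covariate_spec(2)
  model <- true_data_model(beta_true = c(0.2, 0.2), censor_rate = 0,
                           admin_horizon = Inf)
  # with no censoring everyone is an event whatever the rate
  expect_warning(cal <- calibrate_event_rate(spec, model, 1000, seed = 5),
                 "unreachable")
  expect_false(attr(cal, "calibration_converged"))
})

test_that("calibration is reproducible across pilot seeds", {
  spec <- covariate_spec()
  model <- true_data_model()
  c1 <- calibrate_event_rate(spec, model, 5e4, seed = 1)
  c2 <- calibrate_event_rate(spec, model, 5e4, seed = 2)
  expect_lt(abs(attr(c1, "achieved_fraction") -
                  attr(c2, "achieved_fraction")), 3e-3)
  expect_lt(abs(log(c1$baseline_rate / c2$baseline_rate)), 0.1)
})

test_that("make_validation_model controls the published model's deficiency", {
  truth <- true_data_model(beta_true = rep(0.25, 4))
  m1 <- make_validation_model(truth)  # shrinkage 1, no noise: the truth
  expect_equal(m1$beta_model, truth$beta_true)
  expect_equal(m1$s0_10, exp(-truth$baseline_rate * 10^truth$baseline_shape))
  m2 <- make_validation_model(truth, shrinkage = 2)
  expect_equal(m2$beta_model, 2 * truth$beta_true)
  expect_error(make_validation_model(truth, noise_sd = 0.1), "seed")
  m3 <- make_validation_model(truth, noise_sd = 0.1, seed = 4)
  expect_false(all(m3$beta_model == truth$beta_true))
})

test_that("downstream calibration slope tracks 1/shrinkage", {
  spec <- covariate_spec(4)
  truth <- true_data_model(beta_true = rep(0.35, 4))
  cal <- calibrate_event_rate(spec, truth, 3e4, seed = 17)
  for (g in c(0.5, 2)) {
    pm <- make_validation_model(cal, shrinkage = g)
    pop <- generate_population(spec, cal, 3e4, seed = 17,
                               published_model = pm)
    sl <- calibration_slope(pop$pi, pop$time, pop$event)
    expect_lt(abs(sl$estimate - 1 / g), 2.5 * sl$se + 0.02)
  }
})

test_that("true_performance needs events and tracks effect size", {
  spec <- covariate_spec(2)
  model <- true_data_model(beta_true = c(0.2, 0.2))
  pop <- generate_population(spec, model, 200, seed = 2)
  pop$event <- 0L
  expect_error(true_performance(pop), "event")
  # larger true coefficients give a larger true D
  d_of <- function(b) {
    m <- true_data_model(beta_true = rep(b, 2))
    cal <- calibrate_event_rate(spec, m, 2e4, seed = 23)
    p <- generate_population(spec, cal, 2e4, seed = 23)
    th <- true_performance(p)
    th$estimate[th$name == "d_stat"]
  }
  expect_gt(d_of(0.6), d_of(0.25))
})

test_that("cohort round-trips through CSV", {
  spec <- covariate_spec(2)
  model <- true_data_model(beta_true = c(0.2, 0.2))
  pop <- generate_population(spec, model, 50, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_cohort(pop, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(pop), tolerance = 1e-12)
  # validation on read
  bad <- pop; bad$event[1] <- 2
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_cohort(f2), "0/1")
  unlink(c(f, f2))
})
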