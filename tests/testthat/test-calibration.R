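# calibration scenario used throughout: a short synthetic episode with
# known parameters, refit from noisy or exact observations
calib_setup <- function() {
  series <- gen_heatwave_series(fixture_spec("custom", n_days = 28,
                                             plateau_days = 18,
                                             peak_tmax = 40, seed = 5))
  profile <- make_profile()
  truth <- make_params(profile = profile, beta_morb = 500, r_base = 30,
                       mu = 0.03, af0 = 0.35,
                       ma = table_function(c(35, 37.6, 40, 43),
                                           c(1, 1, 1.8, 2.4)),
                       hdaf = table_function(c(0, 6, 15), c(1, 1.4, 1.9)),
                       initial_ap = 5e4)
  list(series = series, profile = profile, truth = truth)
}

test_that("a spec with no free parameters evaluates the objective once", {
  s <- calib_setup()
  obs <- gen_observed_deaths(s$series, s$profile, s$truth, seed = 1,
                             noise = "none")
  res <- calibrate_model(obs, s$series, s$profile, calibration_spec(),
                         s$truth)
  expect_true(res$converged)
  expect_equal(res$n_evaluations, 1L)
  expect_length(res$fitted, 0)
  # noise-free observations differ from the model only by count rounding
  expect_lt(res$objective, nrow(obs) * 0.25 + 1e-9)
})

test_that("misaligned observation dates are rejected", {
  s <- calib_setup()
  obs <- gen_observed_deaths(s$series, s$profile, s$truth, seed = 1,
                             noise = "none")
  obs$date <- obs$date + 1
  expect_error(calibrate_model(obs, s$series, s$profile, calibration_spec(),
                               s$truth), "aligned")
})

test_that("headline parameters are recovered from model-generated data", {
  s <- calib_setup()
  spec <- calibration_spec(
    free = list(beta_morb = c(50, 2500), mu = c(0.003, 0.15),
                af0 = c(0.1, 0.8)),
    restarts = 8, maxit = 600, seed = 99)
  start <- s$truth
  start$exposure$beta_morb <- 150
  start$exposure$mu <- 0.06
  start$adaptation$af0 <- 0.5

  # exact (noise-free) observations: recovery within 1%
  obs0 <- gen_observed_deaths(s$series, s$profile, s$truth, seed = 1,
                              noise = "none")
  res0 <- calibrate_model(obs0, s$series, s$profile, spec, start)
  expect_lt(abs(res0$fitted[["beta_morb"]] - 500) / 500, 0.01)
  expect_lt(abs(res0$fitted[["mu"]] - 0.03) / 0.03, 0.01)
  expect_lt(abs(res0$fitted[["af0"]] - 0.35) / 0.35, 0.01)

  # Poisson observation noise: recovery within 10%
  obs1 <- gen_observed_deaths(s$series, s$profile, s$truth, seed = 7,
                              noise = "poisson")
  res1 <- calibrate_model(obs1, s$series, s$profile, spec, start)
  expect_lt(abs(res1$fitted[["beta_morb"]] - 500) / 500, 0.10)
  expect_lt(abs(res1$fitted[["mu"]] - 0.03) / 0.03, 0.10)
  expect_lt(abs(res1$fitted[["af0"]] - 0.35) / 0.35, 0.10)

  # bookkeeping: the optimum is at least as good as every start
  expect_true(all(res1$objective <= res1$start_objectives + 1e-9))
  expect_true(all(res1$fitted >= c(50, 0.003, 0.1) &
                    res1$fitted <= c(2500, 0.15, 0.8)))
})

test_that("with no heat signal the excess slope is driven to its floor", {
  profile <- make_profile()
  series <- make_series(rep(31, 30))   # no hot day at all
  truth <- make_params(profile = profile, beta_morb = 0, r_base = 0,
                       mu = 0.02, initial_ap = 0)
  obs <- gen_observed_deaths(series, profile, truth, seed = 3,
                             noise = "poisson")
  spec <- calibration_spec(free = list(beta_morb = c(0.01, 1000)),
                           restarts = 3, maxit = 200, seed = 5)
  res <- calibrate_model(obs, series, profile, spec, truth)
  # below the morbidity threshold the slope cannot matter; any value in the
  # bounds leaves the objective flat, so the fit must not move the deaths
  sim <- simulate_episode(series, profile, res$params)
  expect_equal(sim$data$deaths, rep(0, 30))
})

test_that("validation reports RMSE, relative peak error and peak lag", {
  obs <- data.frame(date = as.Date("2003-07-20") + 0:9,
                    deaths = c(100, 120, 150, 210, 260, 240, 180, 150, 120,
                               110))
  expect_equal(unclass(validate_fit(obs, obs$deaths)),
               list(rmse = 0, peak_value_error = 0, peak_lag_days = 0L))
  shifted <- c(obs$deaths[1], obs$deaths[-10])  # simulated peak one day late
  v <- validate_fit(obs, shifted)
  expect_equal(v$peak_lag_days, 1L)
  v2 <- validate_fit(obs, 2 * obs$deaths)
  expect_equal(v2$peak_value_error, 1.0)
  expect_equal(v2$rmse, sqrt(mean(obs$deaths^2)))
  # ties in the peak break to the earliest day
  flat <- rep(5, 10)
  expect_equal(validate_fit(obs, flat)$peak_lag_days, 1L - 5L)
  expect_error(validate_fit(obs[0, ], numeric(0)), "empty")
})

test_that("calibration is invariant to a constant shift of deaths and background", {
  s <- calib_setup()
  spec <- calibration_spec(free = list(mu = c(0.003, 0.15)), restarts = 2,
                           maxit = 300, seed = 11)
  obs <- gen_observed_deaths(s$series, s$profile, s$truth, seed = 2,
                             noise = "none")
  res_a <- calibrate_model(obs, s$series, s$profile, spec, s$truth)
  shift <- 50  # deaths per day, added to observations and to the background
  obs_b <- obs
  obs_b$deaths <- obs_b$deaths + shift
  pars_b <- s$truth
  pars_b$background_rate <- pars_b$background_rate +
    shift * 1e7 / total_population(s$profile)
  res_b <- calibrate_model(obs_b, s$series, s$profile, spec, pars_b)
  expect_equal(res_a$fitted[["mu"]], res_b$fitted[["mu"]], tolerance = 1e-6)
})
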