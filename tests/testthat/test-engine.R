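test_that("a single step reproduces the hand-computed flow split", {
  # stock 100, no inflow, af 0.3, mu*cf 0.1 -> treat 30, die 10, stock 60
  prof <- make_profile()
  params <- make_params(profile = prof, beta_morb = 0, r_base = 0,
                        mu = 0.1, af0 = 0.3, initial_ap = 100)
  state <- list(day = 0L, ap = 100, cum_treated = 0, cum_deaths = 0)
  st <- sd_step(state, 30, 0, prof, params)
  expect_equal(st$flows$apf, 0)
  expect_equal(st$flows$tpf, 30)
  expect_equal(st$flows$deaths, 10)
  expect_equal(st$state$ap, 60)
  expect_equal(st$state$day, 1L)
})

test_that("an empty system stays empty", {
  prof <- make_profile()
  params <- make_params(profile = prof, beta_morb = 0, r_base = 0,
                        mu = 0.05, initial_ap = 0)
  state <- list(day = 3L, ap = 0, cum_treated = 5, cum_deaths = 2)
  st <- sd_step(state, 42, 10, prof, params)
  expect_equal(st$flows$tpf, 0)
  expect_equal(st$flows$deaths, 0)
  expect_equal(st$state$ap, 0)
  expect_equal(st$state$day, 4L)
  expect_equal(st$state$cum_treated, 5)
})

test_that("outflow demand beyond the stock is scaled proportionally", {
  # af 0.9 and mu*cf 0.3 want 120 from a stock of 100: scale by 5/6,
  # preserving the 3:1 treated:death ratio, and empty the stock
  prof <- make_profile()
  params <- make_params(profile = prof, beta_morb = 0, r_base = 0,
                        mu = 0.3, af0 = 0.9, initial_ap = 100)
  st <- sd_step(list(day = 0L, ap = 100, cum_treated = 0, cum_deaths = 0),
                30, 0, prof, params)
  expect_equal(st$flows$tpf + st$flows$deaths, 100)
  expect_equal(st$flows$tpf / st$flows$deaths, 0.9 / 0.3)
  expect_equal(st$state$ap, 0)
})

test_that("no forcing means zero heat deaths on every day", {
  prof <- make_profile()
  params <- make_params(profile = prof, beta_morb = 0, r_base = 0,
                        mu = 0.05, initial_ap = 0)
  sim <- simulate_episode(make_series(rep(40, 10)), prof, params)
  expect_equal(sim$data$deaths, rep(0, 10))
  expect_equal(sim$data$ap, rep(0, 10))
  # but the reported totals still carry the background level
  expect_equal(sim$data$total_deaths,
               rep(total_population(prof) / 1e7 * 114, 10))
})

test_that("mass balance holds exactly over random parameter draws", {
  set.seed(42)
  prof <- make_profile()
  for (i in 1:10) {
    params <- random_params(prof)
    tmax <- round(runif(30, 31, 42), 1)
    sim <- simulate_episode(make_series(tmax), prof, params)
    d <- sim$data
    lhs <- sim$initial_ap + sum(d$apf)
    rhs <- d$ap[30] + sum(d$tpf) + sum(d$deaths)
    expect_equal(lhs, rhs, tolerance = 1e-9)
    expect_true(all(d$ap >= 0))
    expect_true(all(d$apf >= 0 & d$tpf >= 0 & d$deaths >= 0))
  }
})

test_that("the engine matches iterating the public single step", {
  set.seed(9)
  prof <- make_profile()
  params <- random_params(prof)
  s <- make_series(round(runif(25, 31, 42), 1))
  sim <- simulate_episode(s, prof, params)
  state <- list(day = 0L, ap = params$initial_ap, cum_treated = 0,
                cum_deaths = 0)
  for (i in 1:25) {
    st <- sd_step(state, s$tmax[i], hot_day_count(s, i), prof, params)
    state <- st$state
    expect_equal(state$ap, sim$data$ap[i], tolerance = 1e-12)
    expect_equal(st$flows$deaths, sim$data$deaths[i], tolerance = 1e-12)
  }
})

test_that("the engine matches an independent straight-line re-implementation", {
  # oracle_simulate (helper-oracle.R) writes the model equations out
  # directly with manual interpolation; simulated with a profile that
  # differs from the normalisation reference so every factor is exercised
  set.seed(1234)
  ref_prof <- make_profile()
  for (i in 1:10) {
    params <- random_params(ref_prof)
    prof <- make_profile(beds = runif(1, 300, 3000),
                         staff = runif(1, 500, 5000),
                         ac_rate = runif(1, 0.3, 1),
                         income = runif(1, 500, 6000),
                         allowance = runif(1, 100, 1500),
                         insurance = runif(1, 0.3, 1))
    tmax <- round(runif(20, 31, 42), 1)
    sim <- simulate_episode(make_series(tmax), prof, params)$data
    ref <- oracle_simulate(tmax, prof, params)
    expect_equal(sim$deaths, ref$deaths, tolerance = 1e-9)
    expect_equal(sim$tpf, ref$tpf, tolerance = 1e-9)
    expect_equal(sim$ap, ref$ap, tolerance = 1e-9)
  }
})

test_that("scenario transformations act on the inputs as declared", {
  prof <- make_profile(allowance = 790)
  params <- make_params(profile = prof)
  s <- make_series(c(33, 36, 37, 38, 36, 33))
  up <- simulate_episode(s, prof, params,
                         scenario("temp_offset", delta_temp = 1))
  expect_equal(up$data$tmax, s$tmax + 1)
  # 790 * 1.2 = 948: the allowance scenario is exactly this multiplication
  expect_equal(heatsd:::scenario_profile(prof, scenario("allowance_increase"), 5)$allowance,
               948)
  expect_equal(heatsd:::scenario_profile(prof, scenario("bed_readiness"), 5)$beds,
               prof$beds * 1.2)
  # before the warning day the profile is untouched
  late <- scenario("bed_readiness", warning_day = 4)
  expect_equal(heatsd:::scenario_profile(prof, late, 2)$beds, prof$beds)
  expect_equal(heatsd:::scenario_profile(prof, late, 4)$beds, prof$beds * 1.2)
})

test_that("extra treatment capacity never increases any day's deaths", {
  set.seed(77)
  prof <- make_profile()
  for (i in 1:8) {
    params <- random_params(prof)
    s <- make_series(round(runif(20, 33, 41), 1))
    base <- simulate_episode(s, prof, params)$data$deaths
    beds <- simulate_episode(s, prof, params,
                             scenario("bed_readiness"))$data$deaths
    allow <- simulate_episode(s, prof, params,
                              scenario("allowance_increase"))$data$deaths
    expect_true(all(beds <= base + 1e-12))
    expect_true(all(allow <= base + 1e-12))
  }
})

test_that("warming never decreases deaths while the stock is not exhausted", {
  # per-day monotonicity in temperature holds in the interior regime; once
  # outflows hit the stock-exhaustion clamp, earlier extra deaths can
  # deplete the stock and lower a later day's toll
  set.seed(78)
  prof <- make_profile()
  unclamped <- function(sim) {
    d <- sim$data
    ap_prev <- c(sim$initial_ap, d$ap[-nrow(d)])
    all(d$tpf + d$deaths < ap_prev + d$apf - 1e-9 | ap_prev + d$apf == 0)
  }
  for (i in 1:8) {
    params <- make_params(profile = prof,
                          beta_morb = runif(1, 10, 300),
                          r_base = runif(1, 0, 50),
                          mu = runif(1, 0.001, 0.02),
                          af0 = runif(1, 0.1, 0.5),
                          ma = table_function(c(35, 37.6, 41, 43),
                                              c(1, 1, 1.6, 1.9)),
                          hdaf = table_function(c(0, 10, 20), c(1, 1.3, 1.5)),
                          initial_ap = runif(1, 0, 1e5))
    s <- make_series(round(runif(20, 33, 41), 1))
    base <- simulate_episode(s, prof, params)
    hot <- simulate_episode(s, prof, params,
                            scenario("temp_offset", delta_temp = 1))
    expect_true(unclamped(base))
    expect_true(unclamped(hot))
    expect_true(all(hot$data$deaths >= base$data$deaths - 1e-12))
    # cumulative deaths rise with warming here too
    expect_gte(sum(hot$data$deaths), sum(base$data$deaths))
  }
})

test_that("scenario comparison computes per-day reductions and episode days", {
  prof <- make_profile()
  params <- make_params(profile = prof, ma = table_function(c(35, 42), c(1, 2)))
  s <- make_series(c(33, 36, 37, 38, 39, 38, 37, 36, 33))
  base <- simulate_episode(s, prof, params)
  cmp <- compare_scenarios(base, base)
  expect_equal(cmp$reduction, rep(0, 9))
  expect_equal(cmp$pct_reduction, rep(0, 9))
  # episode days are the 1-based position inside the hot run
  expect_equal(cmp$episode_day, c(NA, 1:7, NA))
  alt <- simulate_episode(s, prof, params, scenario("bed_readiness"))
  cmp <- compare_scenarios(base, alt)
  expect_equal(cmp$reduction,
               base$data$total_deaths - alt$data$total_deaths)
  i <- 5
  expect_equal(cmp$pct_reduction[i],
               100 * cmp$reduction[i] / base$data$total_deaths[i])
  short <- simulate_episode(make_series(c(36, 37)), prof, params)
  expect_error(compare_scenarios(base, short), "length")
})

test_that("routing CF into the inflow is off by default and acts when enabled", {
  prof <- make_profile()
  ma <- table_function(c(35, 40), c(1, 2))
  base <- make_params(profile = prof, beta_morb = 100, r_base = 0,
                      mu = 0.01, ma = ma, initial_ap = 0)
  routed <- base
  routed$exposure$cf_on_apf <- TRUE
  s <- make_series(c(38, 38, 38))
  apf_base <- simulate_episode(s, prof, base)$data$apf
  apf_routed <- simulate_episode(s, prof, routed)$data$apf
  cf <- climate_factor(38, 1:3, ma, base$hdaf)
  expect_equal(apf_routed, apf_base * cf)
})
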