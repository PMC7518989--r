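# Stock-flow engine: forward-Euler integration at a 1-day step, scenario
# transformations, and baseline/scenario comparison.

#' Define a simulation scenario
#'
#' A scenario is a declarative transformation of the baseline inputs:
#' `temp_offset` adds `delta_temp` degrees to every day's temperatures;
#' `bed_readiness` raises hospital beds by `bed_fraction` (the short-term
#' emergency-response measure, default 20%); `allowance_increase` multiplies
#' the minimum living allowance by `allowance_multiplier` (the long-term
#' measure, default 1.2). The two mitigation measures are active from
#' `warning_day` onwards; the default of day 1 corresponds to a warning
#' received before the episode starts.
#'
#' @param kind one of `"baseline"`, `"temp_offset"`, `"bed_readiness"`,
#'   `"allowance_increase"`.
#' @param delta_temp temperature offset, degrees C (`temp_offset` only).
#' @param bed_fraction fractional increase in beds (>= 0), default 0.20.
#' @param allowance_multiplier allowance ratio (> 0), default 1.20.
#' @param warning_day 1-based first active day of a mitigation measure.
#' @return A list of class `scenario`.
#' @export
scenario <- function(kind = c("baseline", "temp_offset", "bed_readiness",
                              "allowance_increase"),
                     delta_temp = 0, bed_fraction = 0.20,
                     allowance_multiplier = 1.20, warning_day = 1) {
  kind <- match.arg(kind)
  if (bed_fraction < 0) stop("`bed_fraction` must be >= 0", call. = FALSE)
  if (allowance_multiplier <= 0) stop("`allowance_multiplier` must be > 0", call. = FALSE)
  if (warning_day < 1) stop("`warning_day` must be >= 1", call. = FALSE)
  structure(list(kind = kind, delta_temp = delta_temp,
                 bed_fraction = bed_fraction,
                 allowance_multiplier = allowance_multiplier,
                 warning_day = as.integer(warning_day)),
            class = "scenario")
}

# profile as seen on `day` under `scn`
scenario_profile <- function(profile, scn, day) {
  if (day < scn$warning_day) return(profile)
  if (scn$kind == "bed_readiness") {
    profile$beds <- profile$beds * (1 + scn$bed_fraction)
  } else if (scn$kind == "allowance_increase") {
    profile$allowance <- profile$allowance * scn$allowance_multiplier
  }
  profile
}

#' Advance the stock-flow system by one day
#'
#' One forward-Euler step of the affected-population stock: computes the
#' affected inflow, the treated outflow `TPF = AP * AF` and the death
#' outflow `AP * mu * CF`, scales both outflows proportionally if together
#' they would exceed the stock plus the day's inflow, and updates
#' `AP <- AP + APF - TPF - deaths`.
#'
#' @param state list with elements `day`, `ap`, `cum_treated`, `cum_deaths`.
#' @param tmax the day's maximum temperature, degrees C.
#' @param hot_days the day's consecutive hot-day count.
#' @param profile the [city_profile()] in force on this day.
#' @param params a [model_params()].
#' @return A list with the updated `state` and a `flows` record
#'   (`apf`, `tpf`, `deaths`, `af`, `cf`).
#' @export
sd_step <- function(state, tmax, hot_days, profile, params) {
  exp_pars <- params$exposure
  ad_pars <- params$adaptation
  apf <- affected_flow(tmax, exposed_population(profile, exp_pars), exp_pars)
  ec <- economic_factor(profile, ad_pars)
  hf <- health_factor(profile, ad_pars)
  gf <- governance_factor(profile, ad_pars)
  af <- adaptation_factor(ec, hf, gf, ad_pars)
  cf <- climate_factor(tmax, hot_days, params$ma, params$hdaf)
  if (exp_pars$cf_on_apf) apf <- apf * cf
  tpf <- treated_flow(state$ap, af)
  d <- death_flow(state$ap, cf, exp_pars$mu)
  avail <- state$ap + apf
  out <- tpf + d
  if (out > avail && out > 0) {          # conservation clamp
    s <- avail / out
    tpf <- tpf * s
    d <- d * s
  }
  if (!all(is.finite(c(apf, tpf, d))) || apf < 0 || tpf < 0 || d < 0) {
    stop(sprintf("non-finite or negative flow at day %d (apf=%g tpf=%g deaths=%g)",
                 state$day + 1L, apf, tpf, d), call. = FALSE)
  }
  ap_new <- max(state$ap + apf - tpf - d, 0)
  list(state = list(day = state$day + 1L, ap = ap_new,
                    cum_treated = state$cum_treated + tpf,
                    cum_deaths = state$cum_deaths + d),
       flows = list(apf = apf, tpf = tpf, deaths = d, af = af, cf = cf))
}

#' Simulate the heat-wave episode under a scenario
#'
#' Applies the scenario transformation to the inputs, then integrates the
#' stock-flow system over every day of the series with a 1-day time step.
#' Reported `total_deaths` are the heat-attributable death flow plus a
#' constant background (the cool-day mortality level of the city), so
#' trajectories are comparable to observed total daily death series.
#' Deterministic given its inputs.
#'
#' @param series a [temperature_series()].
#' @param profile a [city_profile()].
#' @param params a [model_params()].
#' @param scn a [scenario()]; default baseline.
#' @param initial_ap initial affected stock, persons; defaults to
#'   `params$initial_ap`.
#' @return An object of class `simulation_result`: a list with `data` (a
#'   data frame with one row per day and columns `day`, `date`, `tmax`,
#'   `hot_days`, `apf`, `tpf`, `deaths`, `ap`, `total_deaths`), the
#'   `scenario`, `initial_ap`, the constant `background` (persons/day) and a
#'   parameter `fingerprint`.
#' @export
simulate_episode <- function(series, profile, params, scn = scenario("baseline"),
                             initial_ap = params$initial_ap) {
  series <- as_temperature_series(series)
  stopifnot(inherits(profile, "city_profile"), inherits(params, "model_params"),
            inherits(scn, "scenario"))
  if (initial_ap < 0) stop("`initial_ap` must be >= 0", call. = FALSE)
  if (scn$kind == "temp_offset") series <- apply_offset(series, scn$delta_temp)
  n <- nrow(series)
  hot_days <- hot_day_runs(series$tmax)
  exp_pars <- params$exposure
  ad_pars <- params$adaptation
  # a scenario yields at most two distinct profiles: before and from the
  # warning day; precompute the day-constant quantities for both
  day_pars <- function(prof) {
    af <- adaptation_factor(economic_factor(prof, ad_pars),
                            health_factor(prof, ad_pars),
                            governance_factor(prof, ad_pars), ad_pars)
    list(af = af, pop = exposed_population(prof, exp_pars))
  }
  pre <- day_pars(profile)
  post <- day_pars(scenario_profile(profile, scn, scn$warning_day))
  active <- seq_len(n) >= scn$warning_day
  af_vec <- ifelse(active, post$af, pre$af)
  pop_vec <- ifelse(active, post$pop, pre$pop)
  apf_vec <- (pop_vec / 1e7) *
    (exp_pars$r_base + exp_pars$beta_morb *
       pmax(0, series$tmax - exp_pars$t_morb))
  cf_vec <- climate_factor(series$tmax, hot_days, params$ma, params$hdaf)
  if (exp_pars$cf_on_apf) apf_vec <- apf_vec * cf_vec
  mu <- exp_pars$mu
  ap <- initial_ap
  ap_vec <- tpf_vec <- d_vec <- numeric(n)
  for (i in seq_len(n)) {
    apf <- apf_vec[i]
    tpf <- ap * af_vec[i]
    d <- ap * mu * cf_vec[i]
    avail <- ap + apf
    out <- tpf + d
    if (out > avail && out > 0) {        # conservation clamp
      s <- avail / out
      tpf <- tpf * s
      d <- d * s
    }
    ap <- max(ap + apf - tpf - d, 0)
    ap_vec[i] <- ap
    tpf_vec[i] <- tpf
    d_vec[i] <- d
  }
  if (!all(is.finite(c(apf_vec, tpf_vec, d_vec)))) {
    stop("non-finite flow encountered; check parameters", call. = FALSE)
  }
  bg <- background_deaths(profile, params)
  data <- data.frame(day = seq_len(n), date = series$date, tmax = series$tmax,
                     hot_days = hot_days, apf = apf_vec,
                     tpf = tpf_vec, deaths = d_vec,
                     ap = ap_vec,
                     total_deaths = d_vec + bg)
  structure(list(data = data, scenario = scn, initial_ap = initial_ap,
                 background = bg, fingerprint = params_fingerprint(params)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  d <- x$data
  cat(sprintf("simulation_result: %d days, scenario `%s` [params %s]\n",
              nrow(d), x$scenario$kind, x$fingerprint))
  cat(sprintf("  cumulative heat-attributable deaths: %.1f; peak total daily deaths: %.1f (day %d)\n",
              sum(d$deaths), max(d$total_deaths), which.max(d$total_deaths)))
  invisible(x)
}

#' Compare a scenario run against its baseline
#'
#' Per-day absolute and percentage reductions in total daily deaths of a
#' scenario run relative to the baseline run:
#' `reduction = baseline - scenario` and
#' `pct_reduction = 100 * reduction / baseline` (NA where the baseline is
#' zero). `episode_day` numbers days 1-based within the run of consecutive
#' hot days of the baseline series, matching how mitigation results are
#' reported ("day 7", "day 8" of the heat wave); it is NA on cool days.
#'
#' @param baseline,alt [simulate_episode()] results of equal length.
#' @return A data frame with columns `day`, `episode_day`,
#'   `deaths_baseline`, `deaths_scenario`, `reduction`, `pct_reduction`,
#'   with attribute `peak_days`: the two episode days with the largest
#'   percentage reduction, in decreasing order.
#' @export
compare_scenarios <- function(baseline, alt) {
  stopifnot(inherits(baseline, "simulation_result"),
            inherits(alt, "simulation_result"))
  b <- baseline$data; a <- alt$data
  if (nrow(b) != nrow(a)) stop("runs have different lengths", call. = FALSE)
  red <- b$total_deaths - a$total_deaths
  pct <- ifelse(b$total_deaths > 0, 100 * red / b$total_deaths, NA_real_)
  epi <- ifelse(b$hot_days > 0, b$hot_days, NA_integer_)
  out <- data.frame(day = b$day, episode_day = epi,
                    deaths_baseline = b$total_deaths,
                    deaths_scenario = a$total_deaths,
                    reduction = red, pct_reduction = pct)
  in_epi <- !is.na(out$episode_day)
  ord <- order(-out$pct_reduction[in_epi], out$day[in_epi])
  attr(out, "peak_days") <- out$episode_day[in_epi][ord][seq_len(min(2L, sum(in_epi)))]
  out
}
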