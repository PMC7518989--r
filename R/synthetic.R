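# Synthetic input generators: stylized heat-wave temperature fixtures,
# city profiles and Poisson daily death series. Every generator is a pure
# function of its spec and seed, so all downstream stages are testable
# without external data.

# run expr under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic heat-wave temperature fixture
#'
#' The presets are stylized stand-ins for the two historical Shanghai
#' episodes the model is exercised on: `hw2003` emulates the 19-day extreme
#' event of July/August 2003 and `hw2013` the 15-day event of July 2013.
#' The real station records are not redistributable, so the fixtures are a
#' smooth rise-plateau-fall profile: cool shoulder days around
#' `shoulder_tmax`, then exactly `plateau_days` consecutive days above
#' 35 degrees C whose maximum equals `peak_tmax`, with small seeded
#' day-to-day jitter that never moves a day across the 35 degree threshold.
#'
#' @param kind `"hw2003"`, `"hw2013"` or `"custom"`. Presets fill all other
#'   fields; pass them explicitly with `kind = "custom"`.
#' @param n_days total series length, days.
#' @param plateau_days number of consecutive days above 35 degrees C.
#' @param peak_tmax episode maximum temperature, degrees C.
#' @param shoulder_tmax typical shoulder-day maximum, degrees C (< 35).
#' @param shape `"arc"` for a single half-sine bump, `"twin_peak"` for a
#'   primary peak followed by a dip and a weaker secondary peak late in the
#'   episode (the qualitative trajectory of the July 2013 event, whose
#'   hottest spells came in two waves).
#' @param start_date first calendar day of the series.
#' @param seed integer seed for the jitter.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("hw2013", "hw2003", "custom"),
                         n_days = NULL, plateau_days = NULL, peak_tmax = NULL,
                         shoulder_tmax = NULL, shape = NULL,
                         start_date = NULL, seed = NULL) {
  kind <- match.arg(kind)
  preset <- switch(kind,
    hw2013 = list(n_days = 21L, plateau_days = 15L, peak_tmax = 40.5,
                  shoulder_tmax = 32, shape = "twin_peak",
                  start_date = as.Date("2013-07-13"), seed = 2013L),
    hw2003 = list(n_days = 25L, plateau_days = 19L, peak_tmax = 40.0,
                  shoulder_tmax = 32, shape = "arc",
                  start_date = as.Date("2003-07-17"), seed = 2003L),
    custom = list(n_days = 21L, plateau_days = 15L, peak_tmax = 40.5,
                  shoulder_tmax = 32, shape = "arc",
                  start_date = as.Date("2013-07-13"), seed = 1L))
  spec <- list(kind = kind,
               n_days = as.integer(n_days %||% preset$n_days),
               plateau_days = as.integer(plateau_days %||% preset$plateau_days),
               peak_tmax = peak_tmax %||% preset$peak_tmax,
               shoulder_tmax = shoulder_tmax %||% preset$shoulder_tmax,
               shape = match.arg(shape %||% preset$shape,
                                 c("arc", "twin_peak")),
               start_date = as.Date(start_date %||% preset$start_date),
               seed = as.integer(seed %||% preset$seed))
  if (spec$plateau_days > spec$n_days) {
    stop("`plateau_days` cannot exceed `n_days`", call. = FALSE)
  }
  if (spec$plateau_days > 0L && spec$peak_tmax <= 35.6) {
    stop("`peak_tmax` must exceed 35.6 for a detectable plateau", call. = FALSE)
  }
  if (spec$shoulder_tmax >= 34.5) {
    stop("`shoulder_tmax` must stay below 34.5", call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalised plateau templates: fraction of episode -> fraction of the
# (peak - 35.5) span. "arc" is a half-sine; "twin_peak" has its primary
# maximum at mid-episode and a weaker secondary maximum around four fifths
# of the way through, like the two hot spells of the July 2013 event.
plateau_shape <- function(shape, frac) {
  if (shape == "arc") return(sin(pi * frac))
  knots_f <- c(0, 0.100, 0.233, 0.300, 0.367, 0.433, 0.500, 0.567, 0.633,
               0.700, 0.767, 0.833, 0.900, 1)
  knots_s <- c(0.12, 0.40, 0.76, 0.86, 0.92, 0.94, 1.00, 0.70, 0.56, 0.62,
               0.88, 0.60, 0.36, 0.12)
  stats::approx(knots_f, knots_s, xout = frac, rule = 2)$y
}

#' Generate a stylized heat-wave temperature series
#'
#' Deterministic given the spec (whose seed drives the jitter). The plateau
#' rises from just above 35 degrees C to `peak_tmax` and falls back,
#' following either a half-sine arc or a twin-peak template (see
#' [fixture_spec()]); jitter is +/- 0.3 degrees C, rounded to 0.01 degrees
#' C, clamped so hot days stay above 35.5 and shoulder days below 34.5.
#' Episode durations are therefore exact by construction; preset shoulders
#' sit near 32 degrees, so the +1 and +2 degree offset scenarios leave them
#' below the 35 degree threshold and the episode length unchanged.
#'
#' @param spec a [fixture_spec()].
#' @return A [temperature_series()] with `tmax`, `tmean`, `tmin`, `humidity`.
#' @export
gen_heatwave_series <- function(spec = fixture_spec("hw2013")) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_days
  p <- spec$plateau_days
  lead <- (n - p) %/% 2L
  base <- rep(spec$shoulder_tmax, n)
  if (p > 0L) {
    j <- seq_len(p)
    base[lead + j] <- 35.5 + (spec$peak_tmax - 35.5) *
      plateau_shape(spec$shape, (j - 0.5) / p)
  }
  jit <- with_local_seed(spec$seed, stats::runif(n, -0.3, 0.3))
  tmax <- base + jit
  hot <- logical(n)
  if (p > 0L) hot[lead + seq_len(p)] <- TRUE
  tmax[hot] <- pmin(pmax(tmax[hot], 35.6), spec$peak_tmax - 0.05)
  tmax[!hot] <- pmin(tmax[!hot], 34.2)
  if (p > 0L) tmax[lead + which.max(base[lead + seq_len(p)])] <- spec$peak_tmax
  tmax <- round(tmax, 2)
  temperature_series(
    date = spec$start_date + seq_len(n) - 1L,
    tmax = tmax,
    tmean = round(tmax - 4.5, 2),
    tmin = round(tmax - 8, 2),
    humidity = pmin(100, pmax(30, round(78 - 1.5 * (tmax - 32))))
  )
}

#' Generate a synthetic city indicator profile
#'
#' Fixed, documented yearbook-like profiles for the study city. The 2013
#' profile carries the indicators the mitigation scenarios act on: a total
#' population of 24.1 million (about 15% aged over 65) and a minimum living
#' allowance of 790 currency units per month. The 2003 profile differs in
#' population, income, air-conditioning usage, health-system capacity,
#' allowance and insurance coverage, reflecting a decade of growth. These
#' are synthetic stand-ins on the published order of magnitude, not
#' yearbook extracts.
#'
#' @param year_like `"y2013"` or `"y2003"`.
#' @return A [city_profile()].
#' @export
gen_city_profile <- function(year_like = c("y2013", "y2003")) {
  year_like <- match.arg(year_like)
  switch(year_like,
    y2013 = city_profile(pop_under14 = 2.41e6, pop_15_64 = 18.075e6,
                         pop_over65 = 3.615e6, hospitals = 338,
                         beds = 113000, staff = 178000, ac_rate = 0.95,
                         income = 3650, allowance = 790, insurance = 0.95),
    y2003 = city_profile(pop_under14 = 2.0e6, pop_15_64 = 14.2e6,
                         pop_over65 = 1.9e6, hospitals = 290,
                         beds = 80000, staff = 120000, ac_rate = 0.70,
                         income = 1250, allowance = 290, insurance = 0.60))
}

#' Generate background (non-heat-wave) daily death counts
#'
#' Draws day `t` deaths from `Poisson(lambda_t)` with
#' `lambda_t = population/1e7 * 114` on cool days (`tmax <= 35`) and
#' `population/1e7 * 124` on hot days: the observed step in summer daily
#' mortality per ten million residents across the 35 degree threshold.
#'
#' @param series a [temperature_series()].
#' @param population total population, persons (> 0).
#' @param seed integer seed.
#' @param cool_rate,hot_rate deaths per ten million population per day below
#'   and above the 35 degree threshold.
#' @return A data frame with columns `date`, `deaths` (integer).
#' @export
gen_baseline_mortality <- function(series, population, seed,
                                   cool_rate = 114, hot_rate = 124) {
  series <- as_temperature_series(series)
  if (population <= 0) stop("`population` must be > 0", call. = FALSE)
  lambda <- population / 1e7 * ifelse(series$tmax > 35, hot_rate, cool_rate)
  deaths <- with_local_seed(seed, stats::rpois(nrow(series), lambda))
  data.frame(date = series$date, deaths = as.integer(deaths))
}

#' Forward-simulate an observed daily death series
#'
#' Ground truth for parameter-recovery experiments: runs the stock-flow
#' model under the baseline scenario with `true_params`, yielding total
#' expected daily deaths (heat-attributable flow plus the cool-day
#' background), then applies observation noise. `noise = "poisson"` draws
#' each day from a Poisson with that mean; `noise = "none"` rounds the
#' expectation (half-up) to integer counts.
#'
#' @param series a [temperature_series()].
#' @param profile a [city_profile()].
#' @param true_params a [model_params()].
#' @param seed integer seed (used only for `noise = "poisson"`).
#' @param noise `"poisson"` or `"none"`.
#' @return A data frame with columns `date`, `deaths` (integer).
#' @export
gen_observed_deaths <- function(series, profile, true_params, seed,
                                noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  sim <- simulate_episode(series, profile, true_params)
  lambda <- sim$data$total_deaths
  deaths <- switch(noise,
    poisson = with_local_seed(seed, stats::rpois(length(lambda), lambda)),
    none = floor(lambda + 0.5))
  data.frame(date = sim$data$date, deaths = as.integer(deaths))
}
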