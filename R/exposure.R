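# Exposure-response: temperature -> affected-people inflow (APF) and the
# climate severity factor (CF) multiplying the death flow.

#' Exposure-response parameters
#'
#' Thresholds and rates linking daily maximum temperature to the inflow of
#' heat-affected people and to heat-attributable deaths. The morbidity
#' threshold (36.6 degrees C) and the mortality threshold (37.6 degrees C)
#' come from the fitted exceedance relationships for Shanghai/Ningbo summer
#' data; the slopes and baseline rates are calibrated, not published.
#'
#' @param t_morb morbidity threshold, degrees C: excess affected inflow is
#'   proportional to `max(0, tmax - t_morb)`.
#' @param t_mort mortality threshold, degrees C; must exceed `t_morb`. It
#'   enters through the MA table, which stays at 1 below this temperature.
#' @param beta_morb affected persons per ten million population per degree C
#'   exceedance per day (>= 0).
#' @param r_base baseline affected persons per ten million population per day
#'   (>= 0), independent of temperature.
#' @param mu baseline per-day case-fatality fraction of the affected stock,
#'   in \[0, 1\].
#' @param vuln_over65 dimensionless vulnerability loading on the share of the
#'   population aged over 65: the exposed population is
#'   `total * (1 + vuln_over65 * share_over65)`.
#' @param cf_on_apf logical; when `TRUE` the climate severity factor also
#'   multiplies the affected inflow. Off by default (CF amplifies outcomes,
#'   adaptation governs treatment); provided for sensitivity analysis.
#' @return A list of class `exposure_params`.
#' @export
exposure_params <- function(t_morb = 36.6, t_mort = 37.6, beta_morb = 0,
                            r_base = 0, mu = 0, vuln_over65 = 1,
                            cf_on_apf = FALSE) {
  if (!(t_mort > t_morb)) {
    stop("`t_mort` must exceed `t_morb`", call. = FALSE)
  }
  if (beta_morb < 0) stop("`beta_morb` must be >= 0", call. = FALSE)
  if (r_base < 0) stop("`r_base` must be >= 0", call. = FALSE)
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]", call. = FALSE)
  if (vuln_over65 < 0) stop("`vuln_over65` must be >= 0", call. = FALSE)
  structure(list(t_morb = t_morb, t_mort = t_mort, beta_morb = beta_morb,
                 r_base = r_base, mu = mu, vuln_over65 = vuln_over65,
                 cf_on_apf = isTRUE(cf_on_apf)),
            class = "exposure_params")
}

#' Affected-people inflow (APF)
#'
#' Daily inflow of heat-affected people: a baseline rate plus a linear
#' excess above the morbidity threshold, both scaled per ten million of the
#' exposed population:
#' `APF = population/1e7 * (r_base + beta_morb * max(0, tmax - t_morb))`.
#'
#' @param tmax daily maximum temperature, degrees C (vectorised).
#' @param population exposed population, persons (> 0).
#' @param params an [exposure_params()].
#' @return Inflow in persons/day, never negative.
#' @export
affected_flow <- function(tmax, population, params) {
  if (!is.numeric(population) || length(population) != 1L || population <= 0) {
    stop("`population` must be a single positive number", call. = FALSE)
  }
  (population / 1e7) *
    (params$r_base + params$beta_morb * pmax(0, tmax - params$t_morb))
}

#' Climate severity factor (CF)
#'
#' Product of the maximum-temperature amplification table MA evaluated at
#' `tmax` and the hot-day amplification table HDAF evaluated at the current
#' consecutive hot-day count: `CF = MA(tmax) * HDAF(hot_days)`. CF
#' multiplies the death flow only.
#'
#' @param tmax daily maximum temperature, degrees C.
#' @param hot_days consecutive hot-day count (>= 0), see [hot_day_count()].
#' @param ma_table,hdaf_table [table_function()]s for MA and HDAF.
#' @return Dimensionless multiplier (vectorised over `tmax`/`hot_days`).
#' @export
climate_factor <- function(tmax, hot_days, ma_table, hdaf_table) {
  if (any(hot_days < 0)) stop("`hot_days` must be >= 0", call. = FALSE)
  table_eval(ma_table, tmax) * table_eval(hdaf_table, hot_days)
}

#' Heat-attributable death flow
#'
#' Deaths leave the affected-people stock at rate `ap * mu * cf`: a baseline
#' case-fatality fraction `mu` amplified by the climate severity factor.
#' The engine step caps the combined outflows so they never exceed the stock
#' plus the day's inflow.
#'
#' @param ap affected-people stock, persons (>= 0).
#' @param cf climate severity factor (>= 0), see [climate_factor()].
#' @param mu baseline per-day case-fatality fraction.
#' @return Deaths in persons/day.
#' @export
death_flow <- function(ap, cf, mu) {
  if (any(ap < 0) || any(cf < 0) || any(mu < 0)) {
    stop("`ap`, `cf` and `mu` must be non-negative", call. = FALSE)
  }
  ap * mu * cf
}
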