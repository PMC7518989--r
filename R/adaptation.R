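# Adaptation capacity: economic, health-system and governance factors and
# their composition into the daily treated fraction AF.

#' City socioeconomic and health-system profile
#'
#' The indicator set describing a city's capacity to absorb a heat-wave
#' shock: population by age cohort (social system), hospitals, beds and
#' medical staff (health system), air-conditioning usage and personal income
#' (economic system), minimum living allowance and social insurance coverage
#' (governance system).
#'
#' @param pop_under14,pop_15_64,pop_over65 population by age cohort, persons.
#' @param hospitals,beds,staff health-system counts.
#' @param ac_rate air-conditioning usage rate, fraction in \[0, 1\].
#' @param income per-capita personal income, currency/month.
#' @param allowance minimum living allowance, currency/month.
#' @param insurance social insurance coverage, fraction in \[0, 1\].
#' @return A list of class `city_profile`.
#' @export
city_profile <- function(pop_under14, pop_15_64, pop_over65, hospitals, beds,
                         staff, ac_rate, income, allowance, insurance) {
  p <- list(pop_under14 = pop_under14, pop_15_64 = pop_15_64,
            pop_over65 = pop_over65, hospitals = hospitals, beds = beds,
            staff = staff, ac_rate = ac_rate, income = income,
            allowance = allowance, insurance = insurance)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && !is.na(v),
                logical(1))
  if (!all(num)) {
    stop("city profile field `", names(p)[!num][1L],
         "` must be a single number", call. = FALSE)
  }
  if (any(unlist(p) < 0)) stop("city profile fields must be >= 0", call. = FALSE)
  if (ac_rate > 1 || insurance > 1) {
    stop("`ac_rate` and `insurance` are fractions in [0, 1]", call. = FALSE)
  }
  structure(p, class = "city_profile")
}

#' @rdname city_profile
#' @param profile a `city_profile`.
#' @return `total_population()`: the sum of the three age cohorts, persons.
#' @export
total_population <- function(profile) {
  profile$pop_under14 + profile$pop_15_64 + profile$pop_over65
}

#' Adaptation-factor parameters
#'
#' The adaptation factor AF = af0 * EC * HF * GF converts the city profile
#' into the daily treated fraction of the affected stock. Each component
#' factor is a weighted power law (Cobb-Douglas) of indicator/reference
#' ratios, so every factor equals 1 when the profile matches the reference
#' city and `af0` is the calibrated baseline treated fraction of the
#' reference city itself.
#'
#' @param af0 baseline treated fraction per day at the reference profile,
#'   in (0, 1].
#' @param weights named list of exponents in \[0, 1\] for `ac`, `income`,
#'   `staff`, `beds`, `hospitals`, `allowance`, `insurance`; missing entries
#'   default to 0 (indicator ignored).
#' @param reference a [city_profile()] used as the normalisation anchor;
#'   fields used as denominators must be positive.
#' @param af_cap upper cap on AF, fraction/day in (0, 1].
#' @param factor_floor,factor_cap clamps on each component factor; the floor
#'   keeps degenerate profiles (for example zero staff) from shutting
#'   treatment off entirely.
#' @return A list of class `adaptation_params`.
#' @export
adaptation_params <- function(af0, weights = list(), reference,
                              af_cap = 0.95, factor_floor = 1e-3,
                              factor_cap = 10) {
  if (af0 <= 0 || af0 > 1) stop("`af0` must lie in (0, 1]", call. = FALSE)
  if (af_cap <= 0 || af_cap > 1) stop("`af_cap` must lie in (0, 1]", call. = FALSE)
  stopifnot(inherits(reference, "city_profile"))
  known <- c("ac", "income", "staff", "beds", "hospitals", "allowance",
             "insurance")
  bad <- setdiff(names(weights), known)
  if (length(bad)) stop("unknown adaptation weight `", bad[1L], "`", call. = FALSE)
  w <- stats::setNames(as.list(rep(0, length(known))), known)
  w[names(weights)] <- weights
  wv <- unlist(w)
  if (any(wv < 0 | wv > 1)) stop("adaptation weights must lie in [0, 1]", call. = FALSE)
  structure(list(af0 = af0, weights = w, reference = reference,
                 af_cap = af_cap, factor_floor = factor_floor,
                 factor_cap = factor_cap),
            class = "adaptation_params")
}

# weighted power law of indicator/reference ratios with component clamps
power_factor <- function(profile, params, fields, weight_names) {
  val <- 1
  for (i in seq_along(fields)) {
    w <- params$weights[[weight_names[i]]]
    if (w == 0) next
    ref <- params$reference[[fields[i]]]
    if (ref <= 0) {
      stop("reference profile field `", fields[i],
           "` must be positive when weighted", call. = FALSE)
    }
    ratio <- max(profile[[fields[i]]] / ref, params$factor_floor)
    val <- val * ratio^w
  }
  min(max(val, params$factor_floor), params$factor_cap)
}

#' Adaptation component factors
#'
#' `economic_factor()` combines air-conditioning usage and income;
#' `health_factor()` combines medical staff, hospital beds and hospitals;
#' `governance_factor()` combines the minimum living allowance and insurance
#' coverage. Each is a weighted power law of indicator/reference ratios,
#' equal to 1 at the reference profile and increasing in every indicator
#' with positive weight.
#'
#' @param profile a [city_profile()].
#' @param params an [adaptation_params()].
#' @return A dimensionless factor, clamped to
#'   `[factor_floor, factor_cap]`.
#' @export
economic_factor <- function(profile, params) {
  power_factor(profile, params, c("ac_rate", "income"), c("ac", "income"))
}

#' @rdname economic_factor
#' @export
health_factor <- function(profile, params) {
  power_factor(profile, params, c("staff", "beds", "hospitals"),
               c("staff", "beds", "hospitals"))
}

#' @rdname economic_factor
#' @export
governance_factor <- function(profile, params) {
  power_factor(profile, params, c("allowance", "insurance"),
               c("allowance", "insurance"))
}

#' Compose the adaptation factor AF
#'
#' `AF = min(af_cap, af0 * EC * HF * GF)`, the daily treated fraction of the
#' affected stock. The component clamps guarantee AF stays in (0, 1] for
#' every admissible profile.
#'
#' @param ec,hf,gf component factors, see [economic_factor()].
#' @param params an [adaptation_params()].
#' @return Treated fraction per day in (0, 1].
#' @export
adaptation_factor <- function(ec, hf, gf, params) {
  if (any(c(ec, hf, gf) < 0)) stop("factors must be >= 0", call. = FALSE)
  min(params$af_cap, params$af0 * ec * hf * gf)
}

#' Treated-people outflow (TPF)
#'
#' `TPF = AP * AF`: the number of affected people treated (and removed from
#' the stock) per day.
#'
#' @param ap affected-people stock, persons (>= 0).
#' @param af adaptation factor, fraction/day in \[0, 1\].
#' @return Outflow in persons/day.
#' @export
treated_flow <- function(ap, af) {
  if (any(ap < 0)) stop("`ap` must be >= 0", call. = FALSE)
  if (any(af < 0 | af > 1)) stop("`af` must lie in [0, 1]", call. = FALSE)
  ap * af
}
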