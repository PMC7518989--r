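# Full model parameter set: exposure response, adaptation, table functions,
# background mortality and the initial stock.

#' Assemble the full model parameter set
#'
#' Bundles everything [simulate_episode()] needs besides the climate series
#' and the city profile: the exposure-response parameters, the adaptation
#' parameters, the MA and HDAF table functions, the background (non-heat)
#' mortality rate and the initial affected stock.
#'
#' @param exposure an [exposure_params()].
#' @param adaptation an [adaptation_params()].
#' @param ma maximum-temperature amplification [table_function()] (MA); by
#'   convention equal to 1 below the mortality threshold.
#' @param hdaf hot-day amplification [table_function()] (HDAF) over the
#'   consecutive hot-day count.
#' @param background_rate background daily deaths per ten million population
#'   on cool days; added to the heat-attributable flow so reported
#'   trajectories are total daily deaths.
#' @param initial_ap initial affected-people stock, persons (>= 0); a user
#'   input of the model.
#' @return A list of class `model_params`.
#' @export
model_params <- function(exposure, adaptation, ma, hdaf,
                         background_rate = 114, initial_ap = 0) {
  stopifnot(inherits(exposure, "exposure_params"),
            inherits(adaptation, "adaptation_params"),
            inherits(ma, "table_function"),
            inherits(hdaf, "table_function"))
  if (background_rate < 0) stop("`background_rate` must be >= 0", call. = FALSE)
  if (initial_ap < 0) stop("`initial_ap` must be >= 0", call. = FALSE)
  structure(list(exposure = exposure, adaptation = adaptation, ma = ma,
                 hdaf = hdaf, background_rate = background_rate,
                 initial_ap = initial_ap),
            class = "model_params")
}

# exposed population: total population with a vulnerability loading on the
# over-65 share (age structure enters exposure, not adaptation)
exposed_population <- function(profile, exposure) {
  tot <- total_population(profile)
  share65 <- if (tot > 0) profile$pop_over65 / tot else 0
  tot * (1 + exposure$vuln_over65 * share65)
}

# background daily deaths for a profile, persons/day
background_deaths <- function(profile, params) {
  total_population(profile) / 1e7 * params$background_rate
}

# short stable fingerprint of a parameter set (position-weighted checksum of
# its serialisation)
params_fingerprint <- function(params) {
  bytes <- as.numeric(serialize(params, NULL, version = 2))
  w <- (seq_along(bytes) %% 251) + 1
  sprintf("%08x", as.integer(sum(bytes * w) %% 2^31))
}

#' @export
print.model_params <- function(x, ...) {
  cat("heat-wave SD model parameters [", params_fingerprint(x), "]\n", sep = "")
  e <- x$exposure
  cat(sprintf("  exposure: t_morb=%.1f t_mort=%.1f beta_morb=%.4g r_base=%.4g mu=%.4g\n",
              e$t_morb, e$t_mort, e$beta_morb, e$r_base, e$mu))
  cat(sprintf("  adaptation: af0=%.4g af_cap=%.2f\n",
              x$adaptation$af0, x$adaptation$af_cap))
  cat(sprintf("  tables: MA %d breakpoints, HDAF %d breakpoints\n",
              length(x$ma$x), length(x$hdaf$x)))
  cat(sprintf("  background_rate=%.4g per 1e7/day, initial_ap=%.6g persons\n",
              x$background_rate, x$initial_ap))
  invisible(x)
}
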