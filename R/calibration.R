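# Least-squares calibration of the free model parameters against an
# observed daily death series, and peak-based validation.

# update one named free parameter inside a model_params object; names:
#   beta_morb, r_base, mu, vuln_over65          (exposure)
#   af0, af_cap, w_ac, w_income, w_staff, w_beds, w_hospitals,
#   w_allowance, w_insurance                    (adaptation)
#   ma_y<i>, hdaf_y<i>                          (table breakpoint heights)
#   initial_ap, background_rate
set_free_param <- function(params, name, value) {
  if (name %in% c("beta_morb", "r_base", "mu", "vuln_over65")) {
    params$exposure[[name]] <- value
  } else if (name %in% c("af0", "af_cap")) {
    params$adaptation[[name]] <- value
  } else if (grepl("^w_", name)) {
    key <- sub("^w_", "", name)
    if (!key %in% names(params$adaptation$weights)) {
      stop("unknown adaptation weight `", name, "`", call. = FALSE)
    }
    params$adaptation$weights[[key]] <- value
  } else if (grepl("^ma_y[0-9]+$", name)) {
    i <- as.integer(sub("^ma_y", "", name))
    if (i < 1L || i > length(params$ma$y)) {
      stop("MA breakpoint index out of range in `", name, "`", call. = FALSE)
    }
    params$ma$y[i] <- value
  } else if (grepl("^hdaf_y[0-9]+$", name)) {
    i <- as.integer(sub("^hdaf_y", "", name))
    if (i < 1L || i > length(params$hdaf$y)) {
      stop("HDAF breakpoint index out of range in `", name, "`", call. = FALSE)
    }
    params$hdaf$y[i] <- value
  } else if (name %in% c("initial_ap", "background_rate")) {
    params[[name]] <- value
  } else {
    stop("unknown free parameter `", name, "`", call. = FALSE)
  }
  params
}

set_free_params <- function(params, values) {
  for (nm in names(values)) params <- set_free_param(params, nm, values[[nm]])
  params
}

#' Specify a calibration problem
#'
#' Declares which parameters are free (with finite box bounds), the
#' objective and the optimizer settings. Optimisation is bounded
#' Nelder-Mead with multi-start: parameters are mapped to the unconstrained
#' scale through a logistic transform of their bounds, and `restarts`
#' initial points (the box midpoint plus seeded uniform draws) are each
#' polished by Nelder-Mead. The objective is cheap and non-smooth (table
#' clamps, outflow caps), so a derivative-free method is used.
#'
#' @param free named list; each element `c(lower, upper)` with
#'   `lower < upper`, both finite. Names follow the vocabulary of the free
#'   parameters: `beta_morb`, `r_base`, `mu`, `af0`, `w_beds`, `ma_y3`,
#'   `hdaf_y2`, `initial_ap`, ... See [calibrate_model()].
#' @param objective `"sse"` (sum of squared errors) or `"rmse"`.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param restarts number of starts (>= 1).
#' @param seed integer seed for the random starts.
#' @return A list of class `calibration_spec`.
#' @export
calibration_spec <- function(free = list(), objective = c("sse", "rmse"),
                             maxit = 500, restarts = 8, seed = 1) {
  objective <- match.arg(objective)
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] >= b[2L]) {
      stop("bounds for `", nm, "` must be finite with lower < upper",
           call. = FALSE)
    }
  }
  if (restarts < 1L) stop("`restarts` must be >= 1", call. = FALSE)
  structure(list(free = free, objective = objective, maxit = maxit,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "calibration_spec")
}

#' Calibrate free parameters against an observed death series
#'
#' Minimises the squared error between simulated total daily deaths
#' (baseline scenario) and an observed daily death series over the free
#' parameters declared in `spec`, within their bounds. Deterministic given
#' `spec$seed`.
#'
#' @param observed data frame with columns `date`, `deaths`, aligned
#'   day-for-day with `series`.
#' @param series the driving [temperature_series()].
#' @param profile the [city_profile()].
#' @param spec a [calibration_spec()].
#' @param params a [model_params()] supplying every fixed parameter and the
#'   starting structure of the free ones.
#' @return A list of class `calibration_result` with elements `fitted`
#'   (named numeric), `objective`, `residuals` (simulated - observed),
#'   `converged`, `n_evaluations`, `start_objectives` (objective at each
#'   initial point) and `params` (the updated full parameter set).
#' @export
calibrate_model <- function(observed, series, profile, spec, params) {
  series <- as_temperature_series(series)
  stopifnot(inherits(spec, "calibration_spec"), inherits(params, "model_params"))
  if (!all(c("date", "deaths") %in% names(observed))) {
    stop("`observed` needs columns `date` and `deaths`", call. = FALSE)
  }
  if (nrow(observed) != nrow(series) ||
      !all(as.Date(observed$date) == series$date)) {
    stop("observed deaths and climate series are not aligned on dates",
         call. = FALSE)
  }
  obs <- as.numeric(observed$deaths)
  n_eval <- 0L
  run_sim <- function(p) simulate_episode(series, profile, p)$data$total_deaths
  loss <- function(sim) {
    sse <- sum((sim - obs)^2)
    if (spec$objective == "rmse") sqrt(sse / length(obs)) else sse
  }

  nm <- names(spec$free)
  if (length(nm) == 0L) {
    sim <- run_sim(params)
    return(structure(list(fitted = stats::setNames(numeric(0), character(0)),
                          objective = loss(sim), residuals = sim - obs,
                          converged = TRUE, n_evaluations = 1L,
                          start_objectives = loss(sim), params = params),
                     class = "calibration_result"))
  }
  lo <- vapply(spec$free, `[`, numeric(1), 1L)
  hi <- vapply(spec$free, `[`, numeric(1), 2L)
  to_theta <- function(z) lo + (hi - lo) * stats::plogis(z)
  to_z <- function(theta) {
    u <- pmin(pmax((theta - lo) / (hi - lo), 1e-6), 1 - 1e-6)
    stats::qlogis(u)
  }
  fn <- function(z) {
    n_eval <<- n_eval + 1L
    theta <- stats::setNames(to_theta(z), nm)
    loss(run_sim(set_free_params(params, as.list(theta))))
  }
  starts <- with_local_seed(spec$seed, {
    s <- list((lo + hi) / 2)
    if (spec$restarts > 1L) {
      for (k in seq_len(spec$restarts - 1L)) {
        s[[k + 1L]] <- lo + (hi - lo) * stats::runif(length(lo))
      }
    }
    s
  })
  best <- NULL
  start_obj <- numeric(length(starts))
  for (k in seq_along(starts)) {
    z0 <- to_z(starts[[k]])
    start_obj[k] <- fn(z0)
    fit <- if (length(nm) == 1L) {
      # Brent is the reliable choice in one dimension
      stats::optim(z0, fn, method = "Brent", lower = -16, upper = 16,
                   control = list(maxit = spec$maxit))
    } else {
      stats::optim(z0, fn, method = "Nelder-Mead",
                   control = list(maxit = spec$maxit, reltol = 1e-10))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  fitted <- stats::setNames(to_theta(best$par), nm)
  final_params <- set_free_params(params, as.list(fitted))
  sim <- run_sim(final_params)
  structure(list(fitted = fitted, objective = best$value,
                 residuals = sim - obs,
                 converged = best$convergence == 0L,
                 n_evaluations = n_eval, start_objectives = start_obj,
                 params = final_params),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: objective %.6g (%s), %d evaluations\n",
              x$objective, if (x$converged) "converged" else "not converged",
              x$n_evaluations))
  if (length(x$fitted)) print(round(x$fitted, 6))
  invisible(x)
}

#' Validate a simulated trajectory against observations
#'
#' Reports the root-mean-square error, the relative peak-value error
#' `|max(sim) - max(obs)| / max(obs)` and the peak lag
#' `argmax(sim) - argmax(obs)` in days (ties broken by the earliest day) --
#' the criteria used to judge whether the model reproduces the peaking
#' process of the daily death toll.
#'
#' @param observed data frame with columns `date`, `deaths`.
#' @param simulated a [simulate_episode()] result, or a numeric vector of
#'   simulated total daily deaths of the same length.
#' @return A list of class `validation_report` with `rmse`,
#'   `peak_value_error` and `peak_lag_days`.
#' @export
validate_fit <- function(observed, simulated) {
  sim <- if (inherits(simulated, "simulation_result")) {
    simulated$data$total_deaths
  } else {
    as.numeric(simulated)
  }
  obs <- as.numeric(observed$deaths)
  if (length(obs) == 0L) stop("`observed` is empty", call. = FALSE)
  if (length(sim) != length(obs)) {
    stop("observed and simulated series have different lengths", call. = FALSE)
  }
  structure(list(rmse = sqrt(mean((sim - obs)^2)),
                 peak_value_error = abs(max(sim) - max(obs)) / max(obs),
                 peak_lag_days = which.max(sim) - which.max(obs)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("RMSE %.3f; relative peak-value error %.3f; peak lag %+d day(s)\n",
              x$rmse, x$peak_value_error, x$peak_lag_days))
  invisible(x)
}
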