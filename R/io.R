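# File formats: climate and death-series CSV, city-profile YAML, parameter
# YAML, trajectory output and the end-to-end pipeline.

#' Read and write daily climate CSV
#'
#' Dialect: header `date,tmax,tmean,tmin,humidity`, ISO-8601 dates, UTF-8,
#' empty cells for missing optional fields. The reader rejects malformed
#' rows, duplicate dates and date gaps with an error naming the offending
#' line (line 1 is the header).
#'
#' @param path file path.
#' @return `read_climate_csv()`: a [temperature_series()].
#' @export
read_climate_csv <- function(path) {
  if (!file.exists(path)) stop("climate file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "tmax") %in% names(df))) {
    stop("climate CSV must have at least `date` and `tmax` columns",
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("climate CSV has no data rows", call. = FALSE)
  line <- function(i) i + 1L  # header offset
  dates <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date at line ", line(which(is.na(dates))[1L]),
         " of ", path, call. = FALSE)
  }
  tmax <- suppressWarnings(as.numeric(df$tmax))
  if (anyNA(tmax)) {
    stop("missing or non-numeric tmax at line ",
         line(which(is.na(tmax))[1L]), " of ", path, call. = FALSE)
  }
  if (nrow(df) > 1L) {
    d <- as.integer(diff(dates))
    if (any(d == 0L)) {
      stop("duplicate date at line ", line(which(d == 0L)[1L] + 1L),
           " of ", path, call. = FALSE)
    }
    if (any(d != 1L)) {
      stop("date gap or disorder before line ",
           line(which(d != 1L)[1L] + 1L), " of ", path, call. = FALSE)
    }
  }
  opt <- function(nm) {
    if (!nm %in% names(df)) return(NULL)
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (all(is.na(v))) NULL else v
  }
  temperature_series(dates, tmax, tmean = opt("tmean"), tmin = opt("tmin"),
                     humidity = opt("humidity"))
}

#' @rdname read_climate_csv
#' @param series a [temperature_series()].
#' @export
write_climate_csv <- function(series, path) {
  series <- as_temperature_series(series)
  out <- data.frame(date = format(series$date, "%Y-%m-%d"))
  for (nm in c("tmax", "tmean", "tmin", "humidity")) {
    out[[nm]] <- if (nm %in% names(series)) series[[nm]] else NA_real_
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write daily death-count CSV
#'
#' Header `date,deaths`, ISO-8601 dates, non-negative integer counts.
#'
#' @param path file path.
#' @return `read_deaths_csv()`: a data frame with `date`, `deaths`.
#' @export
read_deaths_csv <- function(path) {
  if (!file.exists(path)) stop("deaths file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "deaths") %in% names(df))) {
    stop("deaths CSV must have `date` and `deaths` columns", call. = FALSE)
  }
  dates <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  deaths <- suppressWarnings(as.numeric(df$deaths))
  bad <- is.na(dates) | is.na(deaths) | deaths < 0
  if (any(bad)) {
    stop("malformed row at line ", which(bad)[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  data.frame(date = dates, deaths = as.integer(round(deaths)))
}

#' @rdname read_deaths_csv
#' @param deaths data frame with columns `date`, `deaths`.
#' @export
write_deaths_csv <- function(deaths, path) {
  out <- data.frame(date = format(as.Date(deaths$date), "%Y-%m-%d"),
                    deaths = as.integer(deaths$deaths))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a city profile YAML
#'
#' The profile lives under a top-level `city:` key (a bare mapping of the
#' fields is also accepted).
#'
#' @param path file path.
#' @return `read_city_yaml()`: a [city_profile()].
#' @export
read_city_yaml <- function(path) {
  if (!file.exists(path)) stop("city file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.null(y$city)) y <- y$city
  need <- c("pop_under14", "pop_15_64", "pop_over65", "hospitals", "beds",
            "staff", "ac_rate", "income", "allowance", "insurance")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("city profile is missing field `", miss[1L], "`", call. = FALSE)
  }
  do.call(city_profile, y[need])
}

#' @rdname read_city_yaml
#' @param profile a [city_profile()].
#' @export
write_city_yaml <- function(profile, path) {
  stopifnot(inherits(profile, "city_profile"))
  yaml::write_yaml(list(city = unclass(profile)), path, precision = 15L)
  invisible(path)
}

table_from_pairs <- function(pairs, what) {
  m <- tryCatch(do.call(rbind, lapply(pairs, as.numeric)),
                error = function(e) NULL)
  if (is.null(m) || ncol(m) != 2L) {
    stop("table `", what, "` must be a list of [x, y] pairs", call. = FALSE)
  }
  table_function(m[, 1L], m[, 2L])
}

table_to_pairs <- function(tf) {
  lapply(seq_along(tf$x), function(i) c(tf$x[i], tf$y[i]))
}

#' Read and write the full parameter YAML
#'
#' The file carries an `exposure:` block, an `adaptation:` block (including
#' `weights:` and the normalisation `reference:` profile), a `tables:`
#' block with `MA` and `HDAF` as lists of `[x, y]` pairs, plus
#' `background_rate` and `initial_ap`. Every declared invariant is checked
#' on read, with the error naming the offending field; missing tables fall
#' back to neutral (constant 1) tables with a warning; missing optional
#' scalars take their documented defaults.
#'
#' @param path file path.
#' @return `read_params_yaml()`: a [model_params()].
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) stop("params file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  e <- y$exposure %||% list()
  exposure <- exposure_params(
    t_morb = e$t_morb %||% 36.6, t_mort = e$t_mort %||% 37.6,
    beta_morb = e$beta_morb %||% 0, r_base = e$r_base %||% 0,
    mu = e$mu %||% 0, vuln_over65 = e$vuln_over65 %||% 1,
    cf_on_apf = e$cf_on_apf %||% FALSE)
  a <- y$adaptation %||% list()
  if (is.null(a$reference)) {
    stop("params file lacks `adaptation.reference` (normalisation profile)",
         call. = FALSE)
  }
  reference <- do.call(city_profile, a$reference)
  adaptation <- adaptation_params(
    af0 = a$af0 %||% 0.5, weights = a$weights %||% list(),
    reference = reference, af_cap = a$af_cap %||% 0.95,
    factor_floor = a$factor_floor %||% 1e-3,
    factor_cap = a$factor_cap %||% 10)
  tb <- y$tables %||% list()
  if (is.null(tb$MA)) {
    warning("params file lacks tables.MA; using neutral MA = 1", call. = FALSE)
    ma <- table_function(c(35, 45), c(1, 1))
  } else {
    ma <- table_from_pairs(tb$MA, "MA")
  }
  if (is.null(tb$HDAF)) {
    warning("params file lacks tables.HDAF; using neutral HDAF = 1",
            call. = FALSE)
    hdaf <- table_function(c(0, 30), c(1, 1))
  } else {
    hdaf <- table_from_pairs(tb$HDAF, "HDAF")
  }
  model_params(exposure, adaptation, ma, hdaf,
               background_rate = y$background_rate %||% 114,
               initial_ap = y$initial_ap %||% 0)
}

#' @rdname read_params_yaml
#' @param params a [model_params()].
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  y <- list(
    exposure = unclass(params$exposure),
    adaptation = list(af0 = params$adaptation$af0,
                      af_cap = params$adaptation$af_cap,
                      factor_floor = params$adaptation$factor_floor,
                      factor_cap = params$adaptation$factor_cap,
                      weights = params$adaptation$weights,
                      reference = unclass(params$adaptation$reference)),
    tables = list(MA = table_to_pairs(params$ma),
                  HDAF = table_to_pairs(params$hdaf)),
    background_rate = params$background_rate,
    initial_ap = params$initial_ap)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' Write a simulated trajectory CSV
#'
#' Columns `day,tmax,hot_days,apf,tpf,deaths,ap,total_deaths`; the first
#' line is a `#` comment carrying the scenario kind and the parameter
#' fingerprint.
#'
#' @param result a [simulate_episode()] result.
#' @param path file path.
#' @export
write_simulation_csv <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# heatsd trajectory; scenario=%s; params=%s",
                     result$scenario$kind, result$fingerprint), con)
  cols <- c("day", "tmax", "hot_days", "apf", "tpf", "deaths", "ap",
            "total_deaths")
  utils::write.csv(result$data[cols], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline: inputs -> baseline + scenario -> comparison
#'
#' Fail-fast driver used by the command-line interface: resolves and
#' validates every input before simulating, runs the baseline and the
#' requested scenario, compares them, and writes `baseline.csv`,
#' `scenario.csv`, `compare.csv` and `report.json` into `out_dir`. Outputs
#' are written atomically (tempfile then rename): on any failure no partial
#' artifact is left behind. Identical config and seed give identical
#' outputs.
#'
#' @param climate path to a climate CSV, a [temperature_series()], or a
#'   [fixture_spec()] to synthesise one.
#' @param city path to a city YAML or a [city_profile()].
#' @param params path to a parameter YAML or a [model_params()].
#' @param scn the [scenario()] to compare against baseline.
#' @param out_dir output directory (created if needed).
#' @param initial_ap optional override of `params$initial_ap`.
#' @return Invisibly, a list with the four output paths and the comparison
#'   table.
#' @export
run_pipeline <- function(climate, city, params, scn = scenario("bed_readiness"),
                         out_dir, initial_ap = NULL) {
  fail <- function(stage, e) {
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  }
  series <- tryCatch({
    if (inherits(climate, "fixture_spec")) gen_heatwave_series(climate)
    else if (is.character(climate)) read_climate_csv(climate)
    else as_temperature_series(climate)
  }, error = function(e) fail("climate", e))
  profile <- tryCatch({
    if (is.character(city)) read_city_yaml(city) else city
  }, error = function(e) fail("city", e))
  pars <- tryCatch({
    if (is.character(params)) read_params_yaml(params) else params
  }, error = function(e) fail("params", e))
  stopifnot(inherits(profile, "city_profile"), inherits(pars, "model_params"))
  if (!is.null(initial_ap)) pars$initial_ap <- initial_ap

  base <- tryCatch(simulate_episode(series, profile, pars),
                   error = function(e) fail("simulate-baseline", e))
  alt <- tryCatch(simulate_episode(series, profile, pars, scn),
                  error = function(e) fail("simulate-scenario", e))
  cmp <- tryCatch(compare_scenarios(base, alt),
                  error = function(e) fail("compare", e))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("baseline.csv", "scenario.csv", "compare.csv",
                                "report.json"))
  names(paths) <- c("baseline", "scenario", "compare", "report")
  tmp <- paste0(paths, ".tmp")
  on.exit(unlink(tmp[file.exists(tmp)]), add = TRUE)
  tryCatch({
    write_simulation_csv(base, tmp[1L])
    write_simulation_csv(alt, tmp[2L])
    utils::write.csv(cmp, tmp[3L], row.names = FALSE, quote = FALSE, na = "")
    peak <- attr(cmp, "peak_days")
    in_epi <- !is.na(cmp$episode_day)
    report <- list(
      scenario = unclass(scn),
      params_fingerprint = base$fingerprint,
      n_days = nrow(cmp),
      episode_days = sum(in_epi),
      cumulative_reduction = sum(cmp$reduction),
      peak_reduction_days = as.integer(peak),
      peak_pct_reduction = cmp$pct_reduction[in_epi][
        match(peak, cmp$episode_day[in_epi])])
    jsonlite::write_json(report, tmp[4L], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    for (i in seq_along(paths)) file.rename(tmp[i], paths[i])
  }, error = function(e) fail("write-outputs", e))
  invisible(list(paths = as.list(paths), compare = cmp))
}
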