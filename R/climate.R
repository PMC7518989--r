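# Daily climate series, CMA heat-wave episode detection, hot-day counter and
# piecewise-linear table functions.

#' Construct a daily temperature series
#'
#' A `temperature_series` is a data frame of consecutive daily climate
#' records, the driver of the stock-flow model. Dates must be strictly
#' increasing with no gaps; `tmean`, `tmin` and `humidity` are optional.
#'
#' @param date `Date` vector (or ISO-8601 strings), one entry per day.
#' @param tmax daily maximum temperature, degrees Celsius.
#' @param tmean,tmin optional daily mean/minimum temperature, degrees Celsius.
#' @param humidity optional daily relative humidity, percent, in \[0, 100\].
#' @return A data frame of class `temperature_series` with columns
#'   `date`, `tmax` and any optional columns supplied.
#' @examples
#' ts <- temperature_series(as.Date("2013-07-01") + 0:4, tmax = c(36, 37, 38, 37, 36))
#' detect_heatwaves(ts)
#' @export
temperature_series <- function(date, tmax, tmean = NULL, tmin = NULL,
                               humidity = NULL) {
  date <- as.Date(date)
  n <- length(date)
  if (n == 0L) stop("temperature series must be non-empty", call. = FALSE)
  if (anyNA(date)) stop("temperature series contains unparseable dates", call. = FALSE)
  if (length(tmax) != n) stop("`tmax` must match `date` in length", call. = FALSE)
  if (anyNA(tmax)) stop("`tmax` must not contain missing values", call. = FALSE)
  if (n > 1L) {
    d <- as.integer(diff(date))
    if (any(d <= 0L)) stop("dates must be strictly increasing", call. = FALSE)
    if (any(d != 1L)) {
      stop("dates must be consecutive; gap after ",
           format(date[which(d != 1L)[1L]]), call. = FALSE)
    }
  }
  out <- data.frame(date = date, tmax = as.numeric(tmax))
  for (nm in c("tmean", "tmin", "humidity")) {
    v <- switch(nm, tmean = tmean, tmin = tmin, humidity = humidity)
    if (!is.null(v)) {
      if (length(v) != n) stop("`", nm, "` must match `date` in length", call. = FALSE)
      out[[nm]] <- as.numeric(v)
    }
  }
  ok <- rep(TRUE, n)
  if (!is.null(out$tmean) && !is.null(out$tmin)) {
    ok <- is.na(out$tmin) | is.na(out$tmean) |
      (out$tmin <= out$tmean & out$tmean <= out$tmax)
  } else if (!is.null(out$tmean)) {
    ok <- is.na(out$tmean) | out$tmean <= out$tmax
  }
  if (!all(ok)) {
    stop("tmin <= tmean <= tmax violated on ", format(out$date[!ok][1L]),
         call. = FALSE)
  }
  if (!is.null(out$humidity)) {
    h <- out$humidity[!is.na(out$humidity)]
    if (any(h < 0 | h > 100)) stop("humidity must lie in [0, 100]", call. = FALSE)
  }
  class(out) <- c("temperature_series", "data.frame")
  out
}

as_temperature_series <- function(x) {
  if (inherits(x, "temperature_series")) return(x)
  temperature_series(x$date, x$tmax, tmean = x$tmean, tmin = x$tmin,
                     humidity = x$humidity)
}

# run length of consecutive hot days ending at each day (the hot-day counter
# for the HDAF table); vectorised over the whole series
hot_day_runs <- function(tmax, hot_threshold = 35) {
  hot <- tmax > hot_threshold
  out <- integer(length(hot))
  run <- 0L
  for (i in seq_along(hot)) {
    run <- if (hot[i]) run + 1L else 0L
    out[i] <- run
  }
  out
}

#' Hot-day counter
#'
#' Number of consecutive days with `tmax` above the hot threshold ending at
#' (and including) `day`; 0 when `day` itself is not hot. This is the
#' duration input of the hot-day amplification table (HDAF): a single cool
#' day resets the counter.
#'
#' @param series a [temperature_series()].
#' @param day 1-based day index into the series.
#' @param hot_threshold hot-day threshold, degrees Celsius (strict `>`).
#' @return Integer count of consecutive hot days ending at `day`.
#' @export
hot_day_count <- function(series, day, hot_threshold = 35) {
  series <- as_temperature_series(series)
  n <- nrow(series)
  if (length(day) != 1L || is.na(day) || day < 1L || day > n) {
    stop("`day` must be a single index in 1..", n, call. = FALSE)
  }
  hot_day_runs(series$tmax, hot_threshold)[as.integer(day)]
}

longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Detect heat-wave episodes under the CMA consecutive-day rules
#'
#' An episode is a maximal run of consecutive days with daily maximum
#' temperature strictly above `hot_threshold`. Following the China
#' Meteorological Administration definition, a run qualifies as a *strong*
#' heat wave when it lasts at least 5 days, or contains at least 2
#' consecutive days above `severe_threshold`; it qualifies as *extreme* at
#' 8 days, or 3 consecutive days above `severe_threshold`. Runs meeting
#' neither rule are dropped; a run meeting both a strong and an extreme rule
#' is labelled extreme.
#'
#' @inheritParams hot_day_count
#' @param severe_threshold severe-day threshold, degrees Celsius (default 38).
#' @return A data frame with one row per episode and columns `start`, `end`
#'   (1-based inclusive day indices), `duration` (days) and `severity`
#'   (`"strong"` or `"extreme"`), ordered by `start`.
#' @export
detect_heatwaves <- function(series, hot_threshold = 35, severe_threshold = 38) {
  series <- as_temperature_series(series)
  if (hot_threshold <= 0 || severe_threshold <= hot_threshold) {
    stop("need 0 < hot_threshold < severe_threshold", call. = FALSE)
  }
  tmax <- series$tmax
  hot <- tmax > hot_threshold
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = integer(), end = integer(), duration = integer(),
                    severity = character(), stringsAsFactors = FALSE)
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    dur <- e - s + 1L
    sev_run <- longest_true_run(tmax[s:e] > severe_threshold)
    severity <- if (dur >= 8L || sev_run >= 3L) "extreme"
                else if (dur >= 5L || sev_run >= 2L) "strong"
                else NA_character_
    if (!is.na(severity)) {
      out <- rbind(out, data.frame(start = s, end = e, duration = dur,
                                   severity = severity,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Shift a temperature series by a constant offset
#'
#' Adds `delta` degrees to `tmax` (and to `tmean`/`tmin` when present),
#' leaving dates and humidity unchanged. Used by the marginal-temperature
#' scenarios, which add 1 or 2 degrees to every day of the baseline series.
#'
#' @inheritParams hot_day_count
#' @param delta temperature offset, degrees Celsius (may be negative).
#' @return A new `temperature_series`.
#' @export
apply_offset <- function(series, delta) {
  series <- as_temperature_series(series)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  out <- series
  for (nm in intersect(c("tmax", "tmean", "tmin"), names(out))) {
    out[[nm]] <- out[[nm]] + delta
  }
  out
}

#' Piecewise-linear table function
#'
#' Table functions encode empirical input-output relations (the
#' maximum-temperature amplification MA and the hot-day amplification HDAF)
#' as ordered breakpoints with linear interpolation in between and constant
#' (clamped) extrapolation outside the breakpoint range.
#'
#' @param x breakpoint abscissae, strictly increasing, length >= 2.
#' @param y breakpoint ordinates, same length as `x`.
#' @return An object of class `table_function`.
#' @examples
#' ma <- table_function(c(35, 40), c(1, 2))
#' table_eval(ma, c(35, 37.5, 50))  # 1.0 1.5 2.0
#' @export
table_function <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L) stop("a table function needs at least 2 breakpoints", call. = FALSE)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("table breakpoints must be finite", call. = FALSE)
  if (any(diff(x) <= 0)) stop("table abscissae must be strictly increasing", call. = FALSE)
  structure(list(x = x, y = y), class = "table_function")
}

#' @rdname table_function
#' @param tf a `table_function`.
#' @param at numeric vector of evaluation points.
#' @export
table_eval <- function(tf, at) {
  if (!inherits(tf, "table_function")) tf <- table_function(tf$x, tf$y)
  stats::approx(tf$x, tf$y, xout = at, method = "linear", rule = 2,
                ties = "ordered")$y
}

#' @export
print.table_function <- function(x, ...) {
  cat("table function with", length(x$x), "breakpoints\n")
  print(data.frame(x = x$x, y = x$y), row.names = FALSE)
  invisible(x)
}
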