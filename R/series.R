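#' Melanopic irradiance series
#'
#' A `mel_series` is a tibble with columns `time_s` (seconds since the start
#' of `start_date`, uniform grid) and `E_mel` (melanopic irradiance,
#' W m^-2, non-negative), carrying attributes `start_date` (Date) and `dt_s`
#' (grid step, seconds). The grid must cover an integer number of whole days.
#'
#' @param time_s Uniform, strictly increasing grid of seconds from midnight
#'   of `start_date`; the implicit final sample closes the last day.
#' @param E_mel Melanopic irradiance values, W m^-2.
#' @param start_date Calendar date of the first sample.
#' @param tz_offset Fixed local UTC offset in hours (metadata only).
#' @return A `mel_series` tibble.
#' @export
mel_series <- function(time_s, E_mel, start_date = as.Date("2023-01-01"),
                       tz_offset = 0) {
  if (length(time_s) != length(E_mel) || length(time_s) < 2) {
    stop("`time_s` and `E_mel` must have equal length >= 2", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6) {
    stop("`time_s` must be a strictly increasing uniform grid", call. = FALSE)
  }
  check_nonneg(E_mel, "E_mel")
  dt_s <- dt[[1L]]
  span <- time_s[length(time_s)] - time_s[1L] + dt_s
  if (abs(span %% 86400) > 1e-6 && abs(span %% 86400 - 86400) > 1e-6) {
    stop("series must cover an integer number of whole days", call. = FALSE)
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), E_mel = as.numeric(E_mel))
  structure(out,
    class = c("mel_series", class(out)),
    start_date = as.Date(start_date), dt_s = dt_s, tz_offset = tz_offset
  )
}

#' @export
print.mel_series <- function(x, ...) {
  cat(sprintf(
    "<mel_series> %d samples @ %gs, %g day(s) from %s\n",
    nrow(x), attr(x, "dt_s"), n_days(x), format(attr(x, "start_date"))
  ))
  NextMethod()
}

n_days <- function(series) {
  dt <- attr(series, "dt_s")
  round((series$time_s[nrow(series)] - series$time_s[1L] + dt) / 86400)
}

#' Clock hour and date helpers for model time
#'
#' Model time is seconds since midnight of the series start date.
#'
#' @param time_s Seconds since simulation start.
#' @param start_date Start date (`Date`).
#' @return `clock_hour()`: hour-of-day in \[0, 24); `date_of()`: `Date`.
#' @export
clock_hour <- function(time_s) (time_s / 3600) %% 24

#' @rdname clock_hour
#' @export
date_of <- function(time_s, start_date) {
  as.Date(start_date) + floor(time_s / 86400)
}

#' Resample irregular samples onto a uniform melanopic-irradiance grid
#'
#' Linear interpolation of time-stamped samples onto a uniform grid covering
#' whole days; times outside the sampled range are zero (no extrapolation of
#' light).
#'
#' @param time_s Sample times, seconds since midnight of `start_date`,
#'   sorted non-decreasing.
#' @param values Melanopic irradiance at the sample times, W m^-2.
#' @param dt Output grid step, seconds.
#' @param days Number of whole days to cover; default spans the samples.
#' @inheritParams mel_series
#' @return A [mel_series()].
#' @export
resample_series <- function(time_s, values, dt = 60,
                            days = NULL, start_date = as.Date("2023-01-01"),
                            tz_offset = 0) {
  if (length(time_s) == 0L) stop("empty input", call. = FALSE)
  if (is.unsorted(time_s)) stop("sample times must be sorted", call. = FALSE)
  check_nonneg(values, "values")
  dup <- duplicated(time_s)
  if (any(dup)) {
    for (t in unique(time_s[dup])) {
      if (length(unique(values[time_s == t])) > 1L) {
        stop("duplicate timestamps with differing values", call. = FALSE)
      }
    }
    values <- values[!dup]
    time_s <- time_s[!dup]
  }
  if (is.null(days)) days <- max(1, ceiling(max(time_s) / 86400))
  grid <- seq(0, days * 86400 - dt, by = dt)
  if (length(time_s) == 1L) {
    v <- ifelse(abs(grid - time_s) < dt / 2, values, 0)
  } else {
    v <- stats::approx(time_s, values, xout = grid, rule = 1)$y
    v[is.na(v)] <- 0
  }
  mel_series(grid, pmax(v, 0), start_date = start_date, tz_offset = tz_offset)
}

#' Evaluate a series at arbitrary times by linear interpolation
#'
#' @param series A [mel_series()].
#' @param at Times in seconds since simulation start.
#' @return Melanopic irradiance at `at`; zero outside the grid.
#' @export
series_at <- function(series, at) {
  v <- stats::approx(series$time_s, series$E_mel, xout = at, rule = 2)$y
  pmax(v, 0)
}

#' Read / write the exposure CSV interchange format
#'
#' Columns: `timestamp` (ISO-8601 local, `YYYY-MM-DDTHH:MM:SS`) and
#' `E_e_mel_W_m2`; an optional `E_v_lx` photopic column is preserved as an
#' attribute when present.
#'
#' @param path File path.
#' @return `read_exposure_csv()`: a [mel_series()].
#' @export
read_exposure_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "E_e_mel_W_m2") %in% names(df))) {
    stop("exposure CSV needs columns `timestamp`, `E_e_mel_W_m2`",
         call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  start_date <- as.Date(ts[1L])
  t0 <- as.POSIXct(paste0(format(start_date), "T00:00:00"),
                   format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out <- mel_series(as.numeric(ts - t0, units = "secs"), df$E_e_mel_W_m2,
                    start_date = start_date)
  if ("E_v_lx" %in% names(df)) attr(out, "E_v_lx") <- df$E_v_lx
  out
}

#' @rdname read_exposure_csv
#' @param series A [mel_series()].
#' @export
write_exposure_csv <- function(series, path) {
  t0 <- as.POSIXct(paste0(format(attr(series, "start_date")), "T00:00:00"),
                   format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df <- data.frame(
    timestamp = format(t0 + series$time_s, "%Y-%m-%dT%H:%M:%S"),
    E_e_mel_W_m2 = series$E_mel
  )
  ev <- attr(series, "E_v_lx")
  if (!is.null(ev)) df$E_v_lx <- ev
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
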