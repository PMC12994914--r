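#' Build a daily sleep schedule
#'
#' Two hospital-patient archetypes are provided:
#' * `"scheduled"`: lights-out sleep from 00:00 to 06:00 every day — a
#'   moderately short sleeper with very regular habits.
#' * `"disrupted"`: in bed at midnight but sleep onset delayed to 00:24;
#'   the main bout holds 5.6 h of sleep broken by three 12-minute awakenings
#'   (placed at the quartile points of the bout, so sleep runs in four 84-min
#'   segments and ends 06:36), plus a midday nap from 15:00 to 16:20.
#'
#' The schedule is daily-periodic: the same intervals apply to every
#' simulated day.
#'
#' @param type `"scheduled"` or `"disrupted"`.
#' @return A `sleep_schedule`: list with `type`, `intervals` (tibble of
#'   `start_h`, `end_h` clock hours, sorted, non-overlapping) and
#'   `bedtime_h` (in-bed clock hour, used by pre-bed light rules).
#' @export
#' @examples
#' build_sleep_schedule("disrupted")$intervals
build_sleep_schedule <- function(type = c("scheduled", "disrupted")) {
  if (length(type) == 1L && !type[[1L]] %in% c("scheduled", "disrupted")) {
    stop(sprintf("unknown sleep type '%s'", type), call. = FALSE)
  }
  type <- match.arg(type)
  intervals <- if (type == "scheduled") {
    tibble::tibble(start_h = 0, end_h = 6)
  } else {
    # minute arithmetic keeps interval bounds exactly on the clock grid:
    # onset 00:24, four 84-min segments with 12-min awakenings, nap
    # 15:00-16:20
    starts_min <- 24 + (0:3) * (84 + 12)
    tibble::tibble(
      start_h = c(starts_min, 900) / 60,
      end_h = c(starts_min + 84, 980) / 60
    )
  }
  structure(
    list(type = type, intervals = intervals, bedtime_h = 24),
    class = "sleep_schedule"
  )
}

#' @export
print.sleep_schedule <- function(x, ...) {
  cat(sprintf("<sleep_schedule> type '%s'\n", x$type))
  print(x$intervals)
  invisible(x)
}

#' Sleep-wake state of a schedule on a time grid
#'
#' @param schedule A [build_sleep_schedule()] object.
#' @param time_s Times in seconds since simulation start (midnight day 0).
#' @return Logical vector, `TRUE` while awake.
#' @export
schedule_awake <- function(schedule, time_s) {
  # snap to whole seconds so interval boundaries are compared exactly on
  # every simulated day (the %% in clock_hour loses ~1e-15 h otherwise)
  h <- round(clock_hour(time_s) * 3600) / 3600
  eps <- 1e-9
  asleep <- rep(FALSE, length(h))
  for (i in seq_len(nrow(schedule$intervals))) {
    asleep <- asleep |
      (h >= schedule$intervals$start_h[i] - eps &
         h < schedule$intervals$end_h[i] - eps)
  }
  !asleep
}

#' Main-sleep wake-up clock hours of a schedule
#'
#' The end hours of sleep bouts longer than `min_h` hours (contiguous runs of
#' intervals separated by brief awakenings are merged). Used to place the
#' 2-hour post-wake alertness mask; naps shorter than `min_h` do not count.
#'
#' @inheritParams schedule_awake
#' @param min_h Minimum merged-bout length in hours to count as main sleep.
#' @param merge_gap_h Awakenings shorter than this merge adjacent intervals.
#' @return Numeric vector of clock hours.
#' @export
main_wake_hours <- function(schedule, min_h = 3, merge_gap_h = 0.5) {
  iv <- schedule$intervals[order(schedule$intervals$start_h), ]
  merged <- list()
  cur <- c(iv$start_h[1L], iv$end_h[1L])
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (iv$start_h[i] - cur[2L] <= merge_gap_h) {
        cur[2L] <- iv$end_h[i]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(iv$start_h[i], iv$end_h[i])
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur
  ends <- vapply(merged, function(b) b[2L], numeric(1))
  spans <- vapply(merged, function(b) b[2L] - b[1L], numeric(1))
  ends[spans >= min_h]
}

#' Read / write sleep schedules as JSON interval lists
#'
#' @param schedule A [build_sleep_schedule()] object.
#' @param path File path.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(
    list(type = schedule$type, bedtime_h = schedule$bedtime_h,
         intervals = schedule$intervals),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(type = x$type, intervals = tibble::as_tibble(x$intervals),
         bedtime_h = x$bedtime_h),
    class = "sleep_schedule"
  )
}
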