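#' Nightly plasma-melatonin peak times
#'
#' Finds the melatonin plasma peak for each simulated night using a 24-h
#' window centred on the subjective night (15:00 of the previous day to
#' 15:00 of the indexed day), so peaks straddling midnight are not split by
#' the civil-day boundary. The argmax is refined to sub-grid resolution by a
#' parabolic fit through the three samples around it.
#'
#' @param trajectory An `insom_trajectory` (see [integrate_model()]).
#' @return Tibble with `day` (0-based index of the night's morning),
#'   `t_peak_s` (seconds since simulation start) and `clock_h`.
#' @export
melatonin_peaks <- function(trajectory) {
  t <- trajectory$time_s
  m <- trajectory$melatonin_pmol_L
  dt <- attr(trajectory, "dt_s")
  days <- seq_len(max(1, round((t[length(t)] + dt) / 86400))) - 1L
  res <- lapply(days, function(d) {
    lo <- max(0, d * 86400 - 9 * 3600)
    hi <- min(t[length(t)], d * 86400 + 15 * 3600)
    idx <- which(t >= lo & t <= hi)
    if (length(idx) < 3L) return(NULL)
    mm <- m[idx]
    # undetectable (flat) nights are skipped; requesting them from the
    # phase-shift operations raises the undefined-result error there
    if (max(mm) - min(mm) < 1e-9) return(NULL)
    i <- idx[which.max(mm)]
    tp <- t[i]
    if (i > 1L && i < length(t)) {
      den <- m[i - 1L] - 2 * m[i] + m[i + 1L]
      if (den < 0) tp <- t[i] + dt / 2 * (m[i - 1L] - m[i + 1L]) / den
    }
    tibble::tibble(day = d, t_peak_s = tp, clock_h = clock_hour(tp))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(day = integer(), t_peak_s = numeric(),
                          clock_h = numeric())
  }
  out
}

wrap_minutes <- function(mins) {
  w <- ((mins + 720) %% 1440) - 720
  ifelse(w == -720, 720, w)
}

#' Daily circadian phase shift
#'
#' Signed clock-time difference (minutes) of the plasma-melatonin peak
#' between two days, wrapped to (-12 h, +12 h]. A peak that moves earlier
#' (phase advance) is negative.
#'
#' @inheritParams melatonin_peaks
#' @param day_i,day_j Day indices (0-based) of the two nights; typically
#'   consecutive.
#' @param peaks Optionally, a precomputed [melatonin_peaks()] table.
#' @return Shift in minutes.
#' @export
daily_phase_shift <- function(trajectory, day_i, day_j, peaks = NULL) {
  if (is.null(peaks)) peaks <- melatonin_peaks(trajectory)
  ci <- peaks$clock_h[match(day_i, peaks$day)]
  cj <- peaks$clock_h[match(day_j, peaks$day)]
  if (anyNA(c(ci, cj))) {
    stop("melatonin peak not available for the requested day(s)",
         call. = FALSE)
  }
  wrap_minutes((cj - ci) * 60)
}

#' Cumulative seasonal phase shift
#'
#' Sum of [daily_phase_shift()] over all consecutive night pairs whose
#' mornings fall inside the given meteorological season. When no single
#' daily shift exceeds 12 h this telescopes to the wrapped peak-time
#' difference between the season's last and first night.
#'
#' @inheritParams daily_phase_shift
#' @param season One of `"spring"`, `"summer"`, `"fall"`, `"winter"`.
#' @return Cumulative shift in minutes (advance negative).
#' @export
seasonal_phase_shift <- function(trajectory, season, peaks = NULL) {
  if (is.null(peaks)) peaks <- melatonin_peaks(trajectory)
  start_date <- attr(trajectory, "start_date")
  peaks$season <- season_of(start_date + peaks$day)
  d <- peaks$day[peaks$season == season]
  if (length(d) < 2L) {
    stop(sprintf("season '%s' is not fully simulated", season), call. = FALSE)
  }
  shifts <- vapply(seq_len(length(d) - 1L), function(i) {
    daily_phase_shift(trajectory, d[i], d[i + 1L], peaks = peaks)
  }, numeric(1))
  sum(shifts)
}

trapz_auc <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Melatonin suppression by light
#'
#' Percentage reduction of the plasma-melatonin area under the curve in a
#' clock window of one day, relative to a matched dark-reference trajectory
#' (same entrained initial state and sleep schedule, light zeroed):
#' `100 * (AUC_dark - AUC_day) / AUC_dark`. Windows are morning
#' (08:00-12:00) and evening (18:00-24:00); the afternoon carries almost no
#' circulating melatonin and is not assessed.
#'
#' @param trajectory_light,trajectory_dark Matched `insom_trajectory`
#'   objects on the same grid and parameters.
#' @param window `"morning"` or `"evening"`.
#' @param day 0-based day index.
#' @return Suppression in percent, or `NA` when the dark-reference AUC is
#'   zero (undefined ratio).
#' @export
melatonin_suppression <- function(trajectory_light, trajectory_dark,
                                  window = c("evening", "morning"), day = 0) {
  window <- match.arg(window)
  if (nrow(trajectory_light) != nrow(trajectory_dark)) {
    stop("light and dark trajectories must share the same grid",
         call. = FALSE)
  }
  rng <- if (window == "morning") c(8, 12) else c(18, 24)
  t0 <- day * 86400 + rng[1] * 3600
  t1 <- day * 86400 + rng[2] * 3600
  idx <- which(trajectory_light$time_s >= t0 & trajectory_light$time_s <= t1)
  auc_day <- trapz_auc(trajectory_light$time_s[idx],
                       trajectory_light$melatonin_pmol_L[idx])
  auc_dark <- trapz_auc(trajectory_dark$time_s[idx],
                        trajectory_dark$melatonin_pmol_L[idx])
  if (!is.finite(auc_dark) || auc_dark <= 0) return(NA_real_)
  100 * (auc_dark - auc_day) / auc_dark
}

#' Period statistics of alertness outputs
#'
#' Arithmetic mean of KSS or vPVTRT over awake, valid samples in each
#' alertness period (morning 08-12, afternoon 12-18, evening 18-24) within
#' one season. Samples during sleep and within the 2-h post-wake exclusion
#' are not counted; an empty sample set yields `NA`.
#'
#' @inheritParams melatonin_peaks
#' @param metric `"KSS"` or `"vPVTRT"`.
#' @param season Season name, or `NULL` for the whole horizon.
#' @return Tibble with `period` and `mean_value`.
#' @export
period_statistics <- function(trajectory, metric = c("KSS", "vPVTRT"),
                              season = NULL) {
  metric <- match.arg(metric)
  col <- if (metric == "KSS") "KSS" else "vPVTRT_ms"
  df <- tibble::as_tibble(trajectory)
  df$period <- period_of(clock_hour(df$time_s), "alertness")
  df$season <- season_of(date_of(df$time_s, attr(trajectory, "start_date")))
  if (!is.null(season)) df <- df[df$season == season, ]
  df <- df[df$alertness_valid & !is.na(df$period) & !is.na(df[[col]]), ]
  out <- dplyr::summarise(
    dplyr::group_by(df, period = .data$period, .drop = FALSE),
    mean_value = mean(.data[[col]]), .groups = "drop"
  )
  out$mean_value[is.nan(out$mean_value)] <- NA_real_
  out
}

#' Seasonal metric set for one trajectory
#'
#' Derives the full per-season metric table: cumulative phase shift
#' (minutes, advance negative), mean daily melatonin suppression (%) for the
#' morning and evening windows, and mean KSS / vPVTRT per alertness period.
#' Seasonal suppression is the mean of daily suppression values across the
#' season's days.
#'
#' @inheritParams melatonin_peaks
#' @param dark Dark-reference trajectory; defaults to `attr(trajectory,
#'   "dark")` as attached by [simulate_trajectory()]. When absent,
#'   suppression rows are omitted.
#' @return Long tibble: `season`, `metric`, `period`, `value`.
#' @export
seasonal_metrics <- function(trajectory, dark = attr(trajectory, "dark")) {
  start_date <- attr(trajectory, "start_date")
  ndays <- floor(trajectory$time_s[nrow(trajectory)] / 86400)
  day_season <- season_of(start_date + 0:(max(ndays - 1, 0)))
  seasons <- unique(day_season)
  peaks <- melatonin_peaks(trajectory)
  rows <- list()
  for (s in as.character(seasons)) {
    days_s <- which(day_season == s) - 1L
    if (sum(day_season == s) >= 2) {
      ps <- tryCatch(
        seasonal_phase_shift(trajectory, s, peaks = peaks),
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        season = s, metric = "phase_shift_min", period = "season",
        value = ps
      )
    }
    if (!is.null(dark)) {
      for (w in c("morning", "evening")) {
        vals <- vapply(days_s, function(d) {
          melatonin_suppression(trajectory, dark, window = w, day = d)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          season = s, metric = "mel_suppression_pct", period = w,
          value = mean(vals, na.rm = TRUE)
        )
      }
    }
    for (m in c("KSS", "vPVTRT")) {
      st <- period_statistics(trajectory, m, season = s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        season = s,
        metric = if (m == "KSS") "KSS" else "vPVTRT_ms",
        period = as.character(st$period), value = st$mean_value
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$season <- factor(out$season, levels = season_levels())
  out
}
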