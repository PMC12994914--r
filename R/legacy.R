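#' Probability of a non-visual effect (N-VE)
#'
#' Threshold/interpolation rule on D55 equivalent illuminance: 0% at or
#' below 210 lx, 100% at or above 960 lx, and `100 * E_D55 / 750 - 28`
#' between, clamped to \[0, 100\]. Continuous and non-decreasing.
#'
#' @param e_d55 D55 equivalent illuminance, lx (non-negative).
#' @return Probability in percent.
#' @export
#' @examples
#' nve_probability(c(210, 585, 960))
nve_probability <- function(e_d55) {
  check_nonneg(e_d55, "e_d55")
  pmin(pmax(100 * e_d55 / 750 - 28, 0), 100)
}

#' Circadian potential (CP)
#'
#' Mean N-VE probability within one time-of-day period (resetting
#' 06:00-10:00, alerting 10:00-18:00, avoidance 18:00-06:00) across a whole
#' exposure series.
#'
#' @param series A [mel_series()] of D55 equivalent illuminance (lx) -- or a
#'   melanopic series converted via [irradiance_to_ed55()] by setting
#'   `convert = TRUE`.
#' @param nve_period `"resetting"`, `"alerting"` or `"avoidance"`.
#' @param convert If `TRUE`, treat `series` values as melanopic irradiance
#'   (W m^-2) and convert to D55 equivalent illuminance first.
#' @return Mean probability in percent.
#' @export
circadian_potential <- function(series,
                                nve_period = c("resetting", "alerting",
                                               "avoidance"),
                                convert = FALSE) {
  nve_period <- match.arg(nve_period)
  v <- if (convert) irradiance_to_ed55(series$E_mel) else series$E_mel
  per <- period_of(clock_hour(series$time_s), "nve")
  mean(nve_probability(v[per == nve_period]))
}

#' Daily non-visual direct response (nvRD)
#'
#' Cumulative daily light-dose metric on a 6-minute grid: each sample
#' contributes a saturating dose response of the vertical photopic
#' illuminance under a CIE D65 spectrum, accumulated over the day and
#' scaled so that the calibration condition -- 824 lx sustained for 5 h,
#' darkness otherwise -- yields exactly 4.2. The saturating accumulator is
#' this package's documented calibration of the published anchor (flagged
#' in the `calibration` attribute); half-saturation and slope are
#' configurable.
#'
#' @param illuminance_lx Vertical eye illuminance (CIE D65), lx, sampled
#'   every 6 minutes over one day (240 samples).
#' @param half_lx Half-saturation illuminance of the per-sample response.
#' @param hill Hill slope of the per-sample response.
#' @return Daily nvRD (dimensionless, >= 0), attribute
#'   `calibration = "saturating-dose accumulator, 4.2 anchor"`.
#' @export
#' @examples
#' e <- rep(0, 240); e[1:50] <- 824  # 5 h at 824 lx
#' nvrd_daily(e)  # 4.2
nvrd_daily <- function(illuminance_lx, half_lx = 119, hill = 1.8) {
  check_nonneg(illuminance_lx, "illuminance_lx")
  if (length(illuminance_lx) != 240L) {
    stop("nvRD requires one day on a 6-min grid (240 samples)",
         call. = FALSE)
  }
  f <- function(e) e^hill / (e^hill + half_lx^hill)
  anchor <- 4.2 / (f(824) * 5)           # response-hours -> nvRD units
  val <- anchor * sum(f(illuminance_lx)) * 0.1   # 6 min = 0.1 h
  structure(val, calibration = "saturating-dose accumulator, 4.2 anchor")
}

#' WELL equivalent-melanopic-lux compliance
#'
#' Evaluates the WELL circadian-lighting thresholds on an EML series.
#' Daytime tiers (`"150"`, `"250"` EML) require the threshold to be met for
#' at least 4 consecutive hours beginning at or before noon; the
#' residential tier (`"residential"`) requires EML below 50 lx after 20:00.
#' `per = "day"` returns the percentage of days compliant with the rule;
#' `per = "time"` returns the percentage of qualifying timesteps meeting
#' the threshold (the fraction-of-time reading used when correlating
#' against physiological outputs).
#'
#' @param series A [mel_series()] whose values are EML (lx); a melanopic
#'   irradiance series can be converted with `convert = TRUE`.
#' @param tier `"150"`, `"250"` or `"residential"`.
#' @param per `"day"` or `"time"`.
#' @param convert Treat values as melanopic W m^-2 and convert to EML.
#' @return Percentage in \[0, 100\].
#' @export
well_compliance <- function(series, tier = c("250", "150", "residential"),
                            per = c("day", "time"), convert = FALSE) {
  tier <- match.arg(tier)
  per <- match.arg(per)
  v <- if (convert) {
    mel_edi_to_eml(irradiance_to_mel_edi(series$E_mel))
  } else {
    series$E_mel
  }
  h <- clock_hour(series$time_s)
  day <- floor(series$time_s / 86400)
  dt_h <- attr(series, "dt_s") / 3600
  if (tier == "residential") {
    sel <- h >= 20
    ok <- v[sel] < 50
    if (per == "time") return(100 * mean(ok))
    return(100 * mean(tapply(ok, day[sel], all)))
  }
  thr <- as.numeric(tier)
  if (per == "time") {
    sel <- h >= 6 & h < 18   # qualifying daytime hours
    return(100 * mean(v[sel] > thr))
  }
  ok_day <- vapply(split(seq_along(v), day), function(idx) {
    hh <- h[idx]
    met <- v[idx] > thr
    run <- 0
    for (i in order(hh)) {
      run <- if (met[i]) run + dt_h else 0
      # the 4-h block must *begin* at or before noon
      if (run >= 4 && hh[i] - run + dt_h <= 12 + 1e-9) return(TRUE)
    }
    FALSE
  }, logical(1))
  100 * mean(ok_day)
}

#' Compliance with the melanopic-EDI exposure recommendations
#'
#' Expert-consensus (Brown et al.) thresholds evaluated on a melanopic-EDI
#' series against a sleep schedule: daytime samples should reach >= 250 lx,
#' the 3 h before bedtime should stay <= 10 lx, and the sleep environment
#' <= 1 lx. Daytime is the awake portion of the day outside the pre-bed
#' window. Each fraction of compliant samples is returned in percent.
#'
#' @param series A [mel_series()] of melanopic EDI (lx); use
#'   `convert = TRUE` for melanopic irradiance input.
#' @param schedule A [build_sleep_schedule()] (provides sleep intervals and
#'   the in-bed clock hour).
#' @param convert Treat values as melanopic W m^-2 and convert to EDI.
#' @return Named list `daytime`, `nighttime`, `sleep` (percent).
#' @export
brown_compliance <- function(series, schedule = build_sleep_schedule(),
                             convert = FALSE) {
  v <- if (convert) irradiance_to_mel_edi(series$E_mel) else series$E_mel
  h <- clock_hour(series$time_s)
  awake <- schedule_awake(schedule, series$time_s)
  bed <- schedule$bedtime_h %% 24
  prebed <- ((h - (bed - 3)) %% 24) < 3
  daytime <- awake & !prebed
  list(
    daytime = 100 * mean(v[daytime] >= 250),
    nighttime = 100 * mean(v[prebed & awake] <= 10),
    sleep = 100 * mean(v[!awake] <= 1)
  )
}

#' Ferguson effect-size label for a Pearson coefficient
#'
#' Categorizes `|r|` with half-open boundaries on the left: below 0.2 not
#' practically significant, 0.2 to below 0.5 practically significant, 0.5
#' to below 0.8 moderate, 0.8 and above strong.
#'
#' @param r Pearson correlation coefficient(s), `|r| <= 1`.
#' @return Character vector of labels.
#' @export
ferguson_label <- function(r) {
  if (anyNA(r) || any(abs(r) > 1)) {
    stop("|r| must be <= 1 and non-missing", call. = FALSE)
  }
  a <- abs(r)
  dplyr::case_when(
    a >= 0.8 ~ "strong",
    a >= 0.5 ~ "moderate",
    a >= 0.2 ~ "practically significant",
    TRUE ~ "not practically significant"
  )
}
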