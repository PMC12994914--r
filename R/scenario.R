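#' Lighting scenario configuration
#'
#' Describes one of the three annual lighting scenarios:
#' * `"daylight"`: daylight only.
#' * `"electric"`: daylight plus constant 6500 K electric light during all
#'   waking hours (06:00-24:00) and a 6500 K screen through the evening
#'   (18:00-24:00).
#' * `"dimming"`: as `"electric"` until 18:00, then the electric light
#'   shifts to a warm 2800 K preset from 18:00 to 22:00 and is dimmed to
#'   half power from 22:00 to 24:00; the screen shifts to a blue-depleted
#'   1900 K preset from 21:00 to 24:00.
#'
#' The CCT presets are scalar melanopic irradiances standing in for full
#' spectral power distributions (which belong to the upstream raytracing
#' stage, not this package); they are plain config values and can be
#' overridden.
#'
#' @param scenario One of `"daylight"`, `"electric"`, `"dimming"`.
#' @param daylight_peak Clear-sky interior melanopic irradiance at the
#'   window-front viewpoint at solar noon, W m^-2.
#' @param spike_peak Peak of the brief east-facing direct-sun morning spike
#'   before shades drop, W m^-2 (window-front).
#' @param shade_trigger_lx Photopic vertical eye illuminance (lx) above which
#'   dynamic shades lower and clip the received daylight.
#' @param presets Named list of melanopic irradiances (W m^-2) for
#'   `electric_6500`, `electric_2800`, `screen_6500`, `screen_1900`.
#' @param daylength_amplitude_h Half-range of the sinusoidal seasonal
#'   day-length modulation, hours (day length = 12 +/- this value).
#' @param mel_per_photopic Melanopic-EDI lux per photopic lux of interior
#'   daylight (used to express daylight as photopic for the shade rule).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("daylight", "electric", "dimming"),
                            daylight_peak = 2.5,
                            spike_peak = 8,
                            shade_trigger_lx = 3000,
                            presets = list(
                              electric_6500 = 0.35, electric_2800 = 0.10,
                              screen_6500 = 0.12, screen_1900 = 0.02
                            ),
                            daylength_amplitude_h = 2,
                            mel_per_photopic = 1) {
  scenario <- match.arg(scenario)
  vals <- c(daylight_peak, spike_peak, shade_trigger_lx,
            unlist(presets), daylength_amplitude_h, mel_per_photopic)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all scenario parameters must be finite and non-negative",
         call. = FALSE)
  }
  structure(
    list(scenario = scenario, daylight_peak = daylight_peak,
         spike_peak = spike_peak, shade_trigger_lx = shade_trigger_lx,
         presets = presets, daylength_amplitude_h = daylength_amplitude_h,
         mel_per_photopic = mel_per_photopic),
    class = "scenario_config"
  )
}

#' Generate an annual interior daylight melanopic-irradiance series
#'
#' A deterministic emulation of the annual daylight exposure at a reclined,
#' window-facing viewpoint: a raised-cosine daylight curve between sunrise
#' and sunset whose length varies sinusoidally across the year (longest near
#' the June solstice), plus a brief east-facing direct-sun spike after
#' sunrise. Whenever the implied photopic vertical illuminance would exceed
#' the shade trigger (default 3000 lx) dynamic shades lower and the received
#' irradiance is clipped at the trigger level — producing the characteristic
#' morning spike, shaded late morning and early-afternoon peak. Amplitude
#' attenuates monotonically with `view_depth` (0 = window-front, 1 = back of
#' the space).
#'
#' @param config A [scenario_config()].
#' @param year_days Number of days to generate.
#' @param view_depth Position in the space, in \[0, 1\].
#' @param dt Grid step, seconds.
#' @inheritParams mel_series
#' @return A [mel_series()].
#' @export
generate_daylight_series <- function(config, year_days = 365, view_depth = 0,
                                     dt = 60,
                                     start_date = as.Date("2023-01-01")) {
  if (!is.numeric(view_depth) || length(view_depth) != 1L ||
      is.na(view_depth) || view_depth < 0 || view_depth > 1) {
    stop("`view_depth` must be a single number in [0, 1]", call. = FALSE)
  }
  t <- seq(0, year_days * 86400 - dt, by = dt)
  h <- clock_hour(t)
  day <- floor(t / 86400)
  doy <- as.integer(format(date_of(t, start_date), "%j"))
  # day length peaks at the June solstice (day-of-year 172)
  half_len <- (12 + config$daylength_amplitude_h *
                 cos(2 * pi * (doy - 172) / 365.25)) / 2
  sunrise <- 12 - half_len
  sunset <- 12 + half_len
  atten <- 1 - 0.85 * view_depth
  up <- h > sunrise & h < sunset
  base <- ifelse(up,
    config$daylight_peak * atten *
      0.5 * (1 - cos(2 * pi * (h - sunrise) / (2 * half_len))),
    0
  )
  # east-facing direct-sun spike ~1 h after sunrise, pre-shade
  spike <- config$spike_peak * atten *
    exp(-((h - (sunrise + 1)) / 0.5)^2) * as.numeric(up)
  e <- base + spike
  # dynamic shades: clip where implied photopic illuminance exceeds trigger
  e_trigger <- mel_edi_to_irradiance(config$shade_trigger_lx *
                                       config$mel_per_photopic)
  e <- pmin(e, e_trigger)
  mel_series(t, e, start_date = start_date)
}

#' Compose a full scenario exposure series
#'
#' Sums the daylight contribution with the scenario's electric-light and
#' screen schedules (see [scenario_config()] for the three scenarios).
#'
#' @inheritParams generate_daylight_series
#' @param sleep A [build_sleep_schedule()] object (kept alongside the series
#'   in the returned attributes; light gating during sleep happens in the
#'   physiological model, not here).
#' @return A [mel_series()] with attribute `scenario`.
#' @export
compose_scenario <- function(config, sleep = build_sleep_schedule("scheduled"),
                             year_days = 365, view_depth = 0, dt = 60,
                             start_date = as.Date("2023-01-01")) {
  day <- generate_daylight_series(config, year_days, view_depth, dt,
                                  start_date)
  h <- clock_hour(day$time_s)
  e <- day$E_mel + electric_contribution(config, h) +
    screen_contribution(config, h)
  out <- mel_series(day$time_s, e, start_date = start_date)
  attr(out, "scenario") <- config$scenario
  attr(out, "sleep_type") <- sleep$type
  attr(out, "view_depth") <- view_depth
  out
}

electric_contribution <- function(config, h) {
  p <- config$presets
  switch(config$scenario,
    daylight = rep(0, length(h)),
    electric = ifelse(h >= 6 & h < 24, p$electric_6500, 0),
    dimming = dplyr::case_when(
      h >= 6 & h < 18 ~ p$electric_6500,
      h >= 18 & h < 22 ~ p$electric_2800,
      h >= 22 & h < 24 ~ p$electric_2800 / 2,
      TRUE ~ 0
    )
  )
}

screen_contribution <- function(config, h) {
  p <- config$presets
  switch(config$scenario,
    daylight = rep(0, length(h)),
    electric = ifelse(h >= 18 & h < 24, p$screen_6500, 0),
    dimming = dplyr::case_when(
      h >= 18 & h < 21 ~ p$screen_6500,
      h >= 21 & h < 24 ~ p$screen_1900,
      TRUE ~ 0
    )
  )
}

#' Read / write scenario configuration as YAML or JSON
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @export
read_scenario_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- x[intersect(names(x), names(formals(scenario_config)))]
  do.call(scenario_config, args)
}

#' @rdname read_scenario_config
#' @param config A [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
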