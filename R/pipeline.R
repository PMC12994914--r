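#' Legacy metric table for one exposure series
#'
#' Computes the full legacy metric set per season from one melanopic
#' irradiance series: mean daily nvRD, WELL daytime compliance (fraction of
#' daytime timesteps above 250 EML), compliance with the melanopic-EDI
#' daytime / pre-bed / sleep recommendations, and the three N-VE period
#' means (CP restricted to the season's days). Photopic-equivalent inputs
#' for nvRD are derived from melanopic irradiance via the D65 conversion.
#'
#' @param series A [mel_series()] of melanopic irradiance (W m^-2).
#' @param schedule A [build_sleep_schedule()].
#' @param by_season Aggregate per meteorological season (`TRUE`) or over
#'   the whole series (`FALSE`).
#' @return Tibble with one row per season (or one row total) and one
#'   column per legacy metric.
#' @export
legacy_metrics_table <- function(series, schedule = build_sleep_schedule(),
                                 by_season = TRUE) {
  start_date <- attr(series, "start_date")
  seas <- if (by_season) {
    as.character(season_of(date_of(series$time_s, start_date)))
  } else {
    rep("all", nrow(series))
  }
  edi <- irradiance_to_mel_edi(series$E_mel)
  eml <- mel_edi_to_eml(edi)
  ed55 <- irradiance_to_ed55(series$E_mel)
  h <- clock_hour(series$time_s)
  awake <- schedule_awake(schedule, series$time_s)
  bed <- schedule$bedtime_h %% 24
  prebed <- ((h - (bed - 3)) %% 24) < 3
  nvper <- period_of(h, "nve")
  # nvRD on its native 6-min grid per civil day, then averaged by season
  lx6 <- resample_series(series$time_s, edi, dt = 360,
                         days = n_days(series), start_date = start_date)
  nv <- nvrd_series(lx6)
  nv$season <- if (by_season) {
    as.character(season_of(start_date + nv$day))
  } else {
    "all"
  }
  rows <- lapply(unique(seas), function(g) {
    i <- seas == g
    tibble::tibble(
      season = g,
      nvRD = mean(nv$nvRD[nv$season == g]),
      WELL_daytime = 100 * mean(eml[i & h >= 6 & h < 18] > 250),
      brown_daytime = 100 * mean(edi[i & awake & !prebed] >= 250),
      brown_nighttime = 100 * mean(edi[i & awake & prebed] <= 10),
      brown_sleep = 100 * mean(edi[i & !awake] <= 1),
      NVE_resetting = mean(nve_probability(ed55[i & nvper == "resetting"])),
      NVE_alerting = mean(nve_probability(ed55[i & nvper == "alerting"])),
      NVE_avoidance = mean(nve_probability(ed55[i & nvper == "avoidance"]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Deterministic end-to-end run from a configuration file (YAML or JSON) or
#' list: scenario synthesis for every scenario x sleep-type x view-depth
#' unit, 7-day entrainment, annual (or configured-length) integration with a
#' dark reference, seasonal physiological metrics, legacy metrics, and --
#' when at least 3 units are present -- the correlation table. Writes
#' `metrics.csv`, `legacy.csv`, `correlations.csv` and `manifest.json` to
#' `out_dir`.
#'
#' Recognized config fields (all optional; defaults in parentheses):
#' `days` (365), `start_date` ("2023-01-01"), `dt` (20), `out_dt` (60),
#' `entrain_days` (7), `scenarios` (all three), `sleep_types` (both),
#' `view_depths` (0, 0.5, 1), `plots` (FALSE), plus any
#' [scenario_config()] parameter under `scenario_params`.
#'
#' @param config Path to a config file, or a named list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `metrics`, `legacy` and
#'   `correlations` tibbles and the output paths.
#' @export
run_pipeline <- function(config, out_dir = "insom-results") {
  t_start <- Sys.time()
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  units <- expand.grid(
    scenario = config$scenarios, sleep_type = config$sleep_types,
    view_depth = config$view_depths,
    stringsAsFactors = FALSE
  )
  metric_rows <- list()
  legacy_rows <- list()
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    sc_args <- c(list(scenario = u$scenario), config$scenario_params)
    sc <- do.call(scenario_config, sc_args)
    sleep <- build_sleep_schedule(u$sleep_type)
    exposure <- compose_scenario(sc, sleep, year_days = config$days,
                                 view_depth = u$view_depth,
                                 start_date = config$start_date)
    traj <- simulate_trajectory(exposure, sleep, config$params,
                                dt = config$dt, out_dt = config$out_dt,
                                entrain_days = config$entrain_days,
                                dark_reference = TRUE)
    sm <- seasonal_metrics(traj)
    lm <- legacy_metrics_table(exposure, sleep)
    key <- tibble::tibble(scenario = u$scenario, sleep_type = u$sleep_type,
                          view_depth = u$view_depth)
    metric_rows[[i]] <- dplyr::bind_cols(key[rep(1, nrow(sm)), ], sm)
    legacy_rows[[i]] <- dplyr::bind_cols(key[rep(1, nrow(lm)), ], lm)
  }
  metrics <- dplyr::bind_rows(metric_rows)
  legacy <- dplyr::bind_rows(legacy_rows)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(legacy, file.path(out_dir, "legacy.csv"),
                   row.names = FALSE)

  correlations <- NULL
  if (nrow(units) >= 3L) {
    wide <- tidyr::pivot_wider(
      metrics,
      names_from = c("metric", "period"), values_from = "value"
    )
    wide$season <- as.character(wide$season)
    by_type <- split(seq_len(nrow(wide)), wide$sleep_type)
    tabs <- lapply(names(by_type), function(st) {
      w <- wide[by_type[[st]], ]
      l <- legacy[legacy$sleep_type == st, ]
      l$sleep_type <- NULL
      w$sleep_type <- NULL
      correlate_metrics(l, w, sleep_type = st)
    })
    correlations <- dplyr::bind_rows(tabs)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  } else {
    message("fewer than 3 units: correlation stage skipped")
  }

  if (isTRUE(config$plots)) {
    first <- metrics[metrics$scenario == units$scenario[1L] &
                       metrics$sleep_type == units$sleep_type[1L] &
                       metrics$view_depth == units$view_depth[1L], ]
    try(render_ring_plot(first, "KSS",
                         file = file.path(out_dir, "ring_kss.png")),
        silent = TRUE)
  }

  manifest <- list(
    schema_version = 1,
    package_version = as.character(utils::packageVersion("insom")),
    config = config[setdiff(names(config), "params")],
    config_hash = unname(if (!is.null(cfg_path)) {
      tools::md5sum(cfg_path)
    } else {
      tools::md5sum(textConnection_md5(config))
    }),
    n_units = nrow(units),
    wall_time_s = as.numeric(Sys.time() - t_start, units = "secs")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(metrics = metrics, legacy = legacy,
                 correlations = correlations, out_dir = out_dir))
}

textConnection_md5 <- function(x) {
  f <- tempfile()
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE), f)
  f
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a path", call. = FALSE)
  defaults <- list(
    days = 365, start_date = "2023-01-01", dt = 20, out_dt = 60,
    entrain_days = 7,
    scenarios = c("daylight", "electric", "dimming"),
    sleep_types = c("scheduled", "disrupted"),
    view_depths = c(0, 0.5, 1),
    scenario_params = list(), params = list(), plots = FALSE
  )
  unknown <- setdiff(names(config), c(names(defaults), "schema_version"))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (!all(config$scenarios %in% c("daylight", "electric", "dimming"))) {
    stop("invalid scenario id in config", call. = FALSE)
  }
  if (!all(config$sleep_types %in% c("scheduled", "disrupted"))) {
    stop("invalid sleep type in config", call. = FALSE)
  }
  if (any(config$view_depths < 0 | config$view_depths > 1)) {
    stop("view_depths must lie in [0, 1]", call. = FALSE)
  }
  if (config$days < 1 || config$dt <= 0 ||
      config$out_dt %% config$dt != 0) {
    stop("days must be >= 1 and out_dt a multiple of dt", call. = FALSE)
  }
  config$start_date <- as.Date(config$start_date)
  config$params <- do.call(insom_params, as.list(config$params))
  config
}
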