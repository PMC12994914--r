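#' Time derivative of the physiological state
#'
#' Evaluates the full derivative vector of the coupled model at one state:
#' sleep-wake flip-flop voltages (`Vv`, `Vm`), homeostatic sleep pressure
#' (`H`, rising during wake and falling during sleep), circadian oscillator
#' pair (`x`, `y`), photoreceptor activity (`n`) and the two melatonin
#' compartments (`Ms`, `Mp`). Retinal input is gated to zero while asleep
#' (eyes closed), so light then influences neither the pacemaker drive nor
#' melatonin inhibition.
#'
#' @param state Named numeric vector as returned by [initial_state()].
#' @param light Melanopic irradiance at the eye, W m^-2.
#' @param awake Logical sleep-wake flag.
#' @param params An [insom_params()] list.
#' @return Named numeric derivative vector (per second).
#' @export
derivatives <- function(state, light, awake, params = insom_params()) {
  if (light < 0) stop("`light` must be >= 0", call. = FALSE)
  insom_deriv_cpp(as.numeric(state[state_names()]), light,
                  isTRUE(awake), params)
}

state_names <- function() c("Vv", "Vm", "H", "x", "y", "n", "Ms", "Mp")

#' Karolinska Sleepiness Scale prediction
#'
#' Regression on the homeostatic drive `H`, the circadian drive `C` and a
#' saturating instantaneous light term, clamped to the KSS range 1
#' (extremely alert) to 9 (fighting sleep). The light term is nearly fully
#' saturated by 0.075 W m^-2 of melanopic irradiance, so KSS discriminates
#' mainly among dim conditions.
#'
#' @param state An [initial_state()]-style vector (uses `H` and `x`), or any
#'   named vector/list providing `H` and `C` directly.
#' @param light Instantaneous melanopic irradiance, W m^-2.
#' @param params An [insom_params()] list.
#' @return KSS score in \[1, 9\].
#' @export
kss <- function(state, light = 0, params = insom_params()) {
  hc <- extract_hc(state)
  check_nonneg(light, "light")
  kss_value(hc$H, hc$C, light, params)
}

kss_value <- function(H, C, E, p) {
  g <- E^p$kss_hill / (E^p$kss_hill + p$kss_E50^p$kss_hill)
  g[E == 0] <- 0
  raw <- p$kss_0 + p$kss_H * H - p$kss_C * C - p$kss_L * g
  pmin(pmax(raw, 1), 9)
}

#' Mean reaction time (vPVTRT) prediction
#'
#' Regression on `H` and `C` alone: unlike KSS there is no instantaneous
#' light term, so at fixed drives the prediction is independent of the
#' momentary irradiance. Output is in milliseconds and strictly positive.
#'
#' @inheritParams kss
#' @return Mean reaction time, ms.
#' @export
vpvtrt <- function(state, params = insom_params()) {
  hc <- extract_hc(state)
  vpvtrt_value(hc$H, hc$C, params)
}

vpvtrt_value <- function(H, C, p) {
  pmax(p$rt_0 + p$rt_H * H - p$rt_C * C, p$rt_floor)
}

extract_hc <- function(state) {
  if (inherits(state, "insom_state") && !isTRUE(attr(state, "awake"))) {
    stop("alertness outputs are undefined during sleep", call. = FALSE)
  }
  s <- as.list(state)
  H <- s$H
  C <- if (!is.null(s$C)) s$C else 0.5 * (1 + s$x)
  if (is.null(H) || is.null(C)) {
    stop("`state` must provide `H` and either `C` or `x`", call. = FALSE)
  }
  list(H = H, C = C)
}

#' Integrate the physiological model over an exposure series
#'
#' Fixed-step 4th-order Runge-Kutta at `dt` (20 s by default) over the full
#' horizon of `exposure`. In `"forced"` mode the sleep-wake state follows
#' `sleep` exactly (imposed through a wake-effort/sleep-permission drive on
#' the flip-flop); in `"natural"` mode sleep onset occurs when the
#' wake-active voltage falls below threshold and wake on the hysteretic
#' upward recrossing, and `sleep` is ignored.
#'
#' @param exposure A [mel_series()] covering the horizon.
#' @param sleep A [build_sleep_schedule()] object (forced mode).
#' @param params An [insom_params()] list.
#' @param dt Integration step, seconds.
#' @param mode `"forced"` or `"natural"`.
#' @param out_dt Storage step, seconds (a multiple of `dt`); annual runs are
#'   typically stored at 60 s to keep trajectories light.
#' @param substep_s Internal RK4 substep, seconds. The neuronal voltage
#'   pair relaxes in ~10 s, so each macro step of `dt` is integrated in
#'   substeps of this length; the default 0.5 s leaves a wide stability
#'   margin and refining it further changes states only at round-off
#'   level.
#' @param init Initial [initial_state()]-style state (e.g. from [entrain()]).
#' @return An `insom_trajectory` tibble with columns `time_s`, `E_mel`,
#'   `awake`, `Vv`, `Vm`, `H`, `x`, `y`, `n`, `C`, `melatonin_pmol_L`,
#'   `KSS`, `vPVTRT_ms`, `alertness_valid`. KSS and vPVTRT are `NA` during
#'   sleep; `alertness_valid` is `FALSE` during sleep and for the first 2 h
#'   after waking from any sleep bout longer than 3 h.
#' @export
integrate_model <- function(exposure, sleep = build_sleep_schedule(),
                            params = insom_params(), dt = 20,
                            mode = c("forced", "natural"), out_dt = dt,
                            init = initial_state(), substep_s = 0.5) {
  mode <- match.arg(mode)
  stopifnot(out_dt %% dt == 0)
  horizon <- n_days(exposure) * 86400
  n_steps <- round(horizon / dt)
  t_half <- seq(0, horizon, by = dt / 2)
  light_half <- series_at(exposure, t_half)
  awake_sched <- if (mode == "forced") {
    schedule_awake(sleep, seq(0, horizon - dt, by = dt))
  } else {
    logical(0)
  }
  # halving dt refines light sampling and schedule resolution while the
  # substep stays fixed
  n_sub <- max(1L, as.integer(ceiling(dt / substep_s)))
  res <- insom_integrate_cpp(
    as.numeric(init[state_names()]), dt, n_steps, light_half,
    awake_sched, mode == "natural", params, as.integer(out_dt / dt), n_sub
  )
  t_out <- seq(0, horizon, by = out_dt)
  st <- res$states
  awake <- res$awake
  C <- 0.5 * (1 + st[, "x"])
  E <- series_at(exposure, t_out)
  KSS <- ifelse(awake, kss_value(st[, "H"], C, E, params), NA_real_)
  RT <- ifelse(awake, vpvtrt_value(st[, "H"], C, params), NA_real_)
  valid <- alertness_mask(awake, out_dt)
  out <- tibble::tibble(
    time_s = t_out, E_mel = E, awake = awake,
    Vv = st[, "Vv"], Vm = st[, "Vm"], H = st[, "H"],
    x = st[, "x"], y = st[, "y"], n = st[, "n"], C = C,
    melatonin_pmol_L = st[, "Mp"],
    KSS = KSS, vPVTRT_ms = RT, alertness_valid = valid
  )
  final <- structure(stats::setNames(st[nrow(st), ], state_names()),
                     awake = awake[length(awake)], class = "insom_state")
  structure(out,
    class = c("insom_trajectory", class(out)),
    start_date = attr(exposure, "start_date"), dt_s = out_dt,
    params = params, mode = mode, final_state = final
  )
}

# FALSE during sleep and for mask_h hours after waking from any sleep bout
# longer than min_bout_h. Sleep runs separated by awakenings shorter than
# merge_gap_h count as one bout (so a disrupted night with brief
# interruptions masks only after its final wake); naps shorter than
# min_bout_h never trigger the mask.
alertness_mask <- function(awake, dt_s, mask_h = 2, min_bout_h = 3,
                           merge_gap_h = 0.5) {
  n <- length(awake)
  valid <- awake
  r <- rle(awake)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sleep_idx <- which(!r$values)
  if (!length(sleep_idx)) return(valid)
  # merge sleep runs across brief awakenings
  bouts <- list()
  cur <- c(starts[sleep_idx[1L]], ends[sleep_idx[1L]])
  if (length(sleep_idx) > 1L) {
    for (i in sleep_idx[-1L]) {
      gap <- (starts[i] - cur[2L] - 1L) * dt_s
      if (gap <= merge_gap_h * 3600) {
        cur[2L] <- ends[i]
      } else {
        bouts[[length(bouts) + 1L]] <- cur
        cur <- c(starts[i], ends[i])
      }
    }
  }
  bouts[[length(bouts) + 1L]] <- cur
  mask_n <- round(mask_h * 3600 / dt_s)
  for (b in bouts) {
    asleep_s <- sum(!awake[b[1L]:b[2L]]) * dt_s
    if (asleep_s >= min_bout_h * 3600 && b[2L] < n) {
      valid[(b[2L] + 1L):min(n, b[2L] + mask_n)] <- FALSE
    }
  }
  valid
}

#' Entrain the model to a sleep schedule
#'
#' Runs the model for `days` repetitions of the first day of `exposure`
#' (darkness when no exposure is given) under `sleep`, starting from
#' [initial_state()], and returns the terminal state. Used to produce the
#' initial state of the assessed run so that results do not depend on the
#' arbitrary documented initial condition.
#'
#' @inheritParams integrate_model
#' @param days Number of entrainment days; `0` returns `init` unchanged.
#' @param exposure Optional [mel_series()]; only its first day is used,
#'   repeated daily.
#' @return An [initial_state()]-style `insom_state`.
#' @export
entrain <- function(sleep = build_sleep_schedule(), params = insom_params(),
                    days = 7, exposure = NULL, dt = 20,
                    init = initial_state()) {
  if (days == 0) return(init)
  t <- seq(0, days * 86400 - dt, by = dt)
  e <- if (is.null(exposure)) {
    rep(0, length(t))
  } else {
    series_at(exposure, t %% 86400)
  }
  series <- mel_series(t, e, start_date = attr(exposure, "start_date") %||%
                         as.Date("2023-01-01"))
  traj <- integrate_model(series, sleep, params, dt = dt, mode = "forced",
                          out_dt = dt, init = init)
  attr(traj, "final_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an entrained physiological trajectory
#'
#' Convenience wrapper: 7-day entrainment to `sleep` under the first day of
#' `exposure`, then integration over the full exposure horizon.
#'
#' @inheritParams integrate_model
#' @inheritParams entrain
#' @param entrain_days Days of entrainment pre-run.
#' @param dark_reference If `TRUE`, also simulate the same horizon from the
#'   same entrained state with all light zeroed and attach it as attribute
#'   `dark` (used by melatonin-suppression metrics).
#' @return An `insom_trajectory`; with `dark_reference`, the dark twin is in
#'   `attr(, "dark")`.
#' @export
simulate_trajectory <- function(exposure, sleep = build_sleep_schedule(),
                                params = insom_params(), dt = 20,
                                mode = "forced", out_dt = 60,
                                entrain_days = 7, dark_reference = FALSE) {
  state0 <- entrain(sleep, params, days = entrain_days, exposure = exposure,
                    dt = dt)
  traj <- integrate_model(exposure, sleep, params, dt = dt, mode = mode,
                          out_dt = out_dt, init = fill_ms(state0, params))
  if (dark_reference) {
    dark_series <- mel_series(exposure$time_s, rep(0, nrow(exposure)),
                              start_date = attr(exposure, "start_date"))
    attr(traj, "dark") <- integrate_model(
      dark_series, sleep, params, dt = dt, mode = mode, out_dt = out_dt,
      init = fill_ms(state0, params)
    )
  }
  traj
}

# Trajectories only store plasma melatonin; rebuild a consistent pineal
# compartment for a restart state from quasi-equilibrium with clearance.
fill_ms <- function(state, params) {
  if (is.na(state[["Ms"]])) {
    state[["Ms"]] <- state[["Mp"]] * params$k_clr / params$k_syn
  }
  state
}

#' Write a trajectory to the interchange CSV format
#'
#' Columns: `timestamp` (ISO-8601 local), `E_e_mel`, `awake`, `H`, `C`,
#' `melatonin_pmol_L`, `KSS`, `vPVTRT_ms`, `alertness_valid`.
#'
#' @param trajectory An `insom_trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  t0 <- as.POSIXct(paste0(format(attr(trajectory, "start_date")),
                          "T00:00:00"),
                   format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df <- data.frame(
    timestamp = format(t0 + trajectory$time_s, "%Y-%m-%dT%H:%M:%S"),
    E_e_mel = trajectory$E_mel,
    awake = trajectory$awake,
    H = trajectory$H,
    C = trajectory$C,
    melatonin_pmol_L = trajectory$melatonin_pmol_L,
    KSS = trajectory$KSS,
    vPVTRT_ms = trajectory$vPVTRT_ms,
    alertness_valid = trajectory$alertness_valid
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
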