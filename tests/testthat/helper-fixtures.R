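# Fixtures are generated in code; expensive simulations are memoised per
# test run.

flat_series <- function(days, level, dt = 60,
                        start_date = as.Date("2023-01-01")) {
  t <- seq(0, days * 86400 - dt, by = dt)
  mel_series(t, rep(level, length(t)), start_date = start_date)
}

# light `level` during [on, off) clock hours, darkness otherwise
photoperiod_series <- function(days, level = 0.5, on = 6, off = 24, dt = 60,
                               start_date = as.Date("2023-01-01")) {
  t <- seq(0, days * 86400 - dt, by = dt)
  h <- clock_hour(t)
  mel_series(t, ifelse(h >= on & h < off, level, 0),
             start_date = start_date)
}

.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# entrained regular 16:8 subject (scheduled sleep, 0.5 W/m2 while awake)
entrained_16_8 <- function() {
  fixture("e168", {
    p <- insom_params()
    sch <- build_sleep_schedule("scheduled")
    ex <- photoperiod_series(14, 0.5)
    st0 <- entrain(sch, p, days = 7, exposure = ex)
    list(p = p, sch = sch, ex = ex, st0 = st0,
         traj = integrate_model(ex, sch, p, out_dt = 60, init = st0))
  })
}

# trajectory whose plasma melatonin is a gaussian bump per night with
# programmed peak clock times (ground truth for phase-shift oracles)
synthetic_mel_traj <- function(peak_clock_h, dt = 60,
                               start_date = as.Date("2023-03-01"),
                               sd_h = 1.5, amp = 150) {
  n_days <- length(peak_clock_h)
  t <- seq(0, n_days * 86400 - dt, by = dt)
  mel <- rep(0, length(t))
  for (i in seq_len(n_days)) {
    if (is.na(peak_clock_h[i])) next  # NA leaves that night dark
    centre <- (i - 1) * 86400 + peak_clock_h[i] * 3600
    mel <- mel + amp * exp(-((t - centre)^2) / (2 * (sd_h * 3600)^2))
  }
  out <- tibble::tibble(
    time_s = t, E_mel = 0, awake = TRUE,
    Vv = 0, Vm = 0, H = 10, x = 0, y = 0, n = 0, C = 0.5,
    melatonin_pmol_L = mel, KSS = 3, vPVTRT_ms = 250,
    alertness_valid = TRUE
  )
  structure(out, class = c("insom_trajectory", class(out)),
            start_date = as.Date(start_date), dt_s = dt)
}

# hand-built hourly trajectory for period-statistics oracles
manual_traj <- function(kss, rt, awake, valid,
                        start_date = as.Date("2023-01-01")) {
  n <- length(kss)
  t <- seq(0, by = 3600, length.out = n)
  out <- tibble::tibble(
    time_s = t, E_mel = 0, awake = awake,
    Vv = 0, Vm = 0, H = 10, x = 0, y = 0, n = 0, C = 0.5,
    melatonin_pmol_L = 0,
    KSS = ifelse(awake, kss, NA_real_),
    vPVTRT_ms = ifelse(awake, rt, NA_real_),
    alertness_valid = valid
  )
  structure(out, class = c("insom_trajectory", class(out)),
            start_date = as.Date(start_date), dt_s = 3600)
}
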