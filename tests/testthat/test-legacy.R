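test_that("N-VE probability matches the published thresholds and interpolation", {
  expect_equal(nve_probability(960), 100)
  expect_equal(nve_probability(210), 0)
  expect_equal(nve_probability(585), 50)  # 100 * 585 / 750 - 28
  expect_equal(nve_probability(0), 0)
  expect_equal(nve_probability(5000), 100)
  # continuous and non-decreasing on a fine grid
  g <- nve_probability(seq(0, 1500, by = 0.5))
  expect_true(all(diff(g) >= 0))
  expect_lt(max(abs(diff(g))), 0.1)
  expect_error(nve_probability(-1), "non-negative")
})

test_that("circadian potential is the mean N-VE probability per period", {
  s_high <- flat_series(2, 960)  # values used directly as E_D55
  expect_equal(circadian_potential(s_high, "resetting"), 100)
  expect_equal(circadian_potential(s_high, "alerting"), 100)
  s_zero <- flat_series(2, 0)
  expect_equal(circadian_potential(s_zero, "avoidance"), 0)
  # half the period at 960, half at 210 -> 50
  t <- seq(0, 86400 - 60, by = 60)
  h <- clock_hour(t)
  v <- ifelse(h >= 6 & h < 8, 960, ifelse(h >= 8 & h < 10, 210, 0))
  s_mix <- mel_series(t, v)
  expect_equal(circadian_potential(s_mix, "resetting"), 50)
})

test_that("nvRD reproduces its calibration anchor and degenerate cases", {
  e <- rep(0, 240)
  e[21:70] <- 824  # 5 h at 824 lx on the 6-min grid
  expect_equal(as.numeric(nvrd_daily(e)), 4.2, tolerance = 1e-12)
  expect_equal(as.numeric(nvrd_daily(rep(0, 240))), 0)
  # doubling duration at fixed level is non-decreasing (cumulative dose)
  e2 <- rep(0, 240); e2[1:50] <- 400
  e3 <- rep(0, 240); e3[1:100] <- 400
  expect_gte(as.numeric(nvrd_daily(e3)), as.numeric(nvrd_daily(e2)))
  expect_error(nvrd_daily(rep(0, 100)), "6-min grid")
  # per-day wrapper requires the native grid
  s <- flat_series(1, 100, dt = 360)
  expect_equal(nrow(nvrd_series(s)), 1)
  expect_error(nvrd_series(flat_series(1, 100, dt = 60)), "6-min")
})

test_that("WELL compliance implements both tiers and both evaluation modes", {
  s300 <- flat_series(3, 300)  # values are EML
  expect_equal(well_compliance(s300, "150"), 100)
  expect_equal(well_compliance(s300, "250"), 100)
  dark <- flat_series(3, 0)
  expect_equal(well_compliance(dark, "150"), 0)
  expect_equal(well_compliance(dark, "250"), 0)
  expect_equal(well_compliance(dark, "residential"), 100)
  expect_equal(well_compliance(s300, "residential"), 0)
  # 200 EML from 11:00-16:00 only: the 4-h block beginning at 11:00
  # satisfies tier 1 but never reaches the 250 EML tier
  t <- seq(0, 86400 - 60, by = 60)
  h <- clock_hour(t)
  s200 <- mel_series(t, ifelse(h >= 11 & h < 16, 200, 0))
  expect_equal(well_compliance(s200, "150"), 100)
  expect_equal(well_compliance(s200, "250"), 0)
  # a 4-h block that begins after noon fails the day rule
  s_late <- mel_series(t, ifelse(h >= 13 & h < 18, 200, 0))
  expect_equal(well_compliance(s_late, "150"), 0)
  # timestep-fraction mode: fraction of daytime samples above threshold
  expect_equal(well_compliance(s200, "250", per = "time"), 0)
  expect_equal(well_compliance(s200, "150", per = "time"),
               100 * 5 / 12, tolerance = 1e-9)
})

test_that("melanopic-EDI recommendation compliance follows the three windows", {
  sch <- build_sleep_schedule("scheduled")
  t <- seq(0, 2 * 86400 - 60, by = 60)
  h <- clock_hour(t)
  # 300 lx EDI while day-active, dark in the pre-bed window and sleep
  v <- ifelse(h >= 6 & h < 21, 300, 0)
  s <- mel_series(t, v)
  br <- brown_compliance(s, sch)
  expect_equal(br$daytime, 100)
  expect_equal(br$nighttime, 100)
  expect_equal(br$sleep, 100)
  # 20 lx in the pre-bed window violates the <= 10 lx recommendation
  v2 <- ifelse(h >= 21, 20, v)
  br2 <- brown_compliance(mel_series(t, v2), sch)
  expect_equal(br2$nighttime, 0)
  # exactly 250 lx counts as meeting the daytime minimum
  v3 <- ifelse(h >= 6 & h < 21, 250, 0)
  br3 <- brown_compliance(mel_series(t, v3), sch)
  expect_equal(br3$daytime, 100)
  # just below does not
  v4 <- ifelse(h >= 6 & h < 21, 249.9, 0)
  expect_equal(brown_compliance(mel_series(t, v4), sch)$daytime, 0)
})

test_that("Ferguson labels use the published cut-points with half-open boundaries", {
  expect_equal(ferguson_label(0.6), "moderate")
  expect_equal(ferguson_label(-0.98), "strong")
  expect_equal(ferguson_label(0.1), "not practically significant")
  expect_equal(ferguson_label(c(0.2, 0.5, 0.8)),
               c("practically significant", "moderate", "strong"))
  expect_equal(ferguson_label(0.1999), "not practically significant")
  expect_equal(ferguson_label(-0.5), "moderate")
  expect_error(ferguson_label(1.2), "<= 1")
  expect_error(ferguson_label(NA), "<= 1")
})

test_that("correlation matches the textbook Pearson formula on a 10-point fixture", {
  set.seed(7)
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 6.3, 7.0, 8.8, 9.1, 10.5)
  y <- 2.5 * x - 1 + c(0.3, -0.2, 0.4, -0.5, 0.1, 0.2, -0.3, 0.5, -0.1, 0)
  legacy <- tibble::tibble(m_legacy = x)
  insom_m <- tibble::tibble(m_insom = y)
  tab <- correlate_metrics(legacy, insom_m, sleep_type = "scheduled")
  # brute-force covariance oracle
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tab$r, r_brute, tolerance = 1e-12)
  expect_equal(tab$n, 10)
  expect_equal(tab$effect_size, ferguson_label(r_brute))
  expect_lt(tab$p, 0.01)
})

test_that("correlation handles exact linear relations and degenerate columns", {
  x <- 1:8
  exact <- correlate_metrics(tibble::tibble(a = x),
                             tibble::tibble(b = x))
  expect_equal(exact$r, 1, tolerance = 1e-12)
  neg <- correlate_metrics(tibble::tibble(a = x),
                           tibble::tibble(b = -2 * x + 3))
  expect_equal(neg$r, -1, tolerance = 1e-12)
  flat <- correlate_metrics(tibble::tibble(a = x),
                            tibble::tibble(b = rep(1, 8)))
  expect_true(is.na(flat$r))
  expect_match(flat$note, "zero variance")
  expect_error(correlate_metrics(tibble::tibble(a = 1:2),
                                 tibble::tibble(b = 1:2)),
               "at least 3")
})

test_that("correlation joins matched units on shared key columns", {
  keys <- expand.grid(scenario = c("s1", "s2"), season = c("a", "b"),
                      stringsAsFactors = FALSE)
  legacy <- tibble::tibble(keys, lm = c(1, 2, 3, 4))
  insom_m <- tibble::tibble(keys[c(3, 1, 4, 2), ],
                            im = c(6, 2, 8, 4))  # shuffled rows, im = 2*lm
  tab <- correlate_metrics(legacy, insom_m)
  expect_equal(tab$r, 1, tolerance = 1e-12)
})

test_that("legacy metric table has one row per season and sane ranges", {
  sch <- build_sleep_schedule("scheduled")
  ex <- compose_scenario(scenario_config("electric"), sch, year_days = 8)
  lt <- legacy_metrics_table(ex, sch, by_season = FALSE)
  expect_equal(nrow(lt), 1)
  expect_true(all(unlist(lt[, c("WELL_daytime", "brown_daytime",
                                "brown_nighttime", "brown_sleep",
                                "NVE_resetting", "NVE_alerting",
                                "NVE_avoidance")]) >= 0))
  expect_true(all(unlist(lt[, c("WELL_daytime", "brown_daytime",
                                "brown_nighttime", "brown_sleep",
                                "NVE_resetting", "NVE_alerting",
                                "NVE_avoidance")]) <= 100))
  expect_gte(lt$nvRD, 0)
})
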