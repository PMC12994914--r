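#' Per-day nvRD over a multi-day series
#'
#' Splits a 6-minute exposure series into civil days and applies
#' [nvrd_daily()] to each.
#'
#' @param series A [mel_series()] of vertical D65 photopic illuminance (lx)
#'   with a 360-s grid step.
#' @inheritParams nvrd_daily
#' @return Tibble with `day` and `nvRD`.
#' @export
nvrd_series <- function(series, half_lx = 119, hill = 1.8) {
  if (abs(attr(series, "dt_s") - 360) > 1e-9) {
    stop("nvRD requires a 6-min (360 s) grid", call. = FALSE)
  }
  day <- floor(series$time_s / 86400)
  vals <- vapply(split(series$E_mel, day), function(v) {
    as.numeric(nvrd_daily(v, half_lx = half_lx, hill = hill))
  }, numeric(1))
  tibble::tibble(day = as.integer(names(vals)), nvRD = unname(vals))
}

#' Correlate legacy lighting metrics with physiological metrics
#'
#' Pearson correlation between each legacy-metric column and each
#' physiological-metric column of two matched unit tables (one row per
#' analysis unit, e.g. viewpoint x scenario x season), with two-sided
#' p-values and Ferguson effect-size labels. Zero-variance columns yield a
#' missing `r` flagged in `note`.
#'
#' @param legacy Data frame of legacy metrics; one row per unit, metric
#'   columns numeric, plus optional key columns (`unit`, `scenario`,
#'   `season`, ...) shared with `insom`. Any column name present in both
#'   tables is treated as a key.
#' @param insom Data frame of physiological metrics with the same rows
#'   (matched by the shared key columns when present, otherwise by row
#'   order).
#' @param sleep_type Optional label recorded in the output.
#' @return A `CorrelationTable` tibble: `legacy_metric`, `insom_metric`,
#'   `sleep_type`, `n`, `r`, `p`, `effect_size`, `note`.
#' @export
correlate_metrics <- function(legacy, insom, sleep_type = NA_character_) {
  keys <- intersect(names(legacy), names(insom))
  if (length(keys)) {
    merged <- dplyr::inner_join(legacy, insom, by = keys,
                                suffix = c(".legacy", ".insom"),
                                relationship = "one-to-one")
    lcols <- setdiff(names(legacy), keys)
    icols <- setdiff(names(insom), keys)
    lcols <- ifelse(lcols %in% icols, paste0(lcols, ".legacy"), lcols)
    icols <- ifelse(icols %in% setdiff(names(legacy), keys),
                    paste0(icols, ".insom"), icols)
  } else {
    if (nrow(legacy) != nrow(insom)) {
      stop("unit sets must match (same keys or equal row count)",
           call. = FALSE)
    }
    merged <- dplyr::bind_cols(legacy, insom)
    lcols <- names(legacy)
    icols <- names(insom)
  }
  if (nrow(merged) < 3L) {
    stop("need at least 3 matched units to correlate", call. = FALSE)
  }
  grid <- expand.grid(legacy_metric = lcols, insom_metric = icols,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    xv <- merged[[grid$legacy_metric[i]]]
    yv <- merged[[grid$insom_metric[i]]]
    ok <- stats::complete.cases(xv, yv)
    xv <- xv[ok]; yv <- yv[ok]
    if (length(xv) < 3L || stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      return(tibble::tibble(
        legacy_metric = grid$legacy_metric[i],
        insom_metric = grid$insom_metric[i],
        sleep_type = sleep_type, n = length(xv),
        r = NA_real_, p = NA_real_, effect_size = NA_character_,
        note = "zero variance or too few units"
      ))
    }
    ct <- stats::cor.test(xv, yv, method = "pearson")
    tibble::tibble(
      legacy_metric = grid$legacy_metric[i],
      insom_metric = grid$insom_metric[i],
      sleep_type = sleep_type, n = length(xv),
      r = unname(ct$estimate), p = ct$p.value,
      effect_size = ferguson_label(min(max(unname(ct$estimate), -1), 1)),
      note = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}
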