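#' Seasonal ring plot
#'
#' Circular summary of one seasonal metric at a single viewpoint: the four
#' quadrants are the meteorological seasons (spring, summer, fall, winter
#' clockwise from the top-right) and the concentric bands are the
#' time-of-day periods with the morning period innermost; a central arrow
#' marks the view direction. Single-period metrics (cumulative phase shift)
#' use one band with a signed colour scale. Cells with missing values are
#' drawn grey.
#'
#' @param metrics A [seasonal_metrics()] tibble.
#' @param metric Metric id to draw (a value of `metrics$metric`, e.g.
#'   `"KSS"`, `"vPVTRT_ms"`, `"mel_suppression_pct"`, `"phase_shift_min"`).
#' @param file Optional output path (`.png` or `.pdf`); written with
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly when writing to file.
#' @export
render_ring_plot <- function(metrics, metric = "KSS", file = NULL) {
  df <- metrics[metrics$metric == metric, , drop = FALSE]
  if (nrow(df) == 0L) stop("metric not present: ", metric, call. = FALSE)
  missing_seasons <- setdiff(season_levels(), as.character(df$season))
  if (length(missing_seasons)) {
    stop("missing season(s): ", paste(missing_seasons, collapse = ", "),
         call. = FALSE)
  }
  periods <- unique(as.character(df$period))
  band <- stats::setNames(seq_along(periods), periods)  # inner = first
  quad <- stats::setNames(0:3 * 90, season_levels())
  df$xmin <- quad[as.character(df$season)]
  df$xmax <- df$xmin + 90
  df$ymin <- band[as.character(df$period)]
  df$ymax <- df$ymin + 0.9
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax,
      ymin = .data$ymin, ymax = .data$ymax, fill = .data$value
    ), colour = "white") +
    ggplot2::annotate("segment", x = 0, xend = 0, y = 0, yend = 0.8,
                      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(
      limits = c(0, 360), breaks = quad + 45, labels = season_levels()
    ) +
    ggplot2::ylim(0, max(df$ymax) + 0.2) +
    ggplot2::labs(title = metric, fill = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.title = ggplot2::element_blank())
  p <- if (metric == "phase_shift_min") {
    p + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                      high = "#b2182b", midpoint = 0,
                                      na.value = "grey80")
  } else {
    p + ggplot2::scale_fill_viridis_c(na.value = "grey80")
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Stacked dynamics panels of a trajectory
#'
#' Draws the classic stacked view of the model over a day range: H, C,
#' sleep-wake state, melanopic irradiance, KSS, vPVTRT and plasma
#' melatonin. When a dark-reference trajectory is supplied (or attached as
#' `attr(trajectory, "dark")`), its melatonin and alertness traces are
#' overlaid in light red.
#'
#' @inheritParams melatonin_peaks
#' @param days Length-2 day range (0-based, end exclusive).
#' @param dark Optional matched dark-reference trajectory.
#' @param file Optional output path.
#' @return A ggplot object faceted into the 7 panels.
#' @export
render_dynamics <- function(trajectory, days = c(0, 3),
                            dark = attr(trajectory, "dark"), file = NULL) {
  if (length(days) != 2L || days[2] <= days[1]) {
    stop("`days` must be an increasing length-2 range", call. = FALSE)
  }
  sel <- trajectory$time_s >= days[1] * 86400 &
    trajectory$time_s < days[2] * 86400
  if (!any(sel)) stop("empty day range", call. = FALSE)
  panels <- c(H = "H", C = "C", state = "awake", E_e_mel = "E_mel",
              KSS = "KSS", vPVTRT = "vPVTRT_ms", Mel = "melatonin_pmol_L")
  long <- function(tr, who) {
    df <- tibble::as_tibble(tr)[sel, ]
    out <- lapply(names(panels), function(nm) {
      tibble::tibble(
        time_d = df$time_s / 86400,
        panel = nm, value = as.numeric(df[[panels[[nm]]]]), source = who
      )
    })
    dplyr::bind_rows(out)
  }
  df <- long(trajectory, "lit")
  if (!is.null(dark)) {
    dd <- long(dark, "dark")
    dd <- dd[dd$panel %in% c("Mel", "KSS", "vPVTRT"), ]
    df <- dplyr::bind_rows(df, dd)
  }
  df$panel <- factor(df$panel, levels = names(panels))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_d, .data$value,
                                        colour = .data$source)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::scale_colour_manual(
      values = c(lit = "black", dark = "#e08080"), guide = "none"
    ) +
    ggplot2::labs(x = "day", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 9, dpi = 150)
    return(invisible(p))
  }
  p
}
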