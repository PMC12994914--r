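#' Meteorological season of a calendar date
#'
#' Seasons follow the meteorological boundaries used throughout the package:
#' spring Mar 1 - May 31, summer Jun 1 - Aug 31, fall Sep 1 - Nov 30, winter
#' Dec 1 - Feb 28/29 (Feb 29 is assigned to winter).
#'
#' @param date A `Date` vector.
#' @return Factor with levels `spring`, `summer`, `fall`, `winter`.
#' @export
season_of <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  s <- dplyr::case_when(
    m %in% 3:5 ~ "spring",
    m %in% 6:8 ~ "summer",
    m %in% 9:11 ~ "fall",
    TRUE ~ "winter"
  )
  factor(s, levels = season_levels())
}

season_levels <- function() c("spring", "summer", "fall", "winter")

#' Time-of-day period partitions
#'
#' Three partitions of the clock day are used by the metrics:
#' * `"alertness"`: morning \[08:00, 12:00), afternoon \[12:00, 18:00),
#'   evening \[18:00, 24:00); KSS/vPVTRT statistics.
#' * `"melatonin"`: morning \[08:00, 12:00), evening \[18:00, 24:00);
#'   suppression windows (afternoon omitted: little melatonin circulates).
#' * `"nve"`: resetting \[06:00, 10:00), alerting \[10:00, 18:00),
#'   avoidance \[18:00, 06:00).
#'
#' @param hour Clock hour in \[0, 24), numeric vector.
#' @param partition One of `"alertness"`, `"melatonin"`, `"nve"`.
#' @return Factor of period labels; `NA` for hours outside the partition.
#' @export
period_of <- function(hour, partition = c("alertness", "melatonin", "nve")) {
  partition <- match.arg(partition)
  hour <- hour %% 24
  p <- switch(partition,
    alertness = dplyr::case_when(
      hour >= 8 & hour < 12 ~ "morning",
      hour >= 12 & hour < 18 ~ "afternoon",
      hour >= 18 ~ "evening",
      TRUE ~ NA_character_
    ),
    melatonin = dplyr::case_when(
      hour >= 8 & hour < 12 ~ "morning",
      hour >= 18 ~ "evening",
      TRUE ~ NA_character_
    ),
    nve = dplyr::case_when(
      hour >= 6 & hour < 10 ~ "resetting",
      hour >= 10 & hour < 18 ~ "alerting",
      TRUE ~ "avoidance"
    )
  )
  factor(p, levels = period_levels(partition))
}

period_levels <- function(partition) {
  switch(partition,
    alertness = c("morning", "afternoon", "evening"),
    melatonin = c("morning", "evening"),
    nve = c("resetting", "alerting", "avoidance")
  )
}
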