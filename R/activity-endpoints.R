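# Active-period (bout) detection and the activity endpoint set.

#' Detect active periods (bouts) in a per-minute label sequence
#'
#' Maximal runs of consecutive `active` minutes (runs are broken by any
#' non-active minute or by a time discontinuity in the label sequence). Each
#' run of length L minutes is assigned to a half-open duration bin; runs of
#' 1 minute or less are reported but excluded from the ">1 min" statistics.
#'
#' @param labels Tibble with `epoch_start_ms` (or `minute`) and `class`;
#'   minutes must be sorted.
#' @param bin_edges Bin edges in minutes (default `c(1, 2, 5, 15)` giving
#'   bins >1–<=2, >2–<=5, >5–<=15, plus >15).
#' @return Tibble: `start_ms`, `duration_min`, `bin` (factor; `"<=1"` for
#'   excluded short runs).
#' @export
detect_active_periods <- function(labels, bin_edges = c(1, 2, 5, 15)) {
  if (!nrow(labels)) {
    return(tibble(start_ms = numeric(), duration_min = numeric(),
                  bin = character()))
  }
  t <- if ("epoch_start_ms" %in% names(labels)) labels$epoch_start_ms
       else labels$minute * 60000
  act <- labels$class == "active" & !is.na(labels$class)
  # break runs at time discontinuities
  newblock <- c(TRUE, diff(t) != 60000)
  grp <- cumsum(newblock | c(TRUE, act[-1] != act[-length(act)]))
  runs <- tibble(t = t, act = act, grp = grp) |>
    group_by(.data$grp) |>
    summarise(start_ms = min(.data$t), duration_min = dplyr::n(),
              act = .data$act[1], .groups = "drop") |>
    filter(.data$act)
  lab <- c("<=1",
           paste0(">", bin_edges[-length(bin_edges)], " to <=", bin_edges[-1]),
           paste0(">", bin_edges[length(bin_edges)]))
  runs$bin <- cut(runs$duration_min, c(0, bin_edges, Inf), labels = lab,
                  right = TRUE)
  runs |> select("start_ms", "duration_min", "bin")
}

#' Compute the activity endpoint set from per-minute labels and scores
#'
#' Endpoints normalized to wear time: daytime quantities are computed within
#' the daytime clock window and divided by daytime wear hours where "per
#' hour"; percentages are class minutes over daytime wear minutes; "average"
#' endpoints are per-valid-day means over the monitoring period. The daily
#' peak hourly score is the maximum over the day's daytime clock hours of the
#' hour's summed score rescaled to a full wear hour (hours with under 30 wear
#' minutes are not eligible).
#'
#' @param minutes Tibble with one row per recorded minute: `date`, `minute`
#'   (0–1439), `class` (`NA` where unlabelled), `score` (`NA` where absent)
#'   and logical `wear`.
#' @param daytime Daytime clock window in hours, default `c(6, 22)`.
#' @param valid_min Wear minutes for a valid day (default 1080).
#' @param bin_edges Active-period bin edges (minutes).
#' @return One-row tibble of class `wearals_activity_endpoints`: see Details.
#' @details Endpoint columns: `n_valid_days`, `avg_daytime_active_min`,
#'   `pct_daytime_active`, `avg_daytime_sedentary_min` (sedentary including
#'   lying), `pct_daytime_sedentary`, `total_daytime_score_per_h`,
#'   `total_24h_score_per_h`, `max_daytime_score_per_h`,
#'   `mean_max_daytime_score_per_h`, `active_periods_per_h_1_2`,
#'   `active_periods_per_h_2_5`, `active_periods_per_h_5_15`,
#'   `avg_duration_active_periods_gt1`. If no day is valid, all endpoint
#'   values are `NA` and `reason` explains why.
#' @export
compute_activity_endpoints <- function(minutes, daytime = c(6, 22),
                                       valid_min = 1080,
                                       bin_edges = c(1, 2, 5, 15)) {
  stopifnot(all(c("date", "minute", "class", "wear") %in% names(minutes)))
  if (!"score" %in% names(minutes)) minutes$score <- NA_real_
  day_wear <- minutes |>
    group_by(.data$date) |>
    summarise(wear_minutes = sum(.data$wear), .groups = "drop") |>
    mutate(valid_day = .data$wear_minutes >= valid_min)
  valid_days <- day_wear$date[day_wear$valid_day]
  if (!length(valid_days)) {
    out <- tibble(n_valid_days = 0L, reason = "no valid days (>= 18 h wear)")
    class(out) <- c("wearals_activity_endpoints", class(out))
    return(out)
  }
  m <- minutes |>
    filter(.data$date %in% valid_days) |>
    mutate(daytime = .data$minute >= daytime[1] * 60 &
             .data$minute < daytime[2] * 60)
  dm <- m |> filter(.data$daytime, .data$wear)
  n_days <- length(valid_days)
  daytime_wear_min <- nrow(dm)
  daytime_wear_h <- daytime_wear_min / 60
  wear_24h_h <- sum(m$wear) / 60

  active_min <- sum(dm$class == "active", na.rm = TRUE)
  sed_min <- sum(dm$class %in% c("sedentary_not_lying", "lying"), na.rm = TRUE)

  # peak hourly score per day, rescaled to a full wear hour
  daily_peaks <- m |>
    filter(.data$daytime, .data$wear, !is.na(.data$score)) |>
    mutate(hour = .data$minute %/% 60) |>
    group_by(.data$date, .data$hour) |>
    summarise(hscore = sum(.data$score) * 60 / dplyr::n(),
              wear_min = dplyr::n(), .groups = "drop") |>
    filter(.data$wear_min >= 30)
  daily_peaks <- if (nrow(daily_peaks)) {
    daily_peaks |>
      group_by(.data$date) |>
      summarise(peak = max(.data$hscore), .groups = "drop")
  } else tibble(date = as.Date(character()), peak = numeric())

  periods <- m |>
    filter(.data$daytime) |>
    arrange(.data$date, .data$minute) |>
    group_by(.data$date) |>
    group_modify(~ detect_active_periods(.x)) |>
    ungroup()
  per_h <- function(binlab) {
    sum(periods$bin == binlab, na.rm = TRUE) / daytime_wear_h
  }
  gt1 <- periods |> filter(.data$duration_min > 1)

  out <- tibble(
    n_valid_days = n_days,
    avg_daytime_active_min = active_min / n_days,
    pct_daytime_active = 100 * active_min / daytime_wear_min,
    avg_daytime_sedentary_min = sed_min / n_days,
    pct_daytime_sedentary = 100 * sed_min / daytime_wear_min,
    total_daytime_score_per_h = sum(dm$score, na.rm = TRUE) / daytime_wear_h,
    total_24h_score_per_h = sum(m$score[m$wear], na.rm = TRUE) / wear_24h_h,
    max_daytime_score_per_h = if (nrow(daily_peaks)) max(daily_peaks$peak) else NA_real_,
    mean_max_daytime_score_per_h = if (nrow(daily_peaks)) mean(daily_peaks$peak) else NA_real_,
    active_periods_per_h_1_2 = per_h(">1 to <=2"),
    active_periods_per_h_2_5 = per_h(">2 to <=5"),
    active_periods_per_h_5_15 = per_h(">5 to <=15"),
    avg_duration_active_periods_gt1 =
      if (nrow(gt1)) mean(gt1$duration_min) else NA_real_,
    reason = NA_character_
  )
  class(out) <- c("wearals_activity_endpoints", class(out))
  out
}

#' Build a per-minute record table from classified epochs
#'
#' Joins per-minute classification labels and scores into the canonical
#' minute table consumed by [compute_activity_endpoints()].
#'
#' @param labels Tibble from [classify_stream()] (`epoch_start_ms`, `class`,
#'   `score`).
#' @param session_start_clock ISO-8601 clock of `t_ms = 0`.
#' @return Minute tibble: `date`, `minute`, `class`, `score`, `wear`.
#' @export
labels_to_minutes <- function(labels, session_start_clock) {
  t0 <- as.POSIXct(session_start_clock, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d"))
  abs_s <- as.numeric(t0) + labels$epoch_start_ms / 1000
  tibble(
    date = as.Date(as.POSIXct(abs_s, origin = "1970-01-01", tz = "UTC")),
    minute = (floor(abs_s / 60) %% 1440),
    class = labels$class,
    score = labels$score,
    wear = TRUE
  )
}
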