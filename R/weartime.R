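# Nonwear detection, per-day wear accounting, and cohort coverage summaries.

#' Detect nonwear intervals in an accelerometer stream
#'
#' Two nonwear signatures are flagged: (a) recording gaps — stretches longer
#' than 60 s with no samples at all (device off or charging); and (b)
#' still-nonwear — maximal runs of at least `min_gap_min` minutes in which
#' every axis' standard deviation stays below `still_sd_g` (device off-body
#' but recording). Intervals separated by under 5 minutes are merged.
#'
#' @param stream Accelerometer tibble (`t_ms, ax_g, ay_g, az_g`).
#' @param min_gap_min Minimum still-run length to flag, minutes (default 30,
#'   a conventional actigraphy nonwear heuristic).
#' @param still_sd_g Per-axis stillness threshold, g (default 0.004).
#' @param merge_min Merge intervals separated by less than this, minutes.
#' @return Tibble `start_ms, end_ms, kind` (`"gap"` or `"still"`),
#'   time-ordered and non-overlapping.
#' @export
detect_nonwear <- function(stream, min_gap_min = 30, still_sd_g = 0.004,
                           merge_min = 5) {
  stopifnot(nrow(stream) > 0)
  t <- stream$t_ms
  out <- list()
  # (a) recording gaps > 60 s
  dt <- diff(t)
  gi <- which(dt > 60000)
  if (length(gi)) {
    out[[1]] <- tibble(start_ms = t[gi], end_ms = t[gi + 1], kind = "gap")
  }
  # (b) still runs: per-minute per-axis sd below threshold
  minute <- floor(t / 60000)
  sds <- stream |>
    mutate(.minute = minute) |>
    group_by(.data$.minute) |>
    summarise(n = dplyr::n(),
              s1 = sd(.data$ax_g), s2 = sd(.data$ay_g), s3 = sd(.data$az_g),
              .groups = "drop")
  sds$still <- !is.na(sds$s1) &
    sds$s1 < still_sd_g & sds$s2 < still_sd_g & sds$s3 < still_sd_g
  # only consecutive minutes count as one run
  full_min <- tibble(.minute = seq(min(sds$.minute), max(sds$.minute))) |>
    left_join(sds, by = ".minute") |>
    mutate(still = !is.na(.data$still) & .data$still)
  r <- rle(full_min$still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= min_gap_min)
  if (length(runs)) {
    out[[length(out) + 1L]] <- tibble(
      start_ms = (full_min$.minute[starts[runs]]) * 60000,
      end_ms = (full_min$.minute[ends[runs]] + 1) * 60000,
      kind = "still"
    )
  }
  if (!length(out)) {
    return(tibble(start_ms = numeric(), end_ms = numeric(), kind = character()))
  }
  iv <- list_rbind(out) |> arrange(.data$start_ms)
  # merge intervals separated by < merge_min
  merged <- iv[1, ]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv$start_ms[i] - merged$end_ms[last] < merge_min * 60000) {
        merged$end_ms[last] <- max(merged$end_ms[last], iv$end_ms[i])
        if (merged$kind[last] != iv$kind[i]) merged$kind[last] <- "merged"
      } else {
        merged <- bind_rows(merged, iv[i, ])
      }
    }
  }
  merged
}

# per-minute day partition: every minute of each calendar day is exactly one
# of wear / nonwear / nodata. A minute has data if >= 30 s of it lies inside
# the recorded span excluding recording gaps; a data minute is nonwear if
# >= 30 s of it intersects a nonwear interval.
.day_minutes <- function(stream, nonwear, session_start_clock) {
  t0 <- as.POSIXct(session_start_clock, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d"))
  abs_ms <- function(ms) as.numeric(t0) * 1000 + ms
  span0 <- abs_ms(min(stream$t_ms)); span1 <- abs_ms(max(stream$t_ms))
  gaps <- nonwear |> filter(.data$kind %in% c("gap", "merged"))

  day0 <- as.Date(as.POSIXct(span0 / 1000, origin = "1970-01-01", tz = "UTC"))
  day1 <- as.Date(as.POSIXct(span1 / 1000, origin = "1970-01-01", tz = "UTC"))
  all_days <- seq(day0, day1, by = "day")
  mins <- tidyr::expand_grid(date = all_days, minute = 0:1439)
  m0 <- as.numeric(as.POSIXct(paste(mins$date, "00:00:00"), tz = "UTC")) * 1000 +
    mins$minute * 60000
  m1 <- m0 + 60000

  cover <- pmax(0, pmin(m1, span1) - pmax(m0, span0))
  # subtract recording-gap overlap from data coverage
  if (nrow(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      g0 <- abs_ms(gaps$start_ms[i]); g1 <- abs_ms(gaps$end_ms[i])
      cover <- cover - pmax(0, pmin(m1, g1) - pmax(m0, g0))
    }
  }
  nw_cover <- numeric(length(m0))
  if (nrow(nonwear)) {
    for (i in seq_len(nrow(nonwear))) {
      g0 <- abs_ms(nonwear$start_ms[i]); g1 <- abs_ms(nonwear$end_ms[i])
      nw_cover <- nw_cover + pmax(0, pmin(m1, g1) - pmax(m0, g0))
    }
  }
  mins$status <- ifelse(cover < 30000, "nodata",
                        ifelse(nw_cover >= 30000, "nonwear", "wear"))
  # minutes inside an off-body (gap/merged) interval are nonwear, not nodata
  if (nrow(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      g0 <- abs_ms(gaps$start_ms[i]); g1 <- abs_ms(gaps$end_ms[i])
      inside <- pmax(0, pmin(m1, g1) - pmax(m0, g0)) >= 30000
      mins$status[inside] <- "nonwear"
    }
  }
  mins$has_data <- cover >= 30000
  mins
}

#' Summarize wear time by calendar day
#'
#' Partitions every minute of every calendar day touched by the session into
#' wear / nonwear / no-data (the three always sum to 1440 per day), then
#' summarizes each day: a *valid day* has at least 18 hours (1080 min) of
#' wear; a *partial day* is any day with any recorded data.
#'
#' @param stream Accelerometer tibble.
#' @param nonwear Nonwear intervals from [detect_nonwear()] (minutes inside a
#'   recording gap count as nonwear, not missing, when the gap lies within the
#'   recorded span).
#' @param session_start_clock ISO-8601 clock time of session sample `t_ms = 0`.
#' @param valid_min Wear minutes required for a valid day (default 1080 = 18 h).
#' @return Tibble: `calendar_day`, `wear_minutes`, `nonwear_minutes`,
#'   `nodata_minutes`, `valid_day`, `partial_day`.
#' @export
summarize_days <- function(stream, nonwear, session_start_clock,
                           valid_min = 1080) {
  stopifnot(nrow(stream) > 0)
  mins <- .day_minutes(stream, nonwear, session_start_clock)
  mins |>
    group_by(calendar_day = .data$date) |>
    summarise(
      wear_minutes = sum(.data$status == "wear"),
      nonwear_minutes = sum(.data$status == "nonwear"),
      nodata_minutes = sum(.data$status == "nodata"),
      partial_day = any(.data$has_data),
      .groups = "drop"
    ) |>
    mutate(valid_day = .data$wear_minutes >= valid_min) |>
    select("calendar_day", "wear_minutes", "nonwear_minutes", "nodata_minutes",
           "valid_day", "partial_day")
}

#' Cohort coverage matrix and summary fractions
#'
#' Builds the patient × timepoint day-count matrix (full days = valid days
#' with >= 18 h wear; partial days = days with any data) and the cohort-level
#' coverage statistics: the fraction of expected timepoints with at least
#' `min_days` (partial) days of data, the fraction with no data at all, and
#' the per-timepoint percentage of patients providing any data.
#'
#' @param cell_days Tibble with one row per patient × timepoint × day:
#'   columns `patient_id`, `timepoint_id`, and either `status`
#'   (`"full"/"partial"/"absent"`, as in a simulated cohort's `days` table) or
#'   logical `valid_day`/`partial_day` from [summarize_days()].
#' @param expected_grid Tibble of all expected patient × timepoint cells
#'   (`patient_id`, `timepoint_id`); cells absent from `cell_days` count as
#'   no-data.
#' @param min_days Day count defining good coverage (default 3).
#' @return List of class `wearals_coverage`: `cells` (patient_id,
#'   timepoint_id, n_days, n_partial_days), `summary` (one row:
#'   `frac_ge_min_days`, `frac_no_data`), and `by_timepoint`
#'   (`pct_patients_with_data` per timepoint).
#' @export
coverage_matrix <- function(cell_days, expected_grid, min_days = 3) {
  if (!all(c("valid_day", "partial_day") %in% names(cell_days))) {
    if (!"status" %in% names(cell_days)) {
      abort_validation("`cell_days` needs valid_day/partial_day or status", "cell_days")
    }
    cell_days <- cell_days |>
      mutate(valid_day = .data$status == "full",
             partial_day = .data$status != "absent")
  }
  counts <- cell_days |>
    group_by(.data$patient_id, .data$timepoint_id) |>
    summarise(n_days = sum(.data$valid_day),
              n_partial_days = sum(.data$partial_day),
              .groups = "drop")
  cells <- expected_grid |>
    distinct(.data$patient_id, .data$timepoint_id) |>
    left_join(counts, by = c("patient_id", "timepoint_id")) |>
    mutate(n_days = tidyr::replace_na(.data$n_days, 0L),
           n_partial_days = tidyr::replace_na(.data$n_partial_days, 0L))
  summary <- tibble(
    n_cells = nrow(cells),
    frac_ge_min_days = mean(cells$n_partial_days >= min_days),
    frac_ge_min_full_days = mean(cells$n_days >= min_days),
    frac_no_data = mean(cells$n_partial_days == 0)
  )
  by_tp <- cells |>
    group_by(.data$timepoint_id) |>
    summarise(n_patients = dplyr::n(),
              pct_patients_with_data = 100 * mean(.data$n_partial_days > 0),
              .groups = "drop")
  structure(list(cells = cells, summary = summary, by_timepoint = by_tp),
            class = "wearals_coverage")
}

#' @export
print.wearals_coverage <- function(x, ...) {
  cat(sprintf(
    "<wearals_coverage: %d cells; %.0f%% with >=3 (partial) days; %.0f%% no data>\n",
    x$summary$n_cells, 100 * x$summary$frac_ge_min_days,
    100 * x$summary$frac_no_data))
  invisible(x)
}
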