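# Cohort dataset on disk: a manifest JSON indexing per-day session files
# (accel / RR / ground-truth label CSVs, speech WAVs), all timestamps in ms
# from session start, absolute session start clocks (ISO-8601) in the manifest.

#' Write a simulated cohort to a dataset directory
#'
#' Renders a simulated cohort to the on-disk session formats and writes a
#' manifest JSON indexing them. Ground-truth label tracks are always written
#' for days with data; accelerometer and RR streams, and per-visit speech
#' audio, are rendered on request (rendering a full day of accelerometer data
#' at 50 Hz is substantial, so choose `spec$accel_rate_hz` accordingly for
#' large cohorts).
#'
#' @param cohort A `wearals_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param render Character subset of `c("accel", "rr", "audio")`; label tracks
#'   are always written.
#' @param seed Seed for stream rendering noise (defaults to the cohort seed).
#' @return The manifest path, invisibly.
#' @export
write_cohort_dataset <- function(cohort, dir,
                                 render = character(), seed = NULL) {
  stopifnot(inherits(cohort, "wearals_cohort"))
  if (is.null(cohort$schedule)) {
    abort_validation("cohort must be simulated with detail = \"bouts\"", "cohort")
  }
  bad <- setdiff(render, c("accel", "rr", "audio"))
  if (length(bad)) abort_validation(paste0("unknown render target: ", bad[1]), "render")
  dir.create(file.path(dir, "sessions"), recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  seed <- seed %||% spec$seed

  sessions <- list()
  add_session <- function(session_id, patient, tp, day, type, file, start_clock) {
    sessions[[length(sessions) + 1L]] <<- list(
      session_id = session_id, patient_id = patient, timepoint_id = tp,
      day_index = day, type = type, file = file, start_clock = start_clock
    )
  }

  with_seed(seed, {
    with_data <- cohort$days |> filter(.data$status != "absent")
    for (i in seq_len(nrow(with_data))) {
      d <- with_data[i, ]
      sched <- cohort$schedule |>
        filter(.data$patient_id == d$patient_id,
               .data$timepoint_id == d$timepoint_id,
               .data$day_index == d$day_index)
      stem <- sprintf("%s_T%02d_D%d", d$patient_id, d$timepoint_id, d$day_index)
      clock <- format(as.POSIXct(paste(d$date, "00:00:00"), tz = "UTC"),
                      "%Y-%m-%dT%H:%M:%S")
      lab <- sched |>
        transmute(start_ms = round(.data$start_s * 1000),
                  end_ms = round((.data$start_s + .data$duration_s) * 1000),
                  task = .data$task)
      fl <- file.path("sessions", paste0(stem, "_labels.csv"))
      write_label_track(lab, file.path(dir, fl))
      add_session(paste0(stem, "_labels"), d$patient_id, d$timepoint_id,
                  d$day_index, "labels", fl, clock)
      if ("accel" %in% render) {
        stream <- render_day_accel(sched, rate_hz = spec$accel_rate_hz)
        fa <- file.path("sessions", paste0(stem, "_accel.csv"))
        write_accel_session(stream, file.path(dir, fa))
        add_session(paste0(stem, "_accel"), d$patient_id, d$timepoint_id,
                    d$day_index, "accel", fa, clock)
      }
      if ("rr" %in% render) {
        rr <- render_day_rr(sched, spec$hrv_params)
        fr <- file.path("sessions", paste0(stem, "_rr.csv"))
        write_rr_series(rr, file.path(dir, fr))
        add_session(paste0(stem, "_rr"), d$patient_id, d$timepoint_id,
                    d$day_index, "rr", fr, clock)
      }
    }
    if ("audio" %in% render) {
      visits <- cohort$manifest |> filter(.data$present)
      for (i in seq_len(nrow(visits))) {
        v <- visits[i, ]
        for (test in speech_tests()) {
          a <- synthesize_speech(test, spec$voice_params)
          stem <- sprintf("%s_T%02d_%s", v$patient_id, v$timepoint_id, test)
          fw <- file.path("sessions", paste0(stem, ".wav"))
          write_wav(a, file.path(dir, fw))
          add_session(stem, v$patient_id, v$timepoint_id, NA_integer_,
                      paste0("audio_", test), fw, NA_character_)
        }
      }
    }
  })

  manifest <- list(
    format_version = 1L,
    n_patients = spec$n_patients,
    n_timepoints = spec$n_timepoints,
    days_per_period = spec$days_per_period,
    accel_rate_hz = spec$accel_rate_hz,
    patients = cohort$patients$patient_id,
    timepoints = cohort$manifest |> distinct(.data$timepoint_id, .data$week),
    days = cohort$days,
    sessions = dplyr::bind_rows(lapply(sessions, as_tibble))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Render a day's bout schedule as an accelerometer stream
#'
#' @param day_schedule Bout tibble for one day (`start_s`, `duration_s`,
#'   `task`).
#' @param rate_hz Sampling rate, Hz.
#' @param noise_sd_g Per-axis noise sd, g.
#' @return Tibble `t_ms, ax_g, ay_g, az_g` (gaps where no bout is scheduled).
#' @export
render_day_accel <- function(day_schedule, rate_hz = 50, noise_sd_g = 0.02) {
  parts <- vector("list", nrow(day_schedule))
  for (i in seq_len(nrow(day_schedule))) {
    b <- simulate_accel_bout(day_schedule$task[i], day_schedule$duration_s[i],
                             rate_hz = rate_hz, noise_sd_g = noise_sd_g)
    b$t_ms <- b$t_ms + round(day_schedule$start_s[i] * 1000)
    parts[[i]] <- b[, c("t_ms", "ax_g", "ay_g", "az_g")]
  }
  out <- list_rbind(parts) |> arrange(.data$t_ms)
  out[!duplicated(out$t_ms), ]
}

#' Render a day's RR series matching the scheduled data extent
#'
#' @param day_schedule Bout tibble for one day.
#' @param params An [rr_params()] object.
#' @return Tibble `t_ms, rr_ms` covering the scheduled data span, with beats
#'   removed inside scheduling gaps (e.g. the charging gap).
#' @export
render_day_rr <- function(day_schedule, params = rr_params()) {
  span_end <- max(day_schedule$start_s + day_schedule$duration_s)
  rr <- simulate_rr_series(span_end, params)
  keep <- rep(FALSE, nrow(rr))
  for (i in seq_len(nrow(day_schedule))) {
    s <- day_schedule$start_s[i] * 1000
    e <- (day_schedule$start_s[i] + day_schedule$duration_s[i]) * 1000
    keep <- keep | (rr$t_ms >= s & rr$t_ms < e)
  }
  rr[keep, ]
}

#' Load a cohort dataset manifest
#'
#' Reads a manifest JSON and returns the dataset index: the session table
#' (with file paths resolved against the dataset root and verified to exist)
#' and the explicit patient × timepoint grid, with cells that have no data
#' marked missing rather than dropped.
#'
#' @param path Path to `manifest.json`.
#' @return List of class `wearals_dataset`: `root`, `sessions` tibble, `days`
#'   tibble, `grid` tibble (`patient_id`, `timepoint_id`, `week`,
#'   `has_data`).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "wearals_io_error")
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  root <- dirname(path)
  sessions <- as_tibble(m$sessions)
  if (nrow(sessions)) {
    if (anyDuplicated(sessions$session_id)) {
      dup <- sessions$session_id[duplicated(sessions$session_id)][1]
      abort(paste0("manifest error: duplicate session id ", dup),
            class = "wearals_format_error")
    }
    missing <- sessions$file[!file.exists(file.path(root, sessions$file))]
    if (length(missing)) {
      abort(paste0("manifest error: referenced file does not exist: ",
                   missing[1]),
            class = "wearals_io_error")
    }
  }
  tp <- as_tibble(m$timepoints)
  grid <- tidyr::expand_grid(patient_id = m$patients,
                             timepoint_id = tp$timepoint_id) |>
    left_join(tp, by = "timepoint_id")
  cells_with_data <- sessions |>
    filter(!is.na(.data$day_index)) |>
    distinct(.data$patient_id, .data$timepoint_id) |>
    mutate(has_data = TRUE)
  grid <- grid |>
    left_join(cells_with_data, by = c("patient_id", "timepoint_id")) |>
    mutate(has_data = !is.na(.data$has_data))
  structure(
    list(root = root, sessions = sessions, days = as_tibble(m$days),
         grid = grid, n_timepoints = m$n_timepoints,
         days_per_period = m$days_per_period, accel_rate_hz = m$accel_rate_hz),
    class = "wearals_dataset"
  )
}
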