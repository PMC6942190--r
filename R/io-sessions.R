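# On-disk session formats: comma-delimited UTF-8, one header line, fixed
# column names. Timestamps are integer milliseconds from session start;
# absolute session start clocks live in the manifest.

.read_session_csv <- function(path, cols) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "wearals_io_error")
  }
  dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  missing <- setdiff(cols, names(dat))
  if (length(missing)) {
    abort(
      paste0("schema error in ", path, ": missing column(s) ",
             paste(missing, collapse = ", ")),
      class = "wearals_format_error"
    )
  }
  dat[cols]
}

.check_monotone_t <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    # +1 for header line, +1 because the violation is at the later sample
    abort(
      sprintf("format error in %s: non-monotone timestamp at line %d",
              path, bad[1] + 2L),
      class = "wearals_format_error"
    )
  }
}

#' Read / write an accelerometer session
#'
#' Session files are CSV with columns `t_ms, ax_g, ay_g, az_g`: integer
#' milliseconds from session start and tri-axial acceleration in g. Readers
#' validate rather than repair: non-monotone timestamps raise a format error
#' citing the offending line; non-finite values or accelerations at or beyond
#' 16 g are rejected.
#'
#' @param path File path.
#' @return `read_accel_session()`: tibble `t_ms, ax_g, ay_g, az_g`.
#' @export
read_accel_session <- function(path) {
  dat <- .read_session_csv(path, c("t_ms", "ax_g", "ay_g", "az_g"))
  if (!all(vapply(dat, function(x) all(is.finite(x)), logical(1)))) {
    abort(paste0("format error in ", path, ": non-finite values"),
          class = "wearals_format_error")
  }
  .check_monotone_t(dat$t_ms, path)
  if (any(abs(as.matrix(dat[c("ax_g", "ay_g", "az_g")])) >= 16)) {
    abort(paste0("format error in ", path, ": |acceleration| must be < 16 g"),
          class = "wearals_format_error")
  }
  as_tibble(dat)
}

#' @rdname read_accel_session
#' @param stream Tibble with columns `t_ms, ax_g, ay_g, az_g`.
#' @export
write_accel_session <- function(stream, path) {
  stopifnot(all(c("t_ms", "ax_g", "ay_g", "az_g") %in% names(stream)))
  readr::write_csv(stream[c("t_ms", "ax_g", "ay_g", "az_g")], path, progress = FALSE)
  invisible(path)
}

#' Read / write an interbeat-interval session
#'
#' RR session files are CSV with columns `t_ms` (beat time, ms from session
#' start, strictly increasing) and `rr_ms` (interbeat interval, strictly
#' positive).
#'
#' @param path File path.
#' @return `read_rr_series()`: tibble `t_ms, rr_ms`.
#' @export
read_rr_series <- function(path) {
  dat <- .read_session_csv(path, c("t_ms", "rr_ms"))
  if (!all(vapply(dat, function(x) all(is.finite(x)), logical(1)))) {
    abort(paste0("format error in ", path, ": non-finite values"),
          class = "wearals_format_error")
  }
  .check_monotone_t(dat$t_ms, path)
  if (any(dat$rr_ms <= 0)) {
    abort(paste0("validation error in ", path, ": rr_ms must be > 0"),
          class = "wearals_format_error")
  }
  as_tibble(dat)
}

#' @rdname read_rr_series
#' @param series Tibble with columns `t_ms, rr_ms`.
#' @export
write_rr_series <- function(series, path) {
  stopifnot(all(c("t_ms", "rr_ms") %in% names(series)))
  readr::write_csv(series[c("t_ms", "rr_ms")], path, progress = FALSE)
  invisible(path)
}

#' Read / write a task-label track
#'
#' Label tracks are CSV with columns `start_ms, end_ms, task`: half-open
#' labelled intervals, time-ordered and non-overlapping.
#'
#' @param path File path.
#' @return `read_label_track()`: tibble `start_ms, end_ms, task`.
#' @export
read_label_track <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "wearals_io_error")
  }
  dat <- readr::read_csv(
    path,
    col_types = readr::cols(start_ms = readr::col_double(),
                            end_ms = readr::col_double(),
                            task = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(c("start_ms", "end_ms", "task"), names(dat))
  if (length(missing)) {
    abort(paste0("schema error in ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")),
          class = "wearals_format_error")
  }
  validate_label_track(dat, path)
  as_tibble(dat[c("start_ms", "end_ms", "task")])
}

validate_label_track <- function(dat, path = "<labels>") {
  if (any(dat$end_ms <= dat$start_ms)) {
    abort(paste0("format error in ", path, ": label end must exceed start"),
          class = "wearals_format_error")
  }
  o <- order(dat$start_ms)
  if (any(head(dat$end_ms[o], -1) > tail(dat$start_ms[o], -1))) {
    abort(paste0("format error in ", path, ": overlapping label intervals"),
          class = "wearals_format_error")
  }
  invisible(dat)
}

#' @rdname read_label_track
#' @param labels Tibble with columns `start_ms, end_ms, task`.
#' @export
write_label_track <- function(labels, path) {
  stopifnot(all(c("start_ms", "end_ms", "task") %in% names(labels)))
  validate_label_track(labels, "<labels>")
  readr::write_csv(labels[c("start_ms", "end_ms", "task")], path, progress = FALSE)
  invisible(path)
}
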