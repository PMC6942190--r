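# Movement-intensity activity score in rate-independent counts.

# 4th-order Butterworth high-pass at `cutoff_hz`, applied forward-backward
# per axis on contiguous runs (split at sample gaps > 1 s) to avoid filter
# transients bleeding across recording gaps
.highpass_axes <- function(stream, rate_hz, cutoff_hz = 0.5) {
  bf <- signal::butter(4, cutoff_hz / (rate_hz / 2), type = "high")
  run_id <- cumsum(c(0, diff(stream$t_ms) > 1000))
  out <- matrix(NA_real_, nrow(stream), 3)
  axes <- as.matrix(stream[, c("ax_g", "ay_g", "az_g")])
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) > 24) {  # filtfilt needs a few filter lengths of data
      # demean first: filtfilt start-up transients on a large DC offset would
      # otherwise leak gravity into the scores
      for (j in 1:3) {
        x <- axes[idx, j]
        out[idx, j] <- signal::filtfilt(bf, x - mean(x))
      }
    } else {
      out[idx, ] <- sweep(axes[idx, , drop = FALSE], 2,
                          colMeans(axes[idx, , drop = FALSE]))
    }
  }
  out
}

infer_rate_hz <- function(stream) {
  if (nrow(stream) < 2) return(NA_real_)
  1000 / median(diff(stream$t_ms))
}

#' Epoch activity score (movement-intensity counts)
#'
#' Gravity is removed with a 4th-order Butterworth high-pass at 0.5 Hz on each
#' axis; the score of an epoch is the sum over its samples of the magnitude of
#' the filtered acceleration vector, scaled by `1000 / rate` so the value is
#' independent of the sampling rate. Epochs containing no samples are absent
#' from the result (not zero).
#'
#' @param stream Accelerometer tibble (`t_ms, ax_g, ay_g, az_g`).
#' @param epoch_s Epoch length, seconds (default 60).
#' @param rate_hz Sampling rate; inferred from the median sample interval when
#'   `NULL`.
#' @return Tibble: `epoch_start_ms`, `n_samples`, `score`.
#' @examples
#' walk <- simulate_accel_bout("walking", 120, seed = 1)
#' activity_score(walk)
#' @export
activity_score <- function(stream, epoch_s = 60, rate_hz = NULL) {
  stopifnot(nrow(stream) > 1)
  rate_hz <- rate_hz %||% infer_rate_hz(stream)
  if (diff(range(stream$t_ms)) + 1000 / rate_hz < epoch_s * 1000 - 1) {
    abort_validation("stream must span at least one epoch", "stream")
  }
  hp <- .highpass_axes(stream, rate_hz)
  mag <- sqrt(rowSums(hp^2))
  epoch <- floor(stream$t_ms / (epoch_s * 1000))
  tibble(epoch = epoch, mag = mag) |>
    group_by(.data$epoch) |>
    summarise(n_samples = dplyr::n(),
              score = sum(.data$mag) * 1000 / rate_hz,
              .groups = "drop") |>
    transmute(epoch_start_ms = .data$epoch * epoch_s * 1000,
              n_samples = .data$n_samples, score = .data$score)
}
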