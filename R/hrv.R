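# RR cleaning, 5-min windows with retention accounting, RMSSD and LF/HF.

#' Clean an RR series
#'
#' Removes physiologically implausible beats: intervals outside 300–2000 ms,
#' and beats differing from the previous retained beat by more than 25 %
#' (ectopic/artefact screening). Every rejection is logged with its reason.
#'
#' @param series Tibble `t_ms, rr_ms`.
#' @param rr_range Physiological interval range, ms.
#' @param max_rel_jump Maximum allowed relative change vs the previous
#'   retained beat (default 0.25).
#' @return List: `series` (cleaned tibble) and `rejections` (tibble `t_ms,
#'   rr_ms, reason`).
#' @export
clean_rr <- function(series, rr_range = c(300, 2000), max_rel_jump = 0.25) {
  stopifnot(all(c("t_ms", "rr_ms") %in% names(series)))
  n <- nrow(series)
  keep <- logical(n)
  reason <- character(n)
  prev <- NA_real_
  for (i in seq_len(n)) {
    rr <- series$rr_ms[i]
    if (rr < rr_range[1]) {
      reason[i] <- "below physiological floor"
    } else if (rr > rr_range[2]) {
      reason[i] <- "above physiological ceiling"
    } else if (!is.na(prev) && abs(rr - prev) / prev > max_rel_jump) {
      reason[i] <- sprintf("jump > %d%% from previous retained beat",
                           round(100 * max_rel_jump))
    } else {
      keep[i] <- TRUE
      prev <- rr
    }
  }
  list(
    series = series[keep, ],
    rejections = series[!keep, ] |> mutate(reason = reason[!keep])
  )
}

#' Cut an RR series into fixed windows with retention accounting
#'
#' Tumbling (or strided) windows of `window_s` seconds. A window's retention
#' fraction is the time-coverage of its retained beats — the summed RR
#' intervals of beats falling in the window divided by the window span — so
#' it is robust to heart-rate differences. Sufficiency flags compare the
#' retention against the per-metric thresholds.
#'
#' @param series Cleaned RR tibble `t_ms, rr_ms`.
#' @param window_s Window length, seconds (default 300, the recommended
#'   5-min HRV window).
#' @param stride_s Stride between window starts (default = `window_s`).
#' @param thresholds A [sufficiency_thresholds()] object.
#' @param span_ms Optional total span c(start, end) in ms; defaults to
#'   `c(0, ceiling(max t / window) * window)`.
#' @return Nested tibble: `window_id`, `start_ms`, `end_ms`, `n_beats`,
#'   `retention`, `sufficient_rmssd`, `sufficient_lfhf`, and a `beats`
#'   list-column of per-window beat tibbles.
#' @export
window_rr <- function(series, window_s = 300, stride_s = window_s,
                      thresholds = sufficiency_thresholds(),
                      span_ms = NULL) {
  stopifnot(all(c("t_ms", "rr_ms") %in% names(series)))
  if (is.null(span_ms)) {
    end <- if (nrow(series)) ceiling(max(series$t_ms) / (window_s * 1000)) *
      window_s * 1000 else window_s * 1000
    span_ms <- c(0, end)
  }
  starts <- seq(span_ms[1], max(span_ms[1], span_ms[2] - window_s * 1000),
                by = stride_s * 1000)
  out <- lapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- s + window_s * 1000
    w <- series |> filter(.data$t_ms > s, .data$t_ms <= e)
    # time coverage: overlap of each beat's interval [t - rr, t] with the
    # window, including beats whose interval straddles a window edge
    str <- series |> filter(.data$t_ms - .data$rr_ms < e, .data$t_ms > s)
    ov <- pmin(str$t_ms, e) - pmax(str$t_ms - str$rr_ms, s)
    retention <- min(1, sum(ov) / (window_s * 1000))
    tibble(
      window_id = i, start_ms = s, end_ms = e, n_beats = nrow(w),
      retention = retention,
      sufficient_rmssd = retention >= thresholds$rmssd_min_retention,
      sufficient_lfhf = retention >= thresholds$lfhf_min_retention,
      beats = list(w)
    )
  })
  list_rbind(out)
}

#' Root mean square of successive RR differences
#'
#' `sqrt(mean((RR[i+1] - RR[i])^2))` over successive pairs of *temporally
#' adjacent* retained beats: pairs whose beat times are separated by more than
#' `gap_factor` times the window's median RR are excluded, so deleted beats do
#' not create spurious large differences.
#'
#' @param t_ms,rr_ms Beat times and RR intervals of one window.
#' @param gap_factor Gap-bridging exclusion factor (default 2).
#' @param min_beats Minimum beats required (default 3).
#' @return RMSSD in ms, or `NA` with attribute `reason` when not computable.
#' @export
rmssd <- function(t_ms, rr_ms, gap_factor = 2, min_beats = 3) {
  if (length(rr_ms) < min_beats) {
    return(structure(NA_real_, reason = "fewer beats than required"))
  }
  gaps <- diff(t_ms)
  d <- diff(rr_ms)
  ok <- gaps <= gap_factor * median(rr_ms)
  if (!any(ok)) {
    return(structure(NA_real_, reason = "no adjacent beat pairs"))
  }
  sqrt(mean(d[ok]^2))
}

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classical Lomb normalised periodogram evaluated on a frequency grid,
#' appropriate for beat-time-sampled RR series with missing beats (no
#' resampling or interpolation). The series is mean-subtracted; power is
#' scaled so that the integral over the full grid approximates the series
#' variance (ms^2).
#'
#' @param t_s Sample times, seconds.
#' @param y Values (e.g. RR in ms).
#' @param freq_hz Frequency grid, Hz.
#' @return Tibble `freq_hz, power`.
#' @export
lomb_periodogram <- function(t_s, y, freq_hz) {
  y <- y - mean(y)
  n <- length(y)
  stopifnot(n >= 4)
  p <- vapply(freq_hz, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t_s)), sum(cos(2 * w * t_s))) / (2 * w)
    ct <- cos(w * (t_s - tau)); st <- sin(w * (t_s - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
  # scale to a density whose integral over the grid ~ var(y)
  df <- diff(freq_hz)
  raw_int <- sum((p[-1] + p[-length(p)]) / 2 * df)
  dens <- if (raw_int > 0) p * var(y) / raw_int else p
  tibble(freq_hz = freq_hz, power = dens)
}

#' LF and HF spectral power and their ratio for one RR window
#'
#' Lomb-Scargle periodogram of the (beat-time, RR) series, mean-subtracted;
#' LF power is the integral over 0.04–0.15 Hz and HF over 0.15–0.40 Hz
#' (standard short-term HRV band edges); the ratio is LF/HF.
#'
#' @param t_ms,rr_ms Beat times (ms) and RR intervals (ms) of one window.
#' @param lf_band,hf_band Band edges, Hz.
#' @param grid_step_hz Frequency-grid resolution (default 0.002 Hz).
#' @param min_beats Minimum beats required.
#' @return One-row tibble `lf_power, hf_power, lf_hf_ratio, degenerate`
#'   (ratio `NA` and degenerate `TRUE` when HF power is zero).
#' @export
lf_hf <- function(t_ms, rr_ms, lf_band = c(0.04, 0.15),
                  hf_band = c(0.15, 0.40), grid_step_hz = 0.002,
                  min_beats = 16) {
  if (length(rr_ms) < min_beats) {
    return(tibble(lf_power = NA_real_, hf_power = NA_real_,
                  lf_hf_ratio = NA_real_, degenerate = NA))
  }
  grid <- seq(lf_band[1], hf_band[2], by = grid_step_hz)
  pg <- lomb_periodogram(t_ms / 1000, rr_ms, grid)
  band_int <- function(b) {
    idx <- pg$freq_hz >= b[1] & pg$freq_hz <= b[2]
    f <- pg$freq_hz[idx]; p <- pg$power[idx]
    sum((p[-1] + p[-length(p)]) / 2 * diff(f))
  }
  lf <- band_int(lf_band); hf <- band_int(hf_band)
  degenerate <- hf <= 0
  tibble(lf_power = lf, hf_power = hf,
         lf_hf_ratio = if (degenerate) NA_real_ else lf / hf,
         degenerate = degenerate)
}

#' Compute HRV metrics for sufficient windows
#'
#' Adds `rmssd_ms`, `lf_power`, `hf_power` and `lf_hf_ratio` columns to a
#' window table from [window_rr()]. Each metric is computed only where its
#' sufficiency flag is set; elsewhere it is `NA` (with the window's
#' insufficiency as the reason).
#'
#' @param windows Window tibble from [window_rr()].
#' @param ... Passed to [lf_hf()].
#' @return The window tibble with metric columns (beats list-column retained).
#' @export
hrv_metrics <- function(windows, ...) {
  rms <- vapply(seq_len(nrow(windows)), function(i) {
    if (!windows$sufficient_rmssd[i]) return(NA_real_)
    b <- windows$beats[[i]]
    as.numeric(rmssd(b$t_ms, b$rr_ms))
  }, numeric(1))
  lfhf_rows <- lapply(seq_len(nrow(windows)), function(i) {
    if (!windows$sufficient_lfhf[i]) {
      return(tibble(lf_power = NA_real_, hf_power = NA_real_,
                    lf_hf_ratio = NA_real_, degenerate = NA))
    }
    b <- windows$beats[[i]]
    lf_hf(b$t_ms, b$rr_ms, ...)
  })
  bind_cols(windows, tibble(rmssd_ms = rms), list_rbind(lfhf_rows))
}

#' Stratify HRV windows by concurrent activity class
#'
#' Assigns each window the majority activity class of the labelled minutes it
#' spans (windows without a label majority are excluded) and summarizes RMSSD
#' and LF/HF per class over sufficient windows.
#'
#' @param windows Window tibble with metrics from [hrv_metrics()].
#' @param minute_labels Tibble `epoch_start_ms, class` of per-minute activity
#'   labels on the same session clock.
#' @return List: `windows` (with `activity_class`), `summary` (per-class n,
#'   mean and variance of each metric).
#' @export
hrv_by_activity <- function(windows, minute_labels) {
  cls <- vapply(seq_len(nrow(windows)), function(i) {
    m <- minute_labels |>
      filter(.data$epoch_start_ms >= windows$start_ms[i],
             .data$epoch_start_ms < windows$end_ms[i],
             !is.na(.data$class))
    if (!nrow(m)) return(NA_character_)
    tab <- sort(table(m$class), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)  # no majority
    names(tab)[1]
  }, character(1))
  w <- windows |> mutate(activity_class = cls)
  summary <- w |>
    filter(!is.na(.data$activity_class)) |>
    group_by(.data$activity_class) |>
    summarise(
      n_windows = dplyr::n(),
      n_rmssd = sum(!is.na(.data$rmssd_ms)),
      rmssd_mean = mean(.data$rmssd_ms, na.rm = TRUE),
      rmssd_var = var(.data$rmssd_ms, na.rm = TRUE),
      n_lfhf = sum(!is.na(.data$lf_hf_ratio)),
      lfhf_mean = mean(.data$lf_hf_ratio, na.rm = TRUE),
      lfhf_var = var(.data$lf_hf_ratio, na.rm = TRUE),
      .groups = "drop"
    )
  list(windows = w, summary = summary)
}

#' Fraction of windows sufficient for each HRV metric
#'
#' The per-patient quality accounting: the share of 5-min windows whose
#' retention meets each metric's sufficiency threshold, reproducible from the
#' flags alone.
#'
#' @param windows Window tibble from [window_rr()], optionally with grouping
#'   columns (e.g. `patient_id`) already attached.
#' @param ... Grouping columns (tidy-select), e.g. `patient_id`.
#' @return Tibble with `n_windows`, `pct_sufficient_rmssd`,
#'   `pct_sufficient_lfhf` per group.
#' @export
sufficiency_summary <- function(windows, ...) {
  windows |>
    group_by(...) |>
    summarise(
      n_windows = dplyr::n(),
      pct_sufficient_rmssd = 100 * mean(.data$sufficient_rmssd),
      pct_sufficient_lfhf = 100 * mean(.data$sufficient_lfhf),
      .groups = "drop"
    )
}
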