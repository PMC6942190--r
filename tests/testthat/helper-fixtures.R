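# Shared fixture builders: everything is generated in code at test time.

# sinusoidal single-axis test stream (gravity on ay)
sine_stream <- function(freq_hz, amp_g, duration_s = 60, rate_hz = 50) {
  t_s <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  tibble::tibble(
    t_ms = round(t_s * 1000),
    ax_g = amp_g * sin(2 * pi * freq_hz * t_s),
    ay_g = 1,
    az_g = 0
  )
}

# evenly spaced RR window (complete coverage), as a beats tibble
constant_rr_window <- function(rr_ms = 800, window_s = 300) {
  n <- floor(window_s * 1000 / rr_ms)
  tibble::tibble(t_ms = cumsum(rep(rr_ms, n)), rr_ms = rr_ms)
}

# RR window with sinusoidal modulation at one frequency
modulated_rr_window <- function(freq_hz, amp_ms = 30, mean_rr = 800,
                                window_s = 300, noise_sd = 0) {
  p <- wearals::rr_params(
    mean_rr_ms = mean_rr,
    hf_amp_ms = if (freq_hz >= 0.15) amp_ms else 0,
    hf_freq_hz = max(0.15, min(0.4, freq_hz)),
    lf_amp_ms = if (freq_hz < 0.15) amp_ms else 0,
    lf_freq_hz = max(0.04, min(0.1499, freq_hz)),
    noise_sd_ms = noise_sd
  )
  wearals::simulate_rr_series(window_s + 5, p)
}

# minute table builder for endpoint tests: `spec` is a character vector of
# per-minute classes ("A","S","L", NA for no data), starting at `start_min`
minutes_from_classes <- function(classes, date = as.Date("2020-01-01"),
                                 start_min = 0, score = NA_real_) {
  cls <- dplyr::recode(classes, A = "active", S = "sedentary_not_lying",
                       L = "lying", .missing = NA_character_)
  tibble::tibble(
    date = date,
    minute = start_min + seq_along(classes) - 1,
    class = cls,
    score = score,
    wear = !is.na(cls)
  )
}
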