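#' Simulate an interbeat-interval (RR) series
#'
#' Generates a beat-level RR series: beat times are the cumulative sum of RR
#' values, and each RR value is the mean heart period plus low- and
#' high-frequency sinusoidal modulation evaluated at the beat time, plus white
#' noise. Beats are then independently deleted with `dropout_prob`, and
#' optional contiguous detachment gaps remove all beats in random intervals,
#' emulating electrode-contact loss.
#'
#' @param duration_s Duration of the series, seconds.
#' @param params An [rr_params()] object.
#' @param seed Optional seed.
#' @return Tibble with columns `t_ms` (beat time, ms from start) and `rr_ms`;
#'   attribute `n_generated` records the pre-dropout beat count.
#' @examples
#' rr <- simulate_rr_series(300, rr_params(noise_sd_ms = 0), seed = 1)
#' @export
simulate_rr_series <- function(duration_s, params = rr_params(), seed = NULL) {
  check_number(duration_s, "duration_s", 1e-9)
  if (!inherits(params, "rr_params")) {
    abort_validation("`params` must be an rr_params() object", "params")
  }
  with_seed(seed, {
    n_max <- ceiling(duration_s * 1000 / (params$mean_rr_ms - params$hf_amp_ms -
                                            params$lf_amp_ms - 4 * params$noise_sd_ms)) + 16L
    rr <- numeric(n_max)
    tt <- numeric(n_max)
    noise <- if (params$noise_sd_ms > 0) rnorm(n_max, 0, params$noise_sd_ms) else numeric(n_max)
    t_cur <- 0
    n <- 0L
    two_pi <- 2 * pi
    while (n < n_max) {
      t_s <- t_cur / 1000
      val <- params$mean_rr_ms +
        params$lf_amp_ms * sin(two_pi * params$lf_freq_hz * t_s) +
        params$hf_amp_ms * sin(two_pi * params$hf_freq_hz * t_s) +
        noise[n + 1L]
      val <- max(val, 200)  # physiological floor guard under heavy noise
      t_cur <- t_cur + val
      if (t_cur > duration_s * 1000) break
      n <- n + 1L
      rr[n] <- val
      tt[n] <- t_cur
    }
    out <- tibble(t_ms = tt[seq_len(n)], rr_ms = rr[seq_len(n)])
    n_generated <- nrow(out)
    if (params$dropout_prob > 0 && n_generated > 0) {
      keep <- runif(n_generated) >= params$dropout_prob
      out <- out[keep, ]
    }
    if (params$detach_rate_per_hr > 0 && nrow(out) > 0) {
      n_gaps <- rpois(1, params$detach_rate_per_hr * duration_s / 3600)
      if (n_gaps > 0) {
        starts <- runif(n_gaps, 0, duration_s * 1000)
        durs <- rexp(n_gaps, 1 / (params$detach_mean_s * 1000))
        drop <- rep(FALSE, nrow(out))
        for (i in seq_len(n_gaps)) {
          drop <- drop | (out$t_ms >= starts[i] & out$t_ms < starts[i] + durs[i])
        }
        out <- out[!drop, ]
      }
    }
    attr(out, "n_generated") <- n_generated
    out
  })
}
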