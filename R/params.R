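#' Interbeat-interval generator parameters
#'
#' Parameters of the synthetic RR (interbeat-interval) series generator. The
#' series is a mean heart period modulated by two sinusoids — a high-frequency
#' (respiratory, 0.15–0.4 Hz) and a low-frequency (0.04–0.15 Hz) component —
#' plus white noise, with optional per-beat dropout and contiguous
#' "patch-detachment" gaps emulating poor electrode contact.
#'
#' @param mean_rr_ms Mean interbeat interval in ms (300–2000).
#' @param hf_amp_ms,hf_freq_hz High-frequency modulation amplitude (ms) and
#'   frequency (Hz, within 0.15–0.4).
#' @param lf_amp_ms,lf_freq_hz Low-frequency modulation amplitude (ms) and
#'   frequency (Hz, within 0.04–<0.15).
#' @param noise_sd_ms Standard deviation of additive white noise (ms).
#' @param dropout_prob Independent per-beat deletion probability.
#' @param detach_rate_per_hr Expected number of contiguous detachment gaps per
#'   hour (0 disables them).
#' @param detach_mean_s Mean duration of a detachment gap, seconds.
#' @return A list of class `rr_params`.
#' @seealso [simulate_rr_series()]
#' @export
rr_params <- function(mean_rr_ms = 800, hf_amp_ms = 20, hf_freq_hz = 0.25,
                      lf_amp_ms = 20, lf_freq_hz = 0.10, noise_sd_ms = 5,
                      dropout_prob = 0, detach_rate_per_hr = 0,
                      detach_mean_s = 120) {
  check_number(mean_rr_ms, "mean_rr_ms", 300, 2000)
  check_number(hf_amp_ms, "hf_amp_ms", 0)
  check_number(hf_freq_hz, "hf_freq_hz", 0.15, 0.4)
  check_number(lf_amp_ms, "lf_amp_ms", 0)
  check_number(lf_freq_hz, "lf_freq_hz", 0.04, 0.15 - 1e-12)
  check_number(noise_sd_ms, "noise_sd_ms", 0)
  check_number(dropout_prob, "dropout_prob", 0, 1)
  check_number(detach_rate_per_hr, "detach_rate_per_hr", 0)
  check_number(detach_mean_s, "detach_mean_s", 0)
  structure(
    list(mean_rr_ms = mean_rr_ms, hf_amp_ms = hf_amp_ms,
         hf_freq_hz = hf_freq_hz, lf_amp_ms = lf_amp_ms,
         lf_freq_hz = lf_freq_hz, noise_sd_ms = noise_sd_ms,
         dropout_prob = dropout_prob, detach_rate_per_hr = detach_rate_per_hr,
         detach_mean_s = detach_mean_s),
    class = "rr_params"
  )
}

#' Voice synthesis parameters
#'
#' Ground-truth parameters for the source-filter speech synthesizer: an
#' impulse-train glottal source at `f0_hz` passed through two resonators at the
#' first two formants.
#'
#' @param f0_hz Fundamental frequency, Hz (60–400).
#' @param f1_hz,f2_hz First and second formant frequencies, Hz; must satisfy
#'   `f1 < f2 < sample_rate/2`.
#' @param jitter_frac Cycle-to-cycle fractional perturbation of the pitch
#'   period (e.g. 0.01 = 1 %).
#' @param sample_rate_hz Audio sample rate, Hz.
#' @return A list of class `voice_params`.
#' @seealso [synthesize_speech()]
#' @export
voice_params <- function(f0_hz = 120, f1_hz = 700, f2_hz = 1100,
                         jitter_frac = 0.01, sample_rate_hz = 44100) {
  check_number(f0_hz, "f0_hz", 60, 400)
  check_number(f1_hz, "f1_hz", 100)
  check_number(f2_hz, "f2_hz", 100)
  check_number(jitter_frac, "jitter_frac", 0, 0.2)
  check_number(sample_rate_hz, "sample_rate_hz", 4000)
  if (!(f1_hz < f2_hz && f2_hz < sample_rate_hz / 2)) {
    abort_validation("`f1_hz < f2_hz < sample_rate_hz/2` must hold", "f1_hz")
  }
  structure(
    list(f0_hz = f0_hz, f1_hz = f1_hz, f2_hz = f2_hz,
         jitter_frac = jitter_frac, sample_rate_hz = sample_rate_hz),
    class = "voice_params"
  )
}

#' Synthetic cohort specification
#'
#' Describes a remote-monitoring cohort to simulate: patients are followed
#' over monthly home-monitoring periods of about three consecutive days,
#' wearing a chest accelerometer + ECG sensor, with two hours per 24-hour
#' period set aside to recharge the device. Patient activity declines linearly
#' with study week, and patients may drop out between timepoints.
#'
#' @param n_patients Number of patients enrolled (all present at baseline).
#' @param n_timepoints Number of home-monitoring periods (default 13 monthly
#'   periods spanning 48 weeks).
#' @param days_per_period Protocol days of wear per period (default 3).
#' @param accel_rate_hz Accelerometer sampling rate, Hz (default 50).
#' @param baseline_active_min_per_day Baseline mean daytime active minutes per
#'   day (default 34, an ambulant but impaired cohort).
#' @param decline_fraction_48wk Fractional reduction of daily activity by week
#'   48, in `[0, 1]`; activity at week w is `1 - decline * w/48` of baseline.
#' @param dropout_hazard Per-transition probability that a patient leaves the
#'   study before the next timepoint.
#' @param adherence_model List with `wear_prob` (probability a protocol day is
#'   worn fully), `partial_prob` (probability a non-full day still yields a
#'   partial day of data), `charge_start_hr` and `charge_hours` (daily
#'   charging gap, default 02:00–04:00).
#' @param hrv_params An [rr_params()] object for the RR generator.
#' @param voice_params A [voice_params()] object for the speech synthesizer.
#' @param seed Integer seed; the whole cohort is deterministic given the seed.
#' @return A list of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_patients, n_timepoints = 13, days_per_period = 3,
                        accel_rate_hz = 50, baseline_active_min_per_day = 34,
                        decline_fraction_48wk = 0.33, dropout_hazard = 0.027,
                        adherence_model = list(), hrv_params = rr_params(),
                        voice_params = wearals::voice_params(), seed = 1L) {
  check_number(n_patients, "n_patients", 1)
  check_number(n_timepoints, "n_timepoints", 1)
  check_number(days_per_period, "days_per_period", 1)
  check_number(accel_rate_hz, "accel_rate_hz", 1e-9)
  check_number(baseline_active_min_per_day, "baseline_active_min_per_day", 0, 960)
  check_number(decline_fraction_48wk, "decline_fraction_48wk", 0, 1)
  check_number(dropout_hazard, "dropout_hazard", 0, 1)
  check_number(seed, "seed")
  adherence <- utils::modifyList(
    list(wear_prob = 0.9, partial_prob = 0.5, charge_start_hr = 2,
         charge_hours = 2),
    adherence_model
  )
  check_number(adherence$wear_prob, "adherence_model$wear_prob", 0, 1)
  check_number(adherence$partial_prob, "adherence_model$partial_prob", 0, 1)
  check_number(adherence$charge_start_hr, "adherence_model$charge_start_hr", 0, 24)
  check_number(adherence$charge_hours, "adherence_model$charge_hours", 0, 24)
  if (!inherits(hrv_params, "rr_params")) {
    abort_validation("`hrv_params` must be an rr_params() object", "hrv_params")
  }
  if (!inherits(voice_params, "voice_params")) {
    abort_validation("`voice_params` must be a voice_params() object", "voice_params")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_timepoints = as.integer(n_timepoints),
         days_per_period = as.integer(days_per_period),
         accel_rate_hz = accel_rate_hz,
         baseline_active_min_per_day = baseline_active_min_per_day,
         decline_fraction_48wk = decline_fraction_48wk,
         dropout_hazard = dropout_hazard,
         adherence_model = adherence,
         hrv_params = hrv_params,
         voice_params = voice_params,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' HRV data-sufficiency thresholds
#'
#' Minimum beat-time retention fraction of a 5-min RR window required before a
#' metric is computed: 0.88 for RMSSD and 0.99 for the LF/HF ratio by default,
#' reflecting the much greater sensitivity of frequency-domain metrics to
#' missing beats.
#'
#' @param rmssd_min_retention Retention needed for RMSSD (default 0.88).
#' @param lfhf_min_retention Retention needed for LF/HF (default 0.99); must be
#'   at least `rmssd_min_retention`.
#' @return A list of class `sufficiency_thresholds`.
#' @export
sufficiency_thresholds <- function(rmssd_min_retention = 0.88,
                                   lfhf_min_retention = 0.99) {
  check_number(rmssd_min_retention, "rmssd_min_retention", 1e-9, 1)
  check_number(lfhf_min_retention, "lfhf_min_retention", 1e-9, 1)
  if (lfhf_min_retention < rmssd_min_retention) {
    abort_validation(
      "`lfhf_min_retention` must be >= `rmssd_min_retention`",
      "lfhf_min_retention"
    )
  }
  structure(
    list(rmssd_min_retention = rmssd_min_retention,
         lfhf_min_retention = lfhf_min_retention),
    class = "sufficiency_thresholds"
  )
}
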