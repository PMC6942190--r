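test_that("parameter constructors validate their fields by name", {
  expect_error(rr_params(hf_freq_hz = 0.5), class = "wearals_validation_error")
  expect_error(rr_params(mean_rr_ms = 100), "mean_rr_ms")
  expect_error(voice_params(f1_hz = 1200, f2_hz = 900), "f1_hz")
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(2, decline_fraction_48wk = 1.2),
               "decline_fraction_48wk")
  expect_error(sufficiency_thresholds(0.9, 0.8), "lfhf_min_retention")
})

test_that("accel bout simulator reproduces task signatures", {
  # noiseless lying: constant gravity on the anterior-posterior axis
  ly <- simulate_accel_bout("lying down", 10, noise_sd_g = 0, seed = 1)
  expect_equal(sd(ly$ax_g), 0)
  expect_equal(sd(ly$ay_g), 0)
  expect_equal(sd(ly$az_g), 0)
  expect_equal(mean(ly$az_g), 1)

  # sitting with light noise: vector magnitude stays within 1% of 1 g
  sit <- simulate_accel_bout("sitting", 30, noise_sd_g = 0.005, seed = 2)
  vm <- sqrt(sit$ax_g^2 + sit$ay_g^2 + sit$az_g^2)
  expect_lt(abs(mean(vm) - 1), 0.01)

  # walking: dominant spectral peak of the high-pass-filtered magnitude in
  # the gait band, checked with an independent periodogram
  w <- simulate_accel_bout("walking", 60, seed = 3)
  bf <- signal::butter(4, 0.5 / 25, type = "high")
  vm <- sqrt(w$ax_g^2 + w$ay_g^2 + w$az_g^2)
  mag <- signal::filtfilt(bf, vm - mean(vm))
  pg <- stats::spec.pgram(stats::ts(mag, frequency = 50),
                          plot = FALSE, taper = 0)
  dom <- pg$freq[which.max(pg$spec)]
  expect_gte(dom, 1.5)
  expect_lte(dom, 2.5)

  # stairs carry more vertical movement than walking at matched settings
  st <- simulate_accel_bout("climbing stairs", 60, noise_sd_g = 0, seed = 3)
  w0 <- simulate_accel_bout("walking", 60, noise_sd_g = 0, seed = 3)
  expect_gt(sd(st$ay_g), sd(w0$ay_g))

  expect_error(simulate_accel_bout("jogging", 10), "supported tasks")
})

test_that("RR generator matches its construction and dropout statistics", {
  # all modulation and noise off: perfectly constant series at the mean,
  # with beat times the cumulative sum of RR values
  p0 <- rr_params(hf_amp_ms = 0, lf_amp_ms = 0, noise_sd_ms = 0)
  rr <- simulate_rr_series(60, p0, seed = 1)
  expect_true(all(rr$rr_ms == 800))
  expect_equal(rr$t_ms, cumsum(rr$rr_ms))

  # binomial oracle on the retained fraction: E = 1 - dropout, sd ~ sqrt(pq/n)
  pd <- rr_params(hf_amp_ms = 0, lf_amp_ms = 0, noise_sd_ms = 0,
                  dropout_prob = 0.2)
  big <- simulate_rr_series(8000, pd, seed = 2)
  n_gen <- attr(big, "n_generated")
  expect_gt(n_gen, 9000)
  retained <- nrow(big) / n_gen
  expect_lt(abs(retained - 0.8), 3 * sqrt(0.2 * 0.8 / n_gen) + 0.002)

  # determinism
  expect_identical(simulate_rr_series(120, rr_params(), seed = 7),
                   simulate_rr_series(120, rr_params(), seed = 7),
                   ignore_attr = TRUE)
})

test_that("speech synthesizer emits the protocol phonation patterns", {
  vp <- voice_params(sample_rate_hz = 16000)
  expect_equal(nrow(segment_voiced(synthesize_speech("AH_REPEATED", vp, seed = 1))), 7)
  expect_equal(nrow(segment_voiced(synthesize_speech("DOILY", vp, seed = 1))), 3)
  seg <- segment_voiced(synthesize_speech("AH_SUSTAINED", vp, seed = 1))
  expect_equal(nrow(seg), 1)
  expect_lt(abs((seg$end_s - seg$start_s) - 10), 0.1)
  # F0 of the waveform recovered by an independent whole-signal
  # autocorrelation oracle
  a <- synthesize_speech("AH_SUSTAINED", voice_params(jitter_frac = 0,
                                                      sample_rate_hz = 16000),
                         seed = 2)
  x <- a$samples[16000:(16000 + 8000)]
  ac <- stats::acf(x, lag.max = 400, plot = FALSE)$acf[-1]
  lag_range <- 16000 / c(400, 60)
  cand <- seq_len(400) >= lag_range[1] & seq_len(400) <= lag_range[2]
  lag <- which(cand)[which.max(ac[cand])]
  expect_lt(abs(16000 / lag - 120), 1)
  expect_error(synthesize_speech("HUM", vp), "supported")
})

test_that("cohort simulation is deterministic and honours dropout/decline", {
  spec <- cohort_spec(n_patients = 2, n_timepoints = 3, dropout_hazard = 0,
                      seed = 3)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$schedule, c2$schedule)
  # no dropout: every timepoint present for both patients
  expect_true(all(c1$manifest$present))

  # closed-form survival oracle: mean fraction contributing at timepoint 13
  # is (1 - h)^12 over replicate retention draws
  set.seed(42)
  frac <- replicate(10000, mean(simulate_retention(25, 13, 0.03) >= 13))
  mc_se <- sqrt(0.694 * 0.306 / (10000 * 25))
  expect_lt(abs(mean(frac) - (1 - 0.03)^12), 4 * mc_se + 1e-3)

  # dropped-out patients contribute no later sessions
  spec_d <- cohort_spec(n_patients = 12, n_timepoints = 6,
                        dropout_hazard = 0.3, seed = 9)
  cd <- simulate_cohort(spec_d, detail = "days")
  gone <- cd$manifest |>
    dplyr::left_join(cd$patients, by = "patient_id") |>
    dplyr::filter(.data$timepoint_id > .data$last_timepoint)
  expect_true(nrow(gone) > 0)
  expect_false(any(gone$present))
  expect_equal(nrow(dplyr::anti_join(cd$days,
                                     dplyr::filter(cd$manifest, present),
                                     by = c("patient_id", "timepoint_id"))), 0)
})

test_that("bout schedules conserve time and encode the programmed decline", {
  spec <- cohort_spec(n_patients = 4, n_timepoints = 2, days_per_period = 2,
                      decline_fraction_48wk = 0.4,
                      adherence_model = list(wear_prob = 1), seed = 21)
  coh <- simulate_cohort(spec)
  # conservation: scheduled bouts tile each full day minus the 2-h charge gap
  per_day <- coh$schedule |>
    dplyr::group_by(patient_id, timepoint_id, day_index) |>
    dplyr::summarise(total_s = sum(duration_s), .groups = "drop")
  expect_true(all(abs(per_day$total_s - (86400 - 7200)) < 1e-6))
  # no overlap within a day
  overlaps <- coh$schedule |>
    dplyr::group_by(patient_id, timepoint_id, day_index) |>
    dplyr::arrange(start_s, .by_group = TRUE) |>
    dplyr::summarise(bad = any(head(start_s + duration_s, -1) >
                                 tail(start_s, -1) + 1e-9), .groups = "drop")
  expect_false(any(overlaps$bad))
  # programmed decline: final-timepoint active share below baseline
  truth <- cohort_activity_truth(coh)
  base <- mean(truth$pct_daytime_active[truth$timepoint_id == 1])
  last <- mean(truth$pct_daytime_active[truth$timepoint_id == 2])
  expect_lt(last, base)
})
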