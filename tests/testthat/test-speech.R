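vp16 <- function(...) voice_params(sample_rate_hz = 16000, ...)

test_that("voiced segmentation handles silence, bursts and merging", {
  silence <- structure(list(samples = numeric(16000), sample_rate_hz = 16000),
                       class = "wearals_audio")
  expect_equal(nrow(segment_voiced(silence)), 0)

  expect_equal(nrow(segment_voiced(synthesize_speech("AH_REPEATED", vp16(), seed = 1))), 7)
  expect_equal(nrow(segment_voiced(synthesize_speech("DOILY", vp16(), seed = 1))), 3)

  # segments are ordered, non-overlapping, and conserve duration
  a <- synthesize_speech("BAMBOO", vp16(), seed = 2)
  seg <- segment_voiced(a)
  expect_true(all(diff(seg$start_s) > 0))
  expect_true(all(seg$end_s > seg$start_s))
  expect_lte(sum(seg$end_s - seg$start_s),
             length(a$samples) / a$sample_rate_hz)
})

test_that("F0 estimation recovers synthesis ground truth and rejects noise", {
  for (f0 in c(120, 220)) {
    a <- synthesize_speech("AH_SUSTAINED", vp16(f0_hz = f0, jitter_frac = 0),
                           sustain_s = 2, seed = 1)
    est <- estimate_f0(a)
    expect_lt(abs(est$f0_mean_hz - f0) / f0, 0.02, label = paste("f0", f0))
  }
  set.seed(2)
  noise <- structure(list(samples = rnorm(32000, 0, 0.3), sample_rate_hz = 16000),
                     class = "wearals_audio")
  est_n <- estimate_f0(noise)
  expect_gte(1 - est_n$voiced_fraction, 0.95)
})

test_that("formant estimation recovers F1/F2 within 5% with order preserved", {
  for (preset in list(c(700, 1100), c(300, 2300))) {
    a <- synthesize_speech("AH_SUSTAINED",
                           vp16(f1_hz = preset[1], f2_hz = preset[2]),
                           sustain_s = 2, seed = 3)
    fm <- estimate_formants(a)
    expect_false(fm$flagged)
    expect_lt(abs(fm$f1_hz - preset[1]) / preset[1], 0.05)
    expect_lt(abs(fm$f2_hz - preset[2]) / preset[2], 0.05)
    expect_lt(fm$f1_hz, fm$f2_hz)
  }
  set.seed(4)
  burst <- structure(list(samples = rnorm(1600, 0, 1e-6), sample_rate_hz = 16000),
                     class = "wearals_audio")
  expect_true(estimate_formants(burst)$flagged)
})

test_that("F0 and formants recover across a parameter grid", {
  presets <- list(c(500, 1500), c(700, 1100), c(300, 2300))
  grid <- tidyr::expand_grid(f0 = c(100, 150, 200, 250, 300), p = 1:3)
  ok <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pr <- presets[[grid$p[i]]]
    a <- synthesize_speech("AH_SUSTAINED",
                           vp16(f0_hz = grid$f0[i], f1_hz = pr[1],
                                f2_hz = pr[2], jitter_frac = 0.002),
                           sustain_s = 1.5, seed = i)
    f <- extract_speech_features(a, "AH_SUSTAINED")
    ok[i] <- !is.na(f$f0_mean_hz) &&
      abs(f$f0_mean_hz - grid$f0[i]) / grid$f0[i] <= 0.02 &&
      !is.na(f$f1_hz) && abs(f$f1_hz - pr[1]) / pr[1] <= 0.05 &&
      abs(f$f2_hz - pr[2]) / pr[2] <= 0.05
  }
  expect_gte(mean(ok), 0.95)
})

test_that("per-test endpoint extraction follows each protocol", {
  # sustained: 10-s phonation recovered within 0.1 s
  a <- synthesize_speech("AH_SUSTAINED", vp16(), seed = 5)
  f <- extract_speech_features(a, "AH_SUSTAINED")
  expect_lt(abs(f$max_phonation_time_s - 10), 0.1)
  expect_false(f$protocol_deviation)
  expect_lte(f$max_phonation_time_s, f$total_duration_s)

  # repeated-Ah with only 6 bursts: deviation flag set
  a6 <- synthesize_speech("AH_REPEATED", vp16(), n_bursts = 6, seed = 6)
  expect_true(extract_speech_features(a6, "AH_REPEATED")$protocol_deviation)

  # passage: 40 syllables over ~20 s phonated -> rate 2.0 +/- 10%
  ab <- synthesize_speech("BAMBOO", vp16(), n_syllables = 40, seed = 7)
  fb <- extract_speech_features(ab, "BAMBOO")
  expect_lt(abs(fb$speaking_rate_sps - 2) / 2, 0.1)
  expect_equal(fb$pause_count, 4L)

  expect_error(extract_speech_features(a, "SONG"), "supported")
})

test_that("features are invariant to positive amplitude scaling", {
  a <- synthesize_speech("DOILY", vp16(), seed = 8)
  half <- structure(list(samples = a$samples * 0.35,
                         sample_rate_hz = a$sample_rate_hz),
                    class = "wearals_audio")
  f1 <- extract_speech_features(a, "DOILY")
  f2 <- extract_speech_features(half, "DOILY")
  expect_equal(f1$n_segments, f2$n_segments)
  expect_equal(f1$max_phonation_time_s, f2$max_phonation_time_s)
  expect_equal(f1$f0_mean_hz, f2$f0_mean_hz, tolerance = 1e-6)
})
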