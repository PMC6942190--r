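test_that("RR cleaning applies the physiological and jump rules", {
  s <- tibble::tibble(t_ms = cumsum(c(800, 150, 800, 800)),
                      rr_ms = c(800, 150, 800, 800))
  out <- clean_rr(s)
  expect_equal(nrow(out$series), 3)
  expect_match(out$rejections$reason, "below physiological floor")

  # clean constant series unchanged
  cs <- constant_rr_window()
  expect_equal(nrow(clean_rr(cs)$rejections), 0)
  expect_equal(clean_rr(cs)$series, cs)

  # 800,800,1200,800: the 50% jump is removed
  j <- tibble::tibble(t_ms = cumsum(c(800, 800, 1200, 800)),
                      rr_ms = c(800, 800, 1200, 800))
  outj <- clean_rr(j)
  expect_equal(outj$rejections$rr_ms, 1200)
  expect_match(outj$rejections$reason, "jump")

  # above-ceiling beats are rejected too
  expect_match(clean_rr(tibble::tibble(t_ms = 2500, rr_ms = 2500))$rejections$reason,
               "ceiling")
})

test_that("window retention tracks beat-time coverage and drives flags", {
  cs <- constant_rr_window()
  w <- window_rr(cs)
  expect_equal(w$retention, 1)
  expect_true(w$sufficient_rmssd)
  expect_true(w$sufficient_lfhf)

  # ~10% of beats deleted: retention ~0.9, RMSSD ok, LF/HF insufficient
  set.seed(8)
  dropped <- cs[runif(nrow(cs)) > 0.10, ]
  wd <- window_rr(dropped)
  expect_lt(abs(wd$retention - 0.9), 0.05)
  expect_true(wd$sufficient_rmssd)
  expect_false(wd$sufficient_lfhf)

  # empty window: retention 0, both flags false
  we <- window_rr(cs[0, ], span_ms = c(0, 300000))
  expect_equal(we$retention, 0)
  expect_false(we$sufficient_rmssd)
  expect_false(we$sufficient_lfhf)
})

test_that("RMSSD matches its closed forms and a brute-force oracle", {
  cs <- constant_rr_window()
  expect_equal(rmssd(cs$t_ms, cs$rr_ms), 0)

  # alternating 800, 850: every successive difference is +/-50 -> RMSSD 50
  alt <- tibble::tibble(rr_ms = rep(c(800, 850), 180))
  alt$t_ms <- cumsum(alt$rr_ms)
  expect_equal(rmssd(alt$t_ms, alt$rr_ms), 50)

  # 1000 random complete windows: equal to the direct formula within 1e-9
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(50:400, 1)
    rr <- runif(n, 700, 900)  # variation below the gap-exclusion factor
    t <- cumsum(rr)
    oracle <- sqrt(mean(diff(rr)^2))
    expect_equal(rmssd(t, rr), oracle, tolerance = 1e-12)
  }

  # adding a constant to all RR values leaves RMSSD unchanged
  set.seed(12)
  rr <- runif(200, 700, 850)
  t <- cumsum(rr)
  expect_equal(rmssd(t, rr), rmssd(t + 0, rr + 100), tolerance = 1e-9)

  # too few beats: absent with a reason
  out <- rmssd(c(800, 1600), c(800, 800))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "fewer beats")
})

test_that("gap-bridging exclusion stops deleted beats inflating RMSSD", {
  cs <- constant_rr_window()
  # delete a block of beats: the bridging pair spans > 2x median RR
  holed <- cs[-(100:140), ]
  expect_equal(rmssd(holed$t_ms, holed$rr_ms), 0)  # still constant elsewhere
})

test_that("LF/HF separates pure low- and high-frequency modulation", {
  lf_only <- modulated_rr_window(0.10)
  r_lf <- lf_hf(lf_only$t_ms, lf_only$rr_ms)
  expect_gt(r_lf$lf_hf_ratio, 5)

  hf_only <- modulated_rr_window(0.25)
  r_hf <- lf_hf(hf_only$t_ms, hf_only$rr_ms)
  expect_lt(r_hf$lf_hf_ratio, 0.2)

  # cross-check the Lomb route against interpolation + Welch-style FFT on a
  # complete window: band dominance must agree
  interp_ratio <- function(w) {
    g <- seq(min(w$t_ms), max(w$t_ms), by = 250)  # 4 Hz resampling
    y <- stats::approx(w$t_ms, w$rr_ms, xout = g)$y
    sp <- stats::spec.pgram(stats::ts(y - mean(y), frequency = 4), plot = FALSE,
                            taper = 0.1)
    lf <- sum(sp$spec[sp$freq >= 0.04 & sp$freq < 0.15])
    hf <- sum(sp$spec[sp$freq >= 0.15 & sp$freq <= 0.40])
    lf / hf
  }
  expect_gt(interp_ratio(lf_only), 1)
  expect_lt(interp_ratio(hf_only), 1)

  # white-noise RR: both bands positive, ratio near 1 most of the time
  set.seed(13)
  ratios <- replicate(60, {
    rr <- 800 + rnorm(380, 0, 20)
    t <- cumsum(rr)
    keep <- t <= 300000
    lf_hf(t[keep], rr[keep])$lf_hf_ratio
  })
  expect_true(all(is.finite(ratios)))
  expect_gte(mean(ratios > 0.2 & ratios < 5), 0.95)

  # degenerate window: zero HF power flagged, ratio absent
  const <- constant_rr_window()
  r0 <- lf_hf(const$t_ms, const$rr_ms)
  expect_true(r0$degenerate || r0$lf_hf_ratio < 1e-3 || is.na(r0$lf_hf_ratio))
})

test_that("hrv_metrics computes only where sufficiency flags allow", {
  rr <- simulate_rr_series(910, rr_params(noise_sd_ms = 8), seed = 14)
  set.seed(15)
  degraded <- rr[runif(nrow(rr)) > 0.15, ]  # ~85% retention: neither metric
  w <- hrv_metrics(window_rr(degraded))
  expect_true(all(is.na(w$rmssd_ms[!w$sufficient_rmssd])))
  expect_true(all(is.na(w$lf_hf_ratio[!w$sufficient_lfhf])))
  full <- hrv_metrics(window_rr(rr))
  expect_true(all(!is.na(full$rmssd_ms[full$sufficient_rmssd])))
})

test_that("windows stratify by majority activity class with exact accounting", {
  rr <- simulate_rr_series(1510, rr_params(), seed = 16)
  wins <- hrv_metrics(window_rr(rr))
  # 3 lying + 2 active minutes in window 1 -> lying
  ml <- tibble::tibble(
    epoch_start_ms = (0:29) * 60000,
    class = c(c("lying", "lying", "lying", "active", "active"),
              rep("active", 25))
  )
  hb <- hrv_by_activity(wins, ml)
  expect_equal(hb$windows$activity_class[1], "lying")
  expect_true(all(hb$windows$activity_class[-1] == "active"))
  expect_equal(sum(hb$summary$n_windows), nrow(wins))

  # all lying -> a single stratum
  ml2 <- dplyr::mutate(ml, class = "lying")
  expect_equal(hrv_by_activity(wins, ml2)$summary$activity_class, "lying")

  # sufficiency accounting reproducible from the flags alone
  s <- sufficiency_summary(wins)
  expect_equal(s$pct_sufficient_rmssd, 100 * mean(wins$sufficient_rmssd))
  expect_equal(s$pct_sufficient_lfhf, 100 * mean(wins$sufficient_lfhf))
})
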