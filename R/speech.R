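# Acoustic feature extraction for the four in-clinic speech tests.

.frame_energy <- function(x, fs, frame_ms = 25, hop_ms = 10) {
  frame <- max(2L, round(fs * frame_ms / 1000))
  hop <- max(1L, round(fs * hop_ms / 1000))
  starts <- seq(1, max(1, length(x) - frame + 1), by = hop)
  e <- vapply(starts, function(s) mean(x[s:(s + frame - 1)]^2), numeric(1))
  tibble(start_s = (starts - 1) / fs, energy = e)
}

#' Segment voiced (supra-threshold) regions of a recording
#'
#' Frame energies are compared against an adaptive threshold set
#' `energy_floor_db` below the recording's 95th-percentile frame energy;
#' supra-threshold frames are merged into segments, gaps shorter than
#' `min_gap_ms` are bridged, and segments shorter than `min_seg_ms` dropped.
#' An all-silent recording yields an empty segment list, not an error.
#'
#' @param audio A `wearals_audio` object.
#' @param frame_ms,hop_ms Analysis frame and hop, ms.
#' @param energy_floor_db Threshold below the 95th-percentile frame energy,
#'   dB (default -25).
#' @param min_seg_ms Minimum segment length, ms.
#' @param min_gap_ms Gaps shorter than this are merged, ms.
#' @return Tibble `start_s, end_s, mean_energy_db` (dB rel. full scale),
#'   time-ordered and non-overlapping.
#' @export
segment_voiced <- function(audio, frame_ms = 25, hop_ms = 10,
                           energy_floor_db = -25, min_seg_ms = 100,
                           min_gap_ms = 150) {
  fs <- audio$sample_rate_hz
  fe <- .frame_energy(audio$samples, fs, frame_ms, hop_ms)
  ref <- quantile(fe$energy, 0.95, names = FALSE)
  if (ref <= 1e-12) {
    return(tibble(start_s = numeric(), end_s = numeric(),
                  mean_energy_db = numeric()))
  }
  thr <- ref * 10^(energy_floor_db / 10)
  on <- fe$energy > thr
  if (!any(on)) {
    return(tibble(start_s = numeric(), end_s = numeric(),
                  mean_energy_db = numeric()))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  seg <- tibble(
    start_s = fe$start_s[starts[r$values]],
    end_s = fe$start_s[ends[r$values]] + frame_ms / 1000
  )
  # merge gaps < min_gap_ms
  if (nrow(seg) > 1) {
    merged <- seg[1, ]
    for (i in 2:nrow(seg)) {
      last <- nrow(merged)
      if ((seg$start_s[i] - merged$end_s[last]) * 1000 < min_gap_ms) {
        merged$end_s[last] <- seg$end_s[i]
      } else merged <- bind_rows(merged, seg[i, ])
    }
    seg <- merged
  }
  seg <- seg |> filter((.data$end_s - .data$start_s) * 1000 >= min_seg_ms)
  seg$mean_energy_db <- vapply(seq_len(nrow(seg)), function(i) {
    idx <- fe$start_s >= seg$start_s[i] & fe$start_s < seg$end_s[i]
    10 * log10(mean(fe$energy[idx]))
  }, numeric(1))
  seg
}

.audio_slice <- function(audio, start_s, end_s) {
  fs <- audio$sample_rate_hz
  i0 <- max(1L, floor(start_s * fs) + 1L)
  i1 <- min(length(audio$samples), ceiling(end_s * fs))
  structure(list(samples = audio$samples[i0:i1], sample_rate_hz = fs),
            class = "wearals_audio")
}

#' Estimate fundamental frequency by autocorrelation
#'
#' Per-frame normalised autocorrelation with the peak searched within
#' `[fmin, fmax]` and refined by parabolic interpolation; frames whose
#' autocorrelation peak falls below the voicing threshold are treated as
#' unvoiced. Returns per-frame estimates and the voiced-frame summary.
#'
#' @param audio A `wearals_audio` (typically one voiced segment).
#' @param fmin,fmax F0 search range, Hz.
#' @param frame_ms,hop_ms Analysis frame and hop, ms.
#' @param voicing_threshold Minimum normalised autocorrelation peak (default
#'   0.5).
#' @return List: `frames` (tibble `t_s, f0_hz, clarity, voiced`), `f0_mean_hz`,
#'   `f0_sd_hz`, `voiced_fraction`; the means are `NA` (flagged by
#'   `voiced_fraction`) when no periodicity is found.
#' @export
estimate_f0 <- function(audio, fmin = 60, fmax = 400, frame_ms = 40,
                        hop_ms = 10, voicing_threshold = 0.5) {
  fs <- audio$sample_rate_hz
  x <- audio$samples
  frame <- round(fs * frame_ms / 1000)
  hop <- max(1L, round(fs * hop_ms / 1000))
  lag_min <- max(2L, floor(fs / fmax))
  lag_max <- min(frame - 2L, ceiling(fs / fmin))
  if (lag_max <= lag_min || length(x) < frame) {
    return(list(frames = tibble(t_s = numeric(), f0_hz = numeric(),
                                clarity = numeric(), voiced = logical()),
                f0_mean_hz = NA_real_, f0_sd_hz = NA_real_,
                voiced_fraction = 0))
  }
  starts <- seq(1, length(x) - frame + 1, by = hop)
  rows <- lapply(starts, function(s) {
    seg <- x[s:(s + frame - 1)]
    seg <- seg - mean(seg)
    if (sum(seg^2) < 1e-10) {
      return(tibble(t_s = (s - 1) / fs, f0_hz = NA_real_, clarity = 0,
                    voiced = FALSE))
    }
    # center clipping whitens formant ringing so the autocorrelation is
    # dominated by the pitch periodicity, not vocal-tract resonance
    clip <- 0.4 * max(abs(seg))
    seg <- sign(seg) * pmax(abs(seg) - clip, 0)
    e0 <- sum(seg^2)
    if (e0 < 1e-12) {
      return(tibble(t_s = (s - 1) / fs, f0_hz = NA_real_, clarity = 0,
                    voiced = FALSE))
    }
    ac <- vapply(lag_min:lag_max, function(l) {
      sum(seg[1:(frame - l)] * seg[(l + 1):frame])
    }, numeric(1)) / e0
    # subharmonic correction: take the smallest-lag local peak within 90% of
    # the global peak, so a period multiple is not mistaken for the period
    pk <- which(diff(sign(diff(c(-Inf, ac, -Inf)))) == -2)
    pk <- pk[ac[pk] >= 0.9 * max(ac)]
    k <- if (length(pk)) pk[1] else which.max(ac)
    clarity <- ac[k]
    lag <- lag_min + k - 1
    # parabolic interpolation around the peak
    if (k > 1 && k < length(ac)) {
      a <- ac[k - 1]; b <- ac[k]; c <- ac[k + 1]
      denom <- a - 2 * b + c
      if (abs(denom) > 1e-12) lag <- lag + 0.5 * (a - c) / denom
    }
    tibble(t_s = (s - 1) / fs, f0_hz = fs / lag, clarity = clarity,
           voiced = clarity >= voicing_threshold)
  })
  frames <- list_rbind(rows)
  voiced <- frames |> filter(.data$voiced)
  # summary over voiced frames, discarding octave-error outliers (frames more
  # than 20% away from the median track)
  if (nrow(voiced)) {
    med <- median(voiced$f0_hz)
    trk <- voiced$f0_hz[abs(voiced$f0_hz - med) <= 0.2 * med]
  } else trk <- numeric()
  list(
    frames = frames,
    f0_mean_hz = if (length(trk)) mean(trk) else NA_real_,
    f0_sd_hz = if (length(trk) > 1) sd(trk) else NA_real_,
    voiced_fraction = nrow(voiced) / nrow(frames)
  )
}

#' Estimate the first two formants by linear predictive coding
#'
#' The segment is decimated to about 8 kHz (F1/F2 live well below 4 kHz) and
#' lightly pre-emphasized; an LPC polynomial (default order 6 = two poles per
#' sought formant plus two for source tilt) is then fit to the
#' harmonic-suppressed spectral envelope — the Hamming-windowed periodogram
#' smoothed by a running median wider than one pitch-harmonic spacing, turned
#' back into an autocorrelation sequence. Fitting the envelope rather than the
#' raw waveform stops poles locking onto individual pitch harmonics at high
#' F0. Resonant pole root angles with bandwidth under `max_bandwidth_hz` are
#' the formant candidates; candidates are ranked by the LPC spectral-envelope
#' height at the pole frequency so weak computational poles are not mistaken
#' for resonances, and the retained candidates are returned sorted ascending.
#' Segments with no detectable periodicity (normalised autocorrelation peak
#' below `voicing_threshold` in the pitch range) are flagged rather than
#' analysed.
#'
#' @param audio A `wearals_audio` (one voiced vowel segment).
#' @param lpc_order LPC order; `NULL` (default) uses `2 + 2 * n_formants`.
#' @param n_formants Number of formants sought (fixed at 2 here).
#' @param max_bandwidth_hz Maximum pole bandwidth to count as a formant.
#' @param target_fs_hz Decimation target rate (default 8000).
#' @param preemphasis First-difference pre-emphasis coefficient.
#' @param median_hz Width of the harmonic-suppressing running median, Hz;
#'   should exceed the largest expected F0.
#' @param voicing_threshold Minimum autocorrelation peak for the segment to
#'   count as voiced.
#' @return One-row tibble `f1_hz, f2_hz, n_poles, flagged` (`flagged = TRUE`
#'   with `NA` formants when the segment is unvoiced or fewer than two
#'   qualifying poles are found).
#' @export
estimate_formants <- function(audio, lpc_order = NULL, n_formants = 2,
                              max_bandwidth_hz = 400, target_fs_hz = 8000,
                              preemphasis = 0.5, median_hz = 380,
                              voicing_threshold = 0.25) {
  fs <- audio$sample_rate_hz
  x <- audio$samples
  dec <- max(1L, round(fs / target_fs_hz))
  if (dec > 1) {
    x <- signal::decimate(x, dec)
    fs <- fs / dec
  }
  x <- x - mean(x)
  flagged <- tibble(f1_hz = NA_real_, f2_hz = NA_real_, n_poles = 0L,
                    flagged = TRUE)
  if (length(x) < 64 || sd(x) < 1e-8) return(flagged)
  # periodicity gate: unvoiced noise has no autocorrelation peak at pitch lags
  lag_rng <- max(2L, floor(fs / 400)):min(length(x) - 2L, ceiling(fs / 60))
  e0 <- sum(x^2)
  ac <- vapply(lag_rng, function(l) {
    sum(x[1:(length(x) - l)] * x[(l + 1):length(x)])
  }, numeric(1)) / e0
  if (max(ac) < voicing_threshold) return(flagged)

  if (preemphasis > 0) x <- c(x[1], x[-1] - preemphasis * x[-length(x)])
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(n) / (n + 1))
  pspec <- Mod(fft(x * w))^2
  half <- floor(n / 2)
  df <- fs / n
  kmed <- max(3, 2 * floor(median_hz / df / 2) + 1)
  kmed <- min(kmed, 2 * floor((half - 1) / 2) + 1)
  psm <- stats::runmed(pspec[1:half], kmed)
  pfull <- c(psm, rev(psm))
  if (length(pfull) < n) pfull <- append(pfull, psm[half], after = half)
  pfull <- pfull[1:n]
  r <- Re(fft(pfull, inverse = TRUE))[1:(half)] / n
  p <- lpc_order %||% (2L + 2L * n_formants)
  a <- tryCatch(solve(toeplitz(r[1:p]), r[2:(p + 1)]),
                error = function(e) NULL)
  if (is.null(a)) return(flagged)
  roots <- polyroot(c(1, -a))
  f <- Arg(roots) * fs / (2 * pi)
  bw <- -fs / pi * log(pmin(Mod(roots), 0.999999))
  keep <- which(f > 90 & f < fs / 2 - 100 & bw < max_bandwidth_hz)
  if (length(keep) < n_formants) {
    flagged$n_poles <- length(keep)
    return(flagged)
  }
  env_height <- vapply(f[keep], function(fq) {
    1 / abs(1 - sum(a * exp(-1i * 2 * pi * fq * seq_len(p) / fs)))
  }, numeric(1))
  top <- keep[order(env_height, decreasing = TRUE)][seq_len(n_formants)]
  cand <- sort(f[top])
  tibble(f1_hz = cand[1], f2_hz = cand[2], n_poles = length(keep),
         flagged = FALSE)
}

# syllable nuclei: local maxima of the smoothed amplitude envelope separated
# by a true inter-syllable valley (envelope dipping below half the smaller of
# the two neighbouring peaks), so within-syllable ripple is not counted
.count_syllables <- function(audio, segments, hop_ms = 10, smooth_ms = 80,
                             height_frac = 0.15, valley_frac = 0.5) {
  fe <- .frame_energy(audio$samples, audio$sample_rate_hz, 25, hop_ms)
  env <- sqrt(fe$energy)
  k <- max(1L, round(smooth_ms / hop_ms))
  sm <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  in_seg <- rep(FALSE, length(sm))
  for (i in seq_len(nrow(segments))) {
    in_seg <- in_seg | (fe$start_s >= segments$start_s[i] &
                          fe$start_s <= segments$end_s[i])
  }
  thr <- height_frac * quantile(sm[in_seg], 0.95, names = FALSE)
  peaks <- which(diff(sign(diff(sm))) == -2) + 1
  peaks <- peaks[in_seg[peaks] & sm[peaks] > thr]
  if (length(peaks) < 2) return(length(peaks))
  counted <- peaks[1]
  for (p in peaks[-1]) {
    prev <- counted[length(counted)]
    valley <- min(sm[prev:p])
    if (valley < valley_frac * min(sm[prev], sm[p])) {
      counted <- c(counted, p)
    } else if (sm[p] > sm[prev]) {
      counted[length(counted)] <- p  # keep the higher of an unseparated pair
    }
  }
  length(counted)
}

#' Extract the acoustic endpoint set for one speech test
#'
#' Dispatches on the test protocol: `AH_SUSTAINED` reports the maximum
#' phonation time (longest voiced segment) with F0 and F1/F2 measured on it;
#' `AH_REPEATED` reports the segment count (protocol expectation 7) and mean
#' per-segment F0; `DOILY` the segment count (expectation 3) and mean segment
#' duration; `BAMBOO` the total duration, pause count (inter-segment gaps
#' longer than `pause_ms`) and speaking rate (envelope syllable nuclei per
#' phonated second). A protocol-deviation flag is set when the observed
#' segment count differs from the test's expectation.
#'
#' @param audio A `wearals_audio` recording of the test.
#' @param test Test id; see [speech_tests()].
#' @param pause_ms Pause threshold for the passage, ms (default 300).
#' @param ... Passed to [segment_voiced()].
#' @return One-row tibble: `test`, `n_segments`, `total_duration_s`,
#'   `max_phonation_time_s`, `f0_mean_hz`, `f0_sd_hz`, `f1_hz`, `f2_hz`,
#'   `mean_segment_s`, `speaking_rate_sps`, `pause_count`,
#'   `protocol_deviation`.
#' @export
extract_speech_features <- function(audio, test, pause_ms = 300, ...) {
  check_speech_test(test)
  seg <- segment_voiced(audio, ...)
  n_seg <- nrow(seg)
  durs <- seg$end_s - seg$start_s
  total <- length(audio$samples) / audio$sample_rate_hz
  out <- tibble(
    test = test, n_segments = n_seg, total_duration_s = total,
    max_phonation_time_s = if (n_seg) max(durs) else 0,
    f0_mean_hz = NA_real_, f0_sd_hz = NA_real_,
    f1_hz = NA_real_, f2_hz = NA_real_,
    mean_segment_s = if (n_seg) mean(durs) else NA_real_,
    speaking_rate_sps = NA_real_, pause_count = NA_integer_,
    protocol_deviation = FALSE
  )
  expect <- expected_segments(test)
  if (!is.na(expect)) out$protocol_deviation <- n_seg != expect
  if (!n_seg) return(out)

  if (test %in% c("AH_SUSTAINED", "AH_REPEATED", "DOILY")) {
    longest <- which.max(durs)
    sl <- .audio_slice(audio, seg$start_s[longest], seg$end_s[longest])
    f0 <- estimate_f0(sl)
    out$f0_mean_hz <- f0$f0_mean_hz
    out$f0_sd_hz <- f0$f0_sd_hz
    if (test != "DOILY") {
      fm <- estimate_formants(sl)
      out$f1_hz <- fm$f1_hz
      out$f2_hz <- fm$f2_hz
    }
  }
  if (test == "AH_REPEATED" && n_seg > 1) {
    # mean per-segment F0 across repetitions
    f0s <- vapply(seq_len(n_seg), function(i) {
      estimate_f0(.audio_slice(audio, seg$start_s[i], seg$end_s[i]))$f0_mean_hz
    }, numeric(1))
    out$f0_mean_hz <- mean(f0s, na.rm = TRUE)
  }
  if (test == "BAMBOO") {
    gaps <- if (n_seg > 1) (seg$start_s[-1] - seg$end_s[-n_seg]) * 1000 else numeric()
    out$pause_count <- sum(gaps > pause_ms)
    n_syll <- .count_syllables(audio, seg)
    phonated <- sum(durs)
    out$speaking_rate_sps <- if (phonated > 0) n_syll / phonated else NA_real_
  }
  out
}
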