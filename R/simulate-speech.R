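# Source-filter speech synthesis for the four in-clinic speech tests.

.speech_tests <- c("AH_REPEATED", "AH_SUSTAINED", "DOILY", "BAMBOO")

#' Speech test identifiers
#'
#' The four in-clinic speech tests: a short "Ah" repeated 7 times
#' (`AH_REPEATED`), a 10-second sustained "Ah" (`AH_SUSTAINED`), the word
#' "doily" pronounced 3 times (`DOILY`), and a read ~100-word passage
#' (`BAMBOO`).
#'
#' @return Character vector of test ids.
#' @export
speech_tests <- function() .speech_tests

#' Expected number of voiced segments per speech test
#'
#' Protocol expectations used to flag deviations: 7 phonations for
#' `AH_REPEATED`, 1 for `AH_SUSTAINED`, 3 for `DOILY`; the passage has no
#' fixed expectation (`NA`).
#'
#' @param test Test id.
#' @return Integer (or `NA` for `BAMBOO`).
#' @export
expected_segments <- function(test) {
  check_speech_test(test)
  switch(test, AH_REPEATED = 7L, AH_SUSTAINED = 1L, DOILY = 3L, BAMBOO = NA_integer_)
}

check_speech_test <- function(test) {
  if (!is.character(test) || length(test) != 1L || !test %in% .speech_tests) {
    abort_validation(
      paste0("unknown speech test ", deparse(test), "; supported: ",
             paste(.speech_tests, collapse = ", ")),
      field = "test"
    )
  }
  invisible(test)
}

# impulse train at f0 with per-cycle jitter, through two 2nd-order resonators
# at f1 and f2 (bandwidth `bw_hz`), plus an aspiration-noise floor that keeps
# the spectral envelope observable between harmonics
.voiced_source_filter <- function(dur_s, vp, bw_hz = 130, noise_floor = 0.05) {
  fs <- vp$sample_rate_hz
  n <- max(1L, round(dur_s * fs))
  x <- numeric(n)
  # fractional impulse placement (energy split over adjacent samples) keeps
  # the period exact; integer rounding would alias high F0 into subharmonics
  pos <- 1
  while (pos <= n) {
    i0 <- floor(pos); frac <- pos - i0
    x[i0] <- x[i0] + (1 - frac)
    if (i0 + 1 <= n) x[i0 + 1] <- x[i0 + 1] + frac
    period <- fs / vp$f0_hz
    if (vp$jitter_frac > 0) period <- period * (1 + rnorm(1, 0, vp$jitter_frac))
    pos <- pos + max(2, period)
  }
  if (noise_floor > 0) x <- x + rnorm(n, 0, noise_floor)
  for (f in c(vp$f1_hz, vp$f2_hz)) {
    r <- exp(-pi * bw_hz / fs)
    th <- 2 * pi * f / fs
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r^2), method = "recursive"))
  }
  x / max(abs(x)) * 0.5
}

.fade <- function(x, fs, ms = 25) {
  k <- min(length(x), max(2L, round(fs * ms / 1000)))
  ramp <- (1 - cos(pi * seq_len(k) / k)) / 2
  x[seq_len(k)] <- x[seq_len(k)] * ramp
  x[(length(x) - k + 1):length(x)] <- x[(length(x) - k + 1):length(x)] * rev(ramp)
  x
}

.silence <- function(dur_s, fs) numeric(round(dur_s * fs))

#' Synthesize audio for one speech test
#'
#' Source-filter synthesis of the test's phonation pattern: an impulse train at
#' the fundamental frequency passed through resonators at the first two
#' formants, gated by the test's burst/pause envelope. `AH_REPEATED` emits
#' exactly 7 bursts separated by at least 300 ms of silence; `AH_SUSTAINED` one
#' 10-s phonation; `DOILY` 3 two-syllable word bursts; `BAMBOO` a train of
#' `n_syllables` syllable bursts grouped into phrases with inter-phrase pauses.
#' The passage is abstract syllable bursts, not intelligible text: downstream
#' features depend only on envelope, F0 and formants.
#'
#' @param test Test id; see [speech_tests()].
#' @param params A [voice_params()] object (ground truth for recovery tests).
#' @param n_syllables Syllable count for `BAMBOO` (default 40).
#' @param sustain_s Phonation duration for `AH_SUSTAINED`, seconds.
#' @param n_bursts Burst count for `AH_REPEATED`/`DOILY` (defaults to the
#'   protocol expectation; set differently to synthesize protocol deviations).
#' @param seed Optional seed.
#' @return List of class `wearals_audio` with `samples` (numeric in \[-1, 1\])
#'   and `sample_rate_hz`.
#' @examples
#' a <- synthesize_speech("AH_SUSTAINED", voice_params(sample_rate_hz = 16000), seed = 1)
#' @export
synthesize_speech <- function(test, params = voice_params(), n_syllables = 40,
                              sustain_s = 10, n_bursts = NULL, seed = NULL) {
  check_speech_test(test)
  if (!inherits(params, "voice_params")) {
    abort_validation("`params` must be a voice_params() object", "params")
  }
  fs <- params$sample_rate_hz
  with_seed(seed, {
    pieces <- list(.silence(0.25, fs))
    if (test == "AH_SUSTAINED") {
      pieces <- c(pieces, list(.fade(.voiced_source_filter(sustain_s, params), fs)))
    } else if (test == "AH_REPEATED") {
      nb <- n_bursts %||% 7L
      for (i in seq_len(nb)) {
        pieces <- c(pieces, list(.fade(.voiced_source_filter(0.8, params), fs)))
        if (i < nb) pieces <- c(pieces, list(.silence(0.5, fs)))
      }
    } else if (test == "DOILY") {
      nb <- n_bursts %||% 3L
      for (i in seq_len(nb)) {
        # two syllables separated by a short intra-word dip (< merge gap)
        pieces <- c(pieces,
                    list(.fade(.voiced_source_filter(0.28, params), fs)),
                    list(.silence(0.08, fs)),
                    list(.fade(.voiced_source_filter(0.22, params), fs)))
        if (i < nb) pieces <- c(pieces, list(.silence(0.6, fs)))
      }
    } else if (test == "BAMBOO") {
      check_number(n_syllables, "n_syllables", 1)
      per_phrase <- 8L
      k <- 0L
      while (k < n_syllables) {
        m <- min(per_phrase, n_syllables - k)
        for (j in seq_len(m)) {
          pieces <- c(pieces, list(.fade(.voiced_source_filter(0.42, params), fs, ms = 15)))
          if (j < m) pieces <- c(pieces, list(.silence(0.08, fs)))
        }
        k <- k + m
        if (k < n_syllables) pieces <- c(pieces, list(.silence(0.7, fs)))
      }
    }
    pieces <- c(pieces, list(.silence(0.25, fs)))
    structure(
      list(samples = unlist(pieces, use.names = FALSE), sample_rate_hz = fs),
      class = "wearals_audio"
    )
  })
}

#' @export
print.wearals_audio <- function(x, ...) {
  cat(sprintf("<wearals_audio: %.2f s at %d Hz>\n",
              length(x$samples) / x$sample_rate_hz, as.integer(x$sample_rate_hz)))
  invisible(x)
}
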