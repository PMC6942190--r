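# Minimal 16-bit PCM mono RIFF/WAV reader and writer. Audio capture is
# stipulated to this one container; compressed or multi-channel WAV is
# rejected rather than converted.

#' Read / write 16-bit PCM mono WAV audio
#'
#' `write_wav()` clips samples to \[-1, 1\] and quantizes to 16-bit PCM;
#' `read_wav()` accepts only uncompressed 16-bit mono files and returns samples
#' rescaled to \[-1, 1\].
#'
#' @param path File path.
#' @return `read_wav()`: a `wearals_audio` list (`samples`, `sample_rate_hz`).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "wearals_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- rawToChar(readBin(con, "raw", 4))
  if (riff != "RIFF" || wave != "WAVE") {
    abort(paste0("format error in ", path, ": not a RIFF/WAVE file"),
          class = "wearals_format_error")
  }
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    id <- rawToChar(id)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) {
        abort(paste0("format error in ", path, ": only PCM (format 1) supported"),
              class = "wearals_format_error")
      }
      if (fmt[2] != 1L) {
        abort(paste0("format error in ", path, ": only mono audio supported"),
              class = "wearals_format_error")
      }
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16L) {
        abort(paste0("format error in ", path, ": only 16-bit samples supported"),
              class = "wearals_format_error")
      }
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      samples <- readBin(con, "integer", size / 2, size = 2, endian = "little",
                         signed = TRUE)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(sample_rate) || is.null(samples)) {
    abort(paste0("format error in ", path, ": missing fmt or data chunk"),
          class = "wearals_format_error")
  }
  structure(list(samples = samples / 32767, sample_rate_hz = sample_rate),
            class = "wearals_audio")
}

#' @rdname read_wav
#' @param audio A `wearals_audio` object, or a list with `samples` and
#'   `sample_rate_hz`.
#' @export
write_wav <- function(audio, path) {
  stopifnot(is.list(audio), !is.null(audio$samples), !is.null(audio$sample_rate_hz))
  x <- pmin(1, pmax(-1, audio$samples))
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(audio$sample_rate_hz)
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
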