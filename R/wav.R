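#' Waveform container
#'
#' A mono waveform: a numeric sample vector plus its sampling rate.
#' Clinical and laryngeal recordings in this pipeline are 16 kHz, 16-bit,
#' single channel.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling rate in Hz (default 16000).
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate = 16000) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform has no audio samples")
  if (!is.numeric(rate) || rate <= 0) stop("sampling rate must be positive")
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

as_waveform <- function(w, rate = 16000) {
  if (inherits(w, "waveform")) w else waveform(w, rate)
}

#' Read a RIFF WAV file (PCM 16-bit mono)
#'
#' Minimal reader for the uncompressed PCM format used by the corpus:
#' little-endian RIFF with a single 16-bit channel. Samples are returned
#' as integers in [-32768, 32767].
#'
#' @param path Path to a .wav file.
#' @return A [waveform].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data chunk before fmt")
      if (bits != 16L) stop("only 16-bit PCM is supported")
      samples <- readBin(con, "integer", size / 2L, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk")
  if (channels != 1L) stop("only mono WAV is supported (got ", channels, " channels)")
  waveform(samples, rate)
}

#' Write a RIFF WAV file (PCM 16-bit mono)
#'
#' @param w A [waveform] or numeric vector; values are clamped to the
#'   16-bit integer range and rounded.
#' @param path Output path.
#' @param rate Sampling rate, used when `w` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, rate = 16000) {
  w <- as_waveform(w, rate)
  s <- as.integer(pmin(32767, pmax(-32768, round(w$samples))))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(s)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate * 2L), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")          # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, 4, endian = "little")
  writeBin(s, con, 2, endian = "little")
  invisible(path)
}
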