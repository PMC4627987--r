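# MFCC front-end: pre-emphasis, Hamming framing, Mel filterbank cepstra,
# sentence-normalized log energy, HTK-style delta coefficients and stacking.

#' Front-end configuration
#'
#' Defaults follow the HTK conventions used throughout this pipeline:
#' 25 ms Hamming windows shifted every 10 ms, pre-emphasis 0.97, a bank of
#' 26 triangular Mel filters and cepstra c1-c12 (c0 discarded), plus the
#' per-frame log energy normalized over the utterance. FFT size, filterbank
#' edges and liftering are conventions, exposed here so they can be changed.
#'
#' @param window_ms Analysis window length in milliseconds.
#' @param shift_ms Window shift in milliseconds.
#' @param preemphasis Pre-emphasis coefficient in [0, 1).
#' @param n_filters Number of Mel filters.
#' @param n_cepstra Number of cepstral coefficients retained (c1..c12).
#' @param n_fft FFT size (window is zero-padded).
#' @param fmin,fmax Filterbank edge frequencies in Hz (`NULL` fmax = Nyquist).
#' @param energy_norm `"max"` subtracts the per-utterance maximum log energy
#'   (so the normalized energy peaks at 0); `"zscore"` standardizes it.
#' @param lifter Cepstral liftering parameter; 0 disables liftering.
#' @return A list of class `frame_config`.
#' @export
frame_config <- function(window_ms = 25, shift_ms = 10, preemphasis = 0.97,
                         n_filters = 26, n_cepstra = 12, n_fft = 512,
                         fmin = 0, fmax = NULL,
                         energy_norm = c("max", "zscore"), lifter = 0) {
  energy_norm <- match.arg(energy_norm)
  if (window_ms < shift_ms) stop("window_ms must be >= shift_ms")
  if (n_cepstra >= n_filters) stop("n_cepstra must be < n_filters")
  if (preemphasis < 0 || preemphasis >= 1) stop("preemphasis must be in [0, 1)")
  structure(list(window_ms = window_ms, shift_ms = shift_ms,
                 preemphasis = preemphasis, n_filters = n_filters,
                 n_cepstra = n_cepstra, n_fft = n_fft, fmin = fmin,
                 fmax = fmax, energy_norm = energy_norm, lifter = lifter),
            class = "frame_config")
}

#' Pre-emphasize a waveform
#'
#' First-order high-pass filter `s'[t] = s[t] - coeff * s[t-1]`; the first
#' sample is passed through unchanged (HTK boundary convention).
#'
#' @param w A [waveform] or numeric vector.
#' @param coeff Pre-emphasis coefficient in [0, 1).
#' @return A [waveform] of the same length.
#' @export
preemphasize <- function(w, coeff = 0.97) {
  w <- as_waveform(w)
  if (coeff < 0 || coeff >= 1) stop("pre-emphasis coefficient must be in [0, 1)")
  s <- w$samples
  if (length(s) == 0L) stop("waveform has no audio samples")
  out <- s - coeff * c(s[1], s[-length(s)])
  out[1] <- s[1]
  waveform(out, w$rate)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular Mel filterbank as an (n_fft/2 + 1) x n_filters matrix.
mel_filterbank <- function(rate, n_fft, n_filters, fmin, fmax) {
  n_bins <- n_fft %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2))
  fb <- matrix(0, n_bins, n_filters)
  for (m in seq_len(n_filters)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[, m] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Number of complete analysis frames for a waveform length
#'
#' @param n_samples Waveform length in samples.
#' @param rate Sampling rate in Hz.
#' @param cfg A [frame_config].
#' @return Integer frame count (0 if the signal is shorter than one window).
#' @export
n_frames <- function(n_samples, rate = 16000, cfg = frame_config()) {
  win <- round(cfg$window_ms * rate / 1000)
  shift <- round(cfg$shift_ms * rate / 1000)
  if (n_samples < win) return(0L)
  as.integer((n_samples - win) %/% shift + 1L)
}

#' Extract static cepstral features (12 MFCC + normalized log energy)
#'
#' Applies pre-emphasis, slices the signal into complete 25 ms Hamming
#' windows every 10 ms, computes c1..c12 from the log Mel filterbank via a
#' DCT, and appends the frame log energy normalized over the whole
#' utterance. Frame t (0-based) covers samples `[t*shift, t*shift + win)`.
#'
#' @param w A [waveform] or numeric vector at 16 kHz.
#' @param cfg A [frame_config].
#' @return A `T x 13` matrix, columns `c1..c12, E`.
#' @export
extract_static <- function(w, cfg = frame_config()) {
  w <- as_waveform(w)
  rate <- w$rate
  win <- round(cfg$window_ms * rate / 1000)
  shift <- round(cfg$shift_ms * rate / 1000)
  s <- preemphasize(w, cfg$preemphasis)$samples
  T_ <- n_frames(length(s), rate, cfg)
  if (T_ < 1L) stop("waveform shorter than one analysis window")
  starts <- (seq_len(T_) - 1L) * shift
  frames <- matrix(0, T_, win)
  for (t in seq_len(T_)) frames[t, ] <- s[(starts[t] + 1):(starts[t] + win)]

  # log energy before windowing (HTK), floored to avoid log(0)
  energy <- log(pmax(rowSums(frames^2), .Machine$double.xmin))
  e_star <- switch(cfg$energy_norm,
    max = energy - max(energy),
    zscore = (energy - mean(energy)) / max(stats::sd(energy), .Machine$double.eps))

  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  frames <- sweep(frames, 2, ham, `*`)

  n_fft <- cfg$n_fft
  if (n_fft < win) stop("n_fft smaller than the analysis window")
  padded <- cbind(frames, matrix(0, T_, n_fft - win))
  spec <- abs(stats::mvfft(t(padded)))^2          # n_fft x T
  n_bins <- n_fft %/% 2 + 1
  fmax <- cfg$fmax %||% (rate / 2)
  fb <- mel_filterbank(rate, n_fft, cfg$n_filters, cfg$fmin, fmax)
  fbe <- t(fb) %*% spec[seq_len(n_bins), , drop = FALSE]  # n_filters x T
  logfbe <- log(pmax(fbe, .Machine$double.xmin))

  # DCT-II rows for c1..c12 (c0 discarded), HTK scaling sqrt(2/M)
  M <- cfg$n_filters
  k <- seq_len(cfg$n_cepstra)
  dct <- sqrt(2 / M) * cos(outer(k, (seq_len(M) - 0.5), function(k, j) pi * k * j / M))
  cep <- t(dct %*% logfbe)                        # T x n_cepstra
  if (cfg$lifter > 0) {
    L <- cfg$lifter
    cep <- sweep(cep, 2, 1 + (L / 2) * sin(pi * k / L), `*`)
  }
  out <- cbind(cep, e_star)
  colnames(out) <- c(paste0("c", k), "E")
  out
}

#' HTK delta (regression) coefficients
#'
#' Computes, for every frame t and window half-width N,
#' `delta(t) = sum_{i=1..N} i * (C[t+i] - C[t-i]) / (2 * sum i^2)`.
#' Edge frames are replicated so the formula is defined at the boundaries.
#'
#' @param X A `T x d` feature matrix.
#' @param n_delta Half-width N of the regression window (default 2,
#'   i.e. five frames).
#' @return A `T x d` matrix of delta coefficients.
#' @export
delta <- function(X, n_delta = 2) {
  stopifnot_matrix(X)
  if (n_delta < 1) stop("n_delta must be >= 1")
  T_ <- nrow(X)
  if (T_ < 2 * n_delta + 1)
    warning("sequence shorter than the delta window; edge replication dominates")
  idx <- function(t) pmin(pmax(t, 1L), T_)
  num <- 0
  for (i in seq_len(n_delta))
    num <- num + i * (X[idx(seq_len(T_) + i), , drop = FALSE] -
                      X[idx(seq_len(T_) - i), , drop = FALSE])
  num / (2 * sum(seq_len(n_delta)^2))
}

#' Stack derivative coefficients onto static features
#'
#' Appends first/second (order 2, 13 -> 39) or first/second/third
#' (order 3, 13 -> 52) HTK regression coefficients, each computed by
#' re-applying [delta()] to the previous order.
#'
#' @param X A `T x 13` static feature matrix.
#' @param order 2 or 3 derivative orders to append.
#' @param n_delta Delta window half-width passed to [delta()].
#' @return A `T x 13*(order+1)` matrix.
#' @export
stack_derivatives <- function(X, order = 3, n_delta = 2) {
  stopifnot_matrix(X)
  if (ncol(X) != 13L) stop("static features must have 13 columns, got ", ncol(X))
  if (!order %in% c(2L, 3L)) stop("derivative order must be 2 or 3")
  base <- colnames(X) %||% c(paste0("c", 1:12), "E")
  d1 <- delta(X, n_delta)
  d2 <- delta(d1, n_delta)
  out <- cbind(X, d1, d2)
  tags <- c("", "_d", "_dd")
  if (order == 3L) {
    out <- cbind(out, delta(d2, n_delta))
    tags <- c(tags, "_ddd")
  }
  colnames(out) <- unlist(lapply(tags, function(s) paste0(base, s)))
  out
}
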