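# Parallel-utterance alignment: uniform length normalization and dynamic
# time warping over static cepstral frames, producing the source/target
# frame mapping list the conversion model is trained on.

#' Uniformly resample a waveform to a target length
#'
#' Uniform time-scale change (speed change; pitch shifts accordingly):
#' when shrinking, the signal is low-pass filtered at the new Nyquist
#' first, then cubic-spline interpolated onto the new uniform grid.
#'
#' @param w A [waveform] or numeric vector.
#' @param target_len Desired length in samples.
#' @return A [waveform] with exactly `target_len` samples at the same
#'   nominal rate.
#' @export
length_normalize <- function(w, target_len) {
  w <- as_waveform(w)
  if (!is.numeric(target_len) || target_len < 1)
    stop("target_len must be a positive sample count")
  target_len <- as.integer(target_len)
  n <- length(w$samples)
  if (target_len < round(0.025 * w$rate))
    stop("target_len shorter than one analysis window is degenerate")
  if (n == target_len) return(w)
  s <- w$samples
  if (target_len < n) {              # decimation: anti-alias first
    bf <- signal::butter(8, 0.95 * target_len / n)
    s <- signal::filtfilt(bf, s)
  }
  grid <- seq(1, n, length.out = target_len)
  out <- stats::spline(seq_len(n), s, xout = grid, method = "natural")$y
  waveform(out, w$rate)
}

#' Dynamic time warping between two feature sequences
#'
#' Minimum accumulated Euclidean-distance monotone alignment with steps
#' (1,0), (0,1) and (1,1); every visited cell contributes its frame
#' distance. Ties are broken deterministically in the backtrace:
#' diagonal first, then advancing the target index, then the source.
#'
#' @param X,Y Feature matrices (frames in rows, equal column count).
#' @param band Optional Sakoe-Chiba band half-width in frames
#'   (`NULL` = unconstrained).
#' @return An object of class `alignment_path`: list with `pairs`
#'   (two-column matrix of 1-based source/target frame indices, first row
#'   (1,1), last row (T_x, T_y)) and `cost`.
#' @export
dtw_align <- function(X, Y, band = NULL) {
  stopifnot_matrix(X); stopifnot_matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("dimension mismatch: ", ncol(X), " vs ", ncol(Y), " columns")
  n <- nrow(X); m <- nrow(Y)
  # full local distance matrix (Euclidean)
  d2 <- outer(rowSums(X^2), rep(1, m)) + outer(rep(1, n), rowSums(Y^2)) -
    2 * X %*% t(Y)
  ld <- sqrt(pmax(d2, 0))
  D <- matrix(Inf, n, m)
  D[1, 1] <- ld[1, 1]
  inb <- function(i, j) is.null(band) || abs(i - j) <= band
  for (j in 2:max(m, 2)) if (m >= 2 && inb(1, j)) D[1, j] <- D[1, j - 1] + ld[1, j]
  for (i in 2:max(n, 2)) if (n >= 2 && inb(i, 1)) D[i, 1] <- D[i - 1, 1] + ld[i, 1]
  if (n >= 2 && m >= 2) {
    for (i in 2:n) {
      row_prev <- D[i - 1, ]
      row_cur <- D[i, ]
      for (j in 2:m) {
        if (!inb(i, j)) next
        best <- min(row_prev[j - 1], row_prev[j], row_cur[j - 1])
        row_cur[j] <- best + ld[i, j]
      }
      D[i, ] <- row_cur
    }
  }
  if (!is.finite(D[n, m])) stop("no admissible path (band too narrow)")
  # backtrace with deterministic tie-breaking
  path <- matrix(0L, n + m, 2)
  k <- 1L; i <- n; j <- m
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i == 1L) { j <- j - 1L }
    else if (j == 1L) { i <- i - 1L }
    else {
      diag_ <- D[i - 1, j - 1]; left <- D[i, j - 1]; up <- D[i - 1, j]
      if (diag_ <= left && diag_ <= up) { i <- i - 1L; j <- j - 1L }
      else if (left <= up) { j <- j - 1L }
      else { i <- i - 1L }
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  pairs <- path[k:1, , drop = FALSE]
  colnames(pairs) <- c("source", "target")
  structure(list(pairs = pairs, cost = D[n, m]), class = "alignment_path")
}

#' @export
print.alignment_path <- function(x, ...) {
  cat(sprintf("<alignment_path: %d pairs, cost %.4f>\n", nrow(x$pairs), x$cost))
  invisible(x)
}

#' Build the joint source/target mapping list from an alignment
#'
#' Concatenates each aligned source/target frame pair into a joint vector
#' `z = [x, y]`, preserving path order.
#'
#' @param X,Y Feature matrices the path indexes into.
#' @param path An `alignment_path` from [dtw_align()].
#' @return An `N_pairs x (ncol(X) + ncol(Y))` matrix.
#' @export
build_mapping_list <- function(X, Y, path) {
  if (!inherits(path, "alignment_path")) stop("path must be an alignment_path")
  p <- path$pairs
  if (nrow(p) < 1L) stop("empty alignment path")
  if (max(p[, 1]) > nrow(X) || max(p[, 2]) > nrow(Y) || min(p) < 1L)
    stop("alignment path indexes outside the sequences")
  Z <- cbind(X[p[, 1], , drop = FALSE], Y[p[, 2], , drop = FALSE])
  colnames(Z) <- c(paste0("x", seq_len(ncol(X))), paste0("y", seq_len(ncol(Y))))
  Z
}
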