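# Synthetic parallel-corpus generator. A "healthy" speaker is a set of
# per-phone Gaussians in the 13-dim static cepstral space with
# shifted-Poisson phone durations; its "pathological" counterpart is a
# known distortion of the same content: a fixed affine spectral map,
# additive noise, per-phone instability jitter (emulating the unstable
# excitation and specific noises of esophageal voice), and a temporal
# warp. Because the ground truth is known, every downstream stage
# (conversion recovery, HLDA, recognition) is testable without any
# clinical recordings.

#' Build a synthetic speaker model
#'
#' Per-phone Gaussian emissions with controllable minimum pairwise mean
#' separation: means are drawn at random and then radially rescaled so
#' the smallest pairwise Mahalanobis-style distance (at unit reference
#' variance) reaches `min_separation`.
#'
#' @param K Number of phones (inventory size; up to 36).
#' @param dim Static feature dimensionality (default 13).
#' @param seed Integer seed; the model is deterministic given it.
#' @param min_separation Minimum pairwise distance between phone means.
#' @param spread Standard deviation of the phone-mean draw; with unit
#'   emission variance this sets how much neighbouring phones overlap
#'   (smaller = harder recognition task).
#' @param dur_mean Mean phone duration in frames (shifted Poisson, min 3).
#' @param phones Optional label vector of length `K` (defaults to the
#'   first `K` entries of [sampa_phones()]).
#' @return An object of class `speaker_model`.
#' @export
make_speaker <- function(K = 36L, dim = 13L, seed = 1L, min_separation = 0,
                         spread = 1.2, dur_mean = 8, phones = NULL) {
  if (K < 2L) stop("at least two phones are required")
  if (is.null(phones)) {
    inv <- sampa_phones()
    if (K > length(inv)) stop("no labels available for K > ", length(inv))
    phones <- inv[seq_len(K)]
  }
  if (length(phones) != K) stop("phones must have length K")
  set.seed(seed)
  means <- matrix(stats::rnorm(K * dim, sd = spread), K, dim,
                  dimnames = list(phones, NULL))
  dmin <- min(stats::dist(means))
  if (dmin <= .Machine$double.eps)
    stop("degenerate draw: coincident phone means; separation infeasible")
  if (dmin < min_separation)
    means <- means * (min_separation / dmin) * (1 + 1e-12)
  vars <- matrix(stats::runif(K * dim, 0.8, 1.2), K, dim,
                 dimnames = list(phones, NULL))
  durs <- stats::setNames(pmax(3, stats::rpois(K, dur_mean - 3) + 3), phones)
  structure(list(phones = phones, K = as.integer(K), dim = as.integer(dim),
                 means = means,
                 vars = vars, dur_mean = durs, seed = seed),
            class = "speaker_model")
}

#' @export
print.speaker_model <- function(x, ...) {
  cat(sprintf("<speaker_model: %d phones, %d-dim statics, min separation %.2f>\n",
              x$K, x$dim, min(stats::dist(x$means))))
  invisible(x)
}

#' Sample one labeled utterance from a speaker model
#'
#' Draws a phone sequence (or uses the one given), samples a duration
#' per phone (shifted Poisson, minimum 3 frames) and emits Gaussian
#' frames. The transcription gives frame-accurate boundaries converted
#' to sample indices at 160 samples per frame.
#'
#' @param model A `speaker_model`.
#' @param phone_seq Character vector of phones, or `NULL` to draw
#'   `n_phones` at random (no immediate repeats).
#' @param n_phones Length of a random phone sequence.
#' @param seed Integer seed.
#' @param durations Optional integer vector of per-phone durations.
#' @return List with `features` (T x dim matrix), `transcription` (data
#'   frame `start`, `end`, `label`; sample units, half-open), and
#'   `phone_seq`.
#' @export
sample_utterance <- function(model, phone_seq = NULL, n_phones = 8L,
                             seed = 1L, durations = NULL) {
  if (!inherits(model, "speaker_model")) stop("model must be a speaker_model")
  set.seed(seed)
  if (is.null(phone_seq)) {
    phone_seq <- character(n_phones)
    phone_seq[1] <- sample(model$phones, 1)
    for (i in seq_len(n_phones - 1L))
      phone_seq[i + 1L] <- sample(setdiff(model$phones, phone_seq[i]), 1)
  }
  if (length(phone_seq) == 0L) stop("empty phone sequence")
  if (!all(phone_seq %in% model$phones))
    stop("phone(s) not in the model: ",
         paste(setdiff(phone_seq, model$phones), collapse = ", "))
  if (is.null(durations)) {
    lam <- pmax(model$dur_mean[phone_seq] - 3, 0.1)
    durations <- 3L + stats::rpois(length(phone_seq), lam)
  }
  if (length(durations) != length(phone_seq)) stop("one duration per phone required")
  X <- matrix(0, sum(durations), model$dim)
  row <- 0L
  for (i in seq_along(phone_seq)) {
    ph <- phone_seq[i]; d <- durations[i]
    X[row + seq_len(d), ] <- matrix(stats::rnorm(d * model$dim), d) *
      rep(sqrt(model$vars[ph, ]), each = d) +
      rep(model$means[ph, ], each = d)
    row <- row + d
  }
  ends <- cumsum(durations) * 160L
  starts <- c(0L, ends[-length(ends)])
  list(features = X,
       transcription = data.frame(start = starts, end = ends,
                                  label = phone_seq,
                                  stringsAsFactors = FALSE),
       phone_seq = phone_seq)
}

#' Specify a pathological distortion
#'
#' The distortion applied to healthy statics: a non-singular affine map
#' (random rotation composed with per-axis scaling in 0.8..1.25 when not
#' supplied), additive Gaussian noise, a per-phone "instability" offset
#' re-drawn every utterance, and a temporal warp factor rescaling phone
#' durations.
#'
#' @param dim Feature dimensionality.
#' @param seed Seed for the random affine map.
#' @param A,b Optional affine map (matrix, offset) overriding the random one.
#' @param noise_sd Additive noise standard deviation.
#' @param warp Duration scale factor (> 0).
#' @param jitter_sd Per-phone instability offset standard deviation.
#' @return An object of class `distortion_spec`.
#' @export
distortion_spec <- function(dim = 13L, seed = 1L, A = NULL, b = NULL,
                            noise_sd = 0.8, warp = 1.4, jitter_sd = 0.3) {
  if (warp <= 0) stop("warp factor must be positive")
  set.seed(seed)
  if (is.null(A)) {
    Q <- qr.Q(qr(matrix(stats::rnorm(dim^2), dim)))
    A <- Q %*% diag(stats::runif(dim, 0.8, 1.25)) %*% t(Q)
  }
  if (is.null(b)) b <- stats::rnorm(dim, sd = 1)
  if (nrow(A) != dim || ncol(A) != dim) stop("A must be dim x dim")
  if (abs(det(A)) < 1e-10) stop("affine matrix must be non-singular")
  structure(list(dim = dim, A = A, b = b, noise_sd = noise_sd,
                 warp = warp, jitter_sd = jitter_sd), class = "distortion_spec")
}

#' @export
print.distortion_spec <- function(x, ...) {
  cat(sprintf(
    "<distortion_spec: dim %d, noise sd %.2f, warp %.2f, jitter sd %.2f>\n",
    x$dim, x$noise_sd, x$warp, x$jitter_sd))
  invisible(x)
}

#' Distort a healthy utterance into its pathological counterpart
#'
#' Per phone segment, the duration is rescaled by the warp factor
#' (rounded, minimum 3 frames) and frames are resampled onto the new
#' length; every frame is then mapped through the affine spectral map,
#' shifted by the utterance's per-phone instability offset, and additive
#' noise is applied. The transcription is updated consistently.
#'
#' @param utterance A list as returned by [sample_utterance()].
#' @param spec A `distortion_spec`.
#' @param seed Integer seed for noise and jitter.
#' @return A list with the same structure as the input.
#' @export
distort <- function(utterance, spec, seed = 1L) {
  if (!inherits(spec, "distortion_spec")) stop("spec must be a distortion_spec")
  set.seed(seed)
  tr <- utterance$transcription
  segs <- vector("list", nrow(tr))
  phones <- unique(tr$label)
  jitter <- matrix(stats::rnorm(length(phones) * spec$dim, sd = spec$jitter_sd),
                   length(phones), spec$dim, dimnames = list(phones, NULL))
  durs_new <- integer(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    f0 <- tr$start[i] / 160L + 1L
    f1 <- tr$end[i] / 160L
    seg <- utterance$features[f0:f1, , drop = FALSE]
    d_old <- nrow(seg)
    d_new <- max(3L, as.integer(round(d_old * spec$warp)))
    if (d_new == d_old) {
      seg2 <- seg
    } else {
      idx <- seq(1, d_old, length.out = d_new)
      lo <- floor(idx); hi <- ceiling(idx); wgt <- idx - lo
      seg2 <- (1 - wgt) * seg[lo, , drop = FALSE] + wgt * seg[hi, , drop = FALSE]
    }
    seg2 <- seg2 %*% t(spec$A)
    seg2 <- sweep(seg2, 2, spec$b, `+`)
    seg2 <- sweep(seg2, 2, jitter[tr$label[i], ], `+`)
    if (spec$noise_sd > 0)
      seg2 <- seg2 + matrix(stats::rnorm(length(seg2), sd = spec$noise_sd),
                            nrow(seg2))
    segs[[i]] <- seg2
    durs_new[i] <- d_new
  }
  ends <- cumsum(durs_new) * 160L
  starts <- c(0L, ends[-length(ends)])
  list(features = do.call(rbind, segs),
       transcription = data.frame(start = starts, end = ends,
                                  label = tr$label, stringsAsFactors = FALSE),
       phone_seq = utterance$phone_seq)
}

#' Generate a parallel healthy/pathological corpus
#'
#' Draws `n_sentences` utterances from the speaker model and distorts
#' each into its pathological counterpart (same phone content, distorted
#' features and durations). Optionally writes a TIMIT-style directory
#' tree (`.feat`, `.phn`, `.wrd` per sentence, a train/test split file,
#' and the serialized ground truth) under `out_dir`.
#'
#' @param n_sentences Number of parallel sentence pairs.
#' @param model A `speaker_model`.
#' @param spec A `distortion_spec`.
#' @param seed Integer seed.
#' @param n_phones_range Range of phones per sentence (inclusive).
#' @param out_dir Optional output directory.
#' @param train_frac Fraction of sentences in the training split.
#' @return An object of class `parallel_corpus`: lists `target`
#'   (healthy) and `source` (pathological) of utterances, `split`
#'   (character vector "train"/"test"), `model`, `spec`.
#' @export
generate_parallel_corpus <- function(n_sentences, model, spec, seed = 1L,
                                     n_phones_range = c(6L, 10L),
                                     out_dir = NULL, train_frac = 0.8) {
  if (n_sentences < 1L) stop("n_sentences must be >= 1")
  set.seed(seed)
  sent_seeds <- sample.int(2^30, 2L * n_sentences)
  n_ph <- sample(seq(n_phones_range[1], n_phones_range[2]), n_sentences,
                 replace = TRUE)
  target <- vector("list", n_sentences)
  source <- vector("list", n_sentences)
  for (s in seq_len(n_sentences)) {
    target[[s]] <- sample_utterance(model, n_phones = n_ph[s],
                                    seed = sent_seeds[2L * s - 1L])
    source[[s]] <- distort(target[[s]], spec, seed = sent_seeds[2L * s])
  }
  n_train <- max(1L, min(n_sentences - 1L, round(train_frac * n_sentences)))
  if (n_sentences == 1L) n_train <- 1L
  split <- rep("test", n_sentences)
  split[seq_len(n_train)] <- "train"
  corpus <- structure(list(target = target, source = source, split = split,
                           model = model, spec = spec, seed = seed),
                      class = "parallel_corpus")
  if (!is.null(out_dir)) write_corpus(corpus, out_dir)
  corpus
}

#' @export
print.parallel_corpus <- function(x, ...) {
  cat(sprintf("<parallel_corpus: %d sentence pairs (%d train / %d test), %d phones>\n",
              length(x$target), sum(x$split == "train"),
              sum(x$split == "test"), x$model$K))
  invisible(x)
}

#' Synthesize a crude waveform for a phone sequence
#'
#' Filtered pulse-train audio (per-phone resonator and fundamental) used
#' solely to exercise the MFCC front-end; no claim of acoustic realism.
#'
#' @param phone_seq Character vector of phone labels.
#' @param durations Per-phone durations in frames (160 samples each).
#' @param seed Seed for the per-phone resonator parameters.
#' @param rate Sampling rate in Hz.
#' @return A [waveform].
#' @export
synthesize_waveform <- function(phone_seq, durations = rep(20L, length(phone_seq)),
                                seed = 1L, rate = 16000) {
  if (length(phone_seq) == 0L) stop("empty phone sequence")
  set.seed(seed)
  phones <- unique(phone_seq)
  f0 <- stats::setNames(stats::runif(length(phones), 80, 220), phones)
  fr <- stats::setNames(stats::runif(length(phones), 300, 3000), phones)
  out <- numeric(0)
  for (i in seq_along(phone_seq)) {
    ph <- phone_seq[i]
    n <- durations[i] * 160L + 240L
    pulses <- numeric(n)
    period <- max(2L, round(rate / f0[ph]))
    pulses[seq(1, n, by = period)] <- 1
    r <- 0.97
    w <- 2 * pi * fr[ph] / rate
    s <- signal::filter(signal::Arma(b = 1, a = c(1, -2 * r * cos(w), r^2)), pulses)
    out <- c(out, as.numeric(s)[seq_len(durations[i] * 160L)])
  }
  waveform(out * 1000, rate)
}
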