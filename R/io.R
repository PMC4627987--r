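# Corpus and model I/O: TIMIT-dialect .phn/.wrd transcriptions, a
# documented binary feature-file format with plain-text export, JSON
# model serialization, and frame labeling from transcriptions.

#' The 36-label SAMPA phone inventory of standard French
#'
#' Consonants, glides, oral and nasal vowels, plus the silence marker.
#'
#' @return Character vector of 36 unique SAMPA labels (last is `"sil"`).
#' @export
sampa_phones <- function() {
  c("p", "b", "t", "d", "k", "g", "f", "v", "s", "z", "j", "m", "n", "N",
    "S", "Z", "O", "o", "u", "y", "@", "l", "R", "w", "H", "i", "e", "E",
    "a", "2", "9", "9~", "e~", "a~", "o~", "sil")
}

#' Read a TIMIT-style transcription file
#'
#' Each line is `start_sample end_sample label`, 0-based, half-open.
#' Intervals must be sorted and non-overlapping.
#'
#' @param path Path to a `.phn` or `.wrd` file.
#' @param phones Optional label inventory; unknown labels are an error.
#' @return Data frame with columns `start`, `end`, `label`.
#' @export
read_phn <- function(path, phones = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty transcription file: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  out <- data.frame(start = integer(length(parts)), end = integer(length(parts)),
                    label = character(length(parts)), stringsAsFactors = FALSE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 3L)
      stop("malformed line ", i, " in ", path, ": expected 'start end label'")
    st <- suppressWarnings(as.integer(p[1])); en <- suppressWarnings(as.integer(p[2]))
    if (is.na(st) || is.na(en) || st < 0L || en <= st)
      stop("malformed interval on line ", i, " in ", path)
    if (!is.null(phones) && !p[3] %in% phones)
      stop("unknown label '", p[3], "' on line ", i, " in ", path)
    out$start[i] <- st; out$end[i] <- en; out$label[i] <- p[3]
  }
  if (is.unsorted(out$start) || any(out$start[-1] < out$end[-nrow(out)]))
    stop("intervals overlap or are unsorted in ", path)
  out
}

#' Write a TIMIT-style transcription file
#'
#' @param trans Data frame with `start`, `end`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phn <- function(trans, path) {
  writeLines(sprintf("%d %d %s", trans$start, trans$end, trans$label), path)
  invisible(path)
}

#' Label every frame with the phone covering its center
#'
#' Frame t (0-based) covers samples `[t*shift, t*shift + window)`; its
#' center sample `t*shift + window/2` selects the transcription interval
#' (half-open). Frames whose center falls outside every interval are
#' assigned silence with a warning.
#'
#' @param trans Transcription data frame (`start`, `end`, `label`).
#' @param n_frames Number of frames T to label.
#' @param shift Frame shift in samples.
#' @param window Window length in samples.
#' @param silence Label used for uncovered frames.
#' @return Character vector of length `n_frames`.
#' @export
frame_labels <- function(trans, n_frames, shift = 160L, window = 400L,
                         silence = "sil") {
  centers <- (seq_len(n_frames) - 1L) * shift + window %/% 2L
  idx <- findInterval(centers, trans$start)
  lab <- rep(NA_character_, n_frames)
  ok <- idx >= 1L
  ok[ok] <- centers[ok] < trans$end[idx[ok]]
  lab[ok] <- trans$label[idx[ok]]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " frame center(s) uncovered; assigned '", silence, "'")
    lab[is.na(lab)] <- silence
  }
  lab
}

# --- feature files -----------------------------------------------------

#' Write a binary feature file
#'
#' Documented little-endian layout: magic `"ESOF"`, int32 frame count T,
#' int32 dimensionality d, float64 frame period in ms, then T*d float64
#' values frame by frame.
#'
#' @param X Feature matrix (frames in rows).
#' @param path Output path.
#' @param frame_period_ms Frame period recorded in the header.
#' @return `path`, invisibly.
#' @export
write_feat <- function(X, path, frame_period_ms = 10) {
  stopifnot_matrix(X)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("ESOF", con, eos = NULL)
  writeBin(c(nrow(X), ncol(X)), con, 4, endian = "little")
  writeBin(as.numeric(frame_period_ms), con, 8, endian = "little")
  writeBin(as.numeric(t(X)), con, 8, endian = "little")
  invisible(path)
}

#' Read a binary feature file written by [write_feat()]
#'
#' @param path Path to a `.feat` file.
#' @return Feature matrix with attribute `frame_period_ms`.
#' @export
read_feat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), "ESOF"))
    stop("not a feature file: ", path)
  hd <- readBin(con, "integer", 2, 4, endian = "little")
  period <- readBin(con, "numeric", 1, 8, endian = "little")
  X <- matrix(readBin(con, "numeric", hd[1] * hd[2], 8, endian = "little"),
              hd[1], hd[2], byrow = TRUE)
  attr(X, "frame_period_ms") <- period
  X
}

#' Export features as delimited text
#'
#' Tab-separated, one frame per line, full (`%.17g`) precision so the
#' values survive a round-trip exactly.
#'
#' @param X Feature matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feat_text <- function(X, path) {
  stopifnot_matrix(X)
  rows <- apply(X, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_feat_text
#' @export
read_feat_text <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", colClasses = "numeric"))
}

# --- model serialization ----------------------------------------------

#' Save a model object as JSON
#'
#' Serializes any of the pipeline's model objects (`joint_gmm`,
#' `conversion_function`, `hlda`, `phone_hmm_set`, `bigram_lm`,
#' `speaker_model`, `distortion_spec`) to JSON at full floating-point
#' precision, so [load_model()] restores it bit-identically.
#'
#' @param object A supported model object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(object, path) {
  json <- jsonlite::serializeJSON(object, digits = 17)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

# --- corpus directories ------------------------------------------------

#' Write a parallel corpus as a TIMIT-style directory tree
#'
#' Creates `source/` (pathological) and `target/` (healthy) directories
#' with per-sentence `.feat`, `.phn` and `.wrd` files, a `split.txt`
#' train/test assignment, and the serialized ground truth
#' (`speaker_model.json`, `distortion_spec.json`).
#'
#' @param corpus A `parallel_corpus`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  for (sub in c("source", "target"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(corpus$target)) {
    id <- sprintf("s%04d", s)
    for (sub in c("source", "target")) {
      u <- corpus[[sub]][[s]]
      write_feat(u$features, file.path(dir, sub, paste0(id, ".feat")))
      write_phn(u$transcription, file.path(dir, sub, paste0(id, ".phn")))
      wrd <- data.frame(start = min(u$transcription$start),
                        end = max(u$transcription$end),
                        label = paste(u$phone_seq, collapse = "-"))
      write_phn(wrd, file.path(dir, sub, paste0(id, ".wrd")))
    }
  }
  writeLines(sprintf("s%04d %s", seq_along(corpus$split), corpus$split),
             file.path(dir, "split.txt"))
  save_model(corpus$model, file.path(dir, "speaker_model.json"))
  save_model(corpus$spec, file.path(dir, "distortion_spec.json"))
  invisible(dir)
}

#' Read back a corpus directory written by [write_corpus()]
#'
#' @param dir Corpus directory.
#' @return A `parallel_corpus`.
#' @export
read_corpus <- function(dir) {
  split_lines <- strsplit(readLines(file.path(dir, "split.txt")), " ")
  ids <- vapply(split_lines, `[[`, character(1), 1L)
  split <- vapply(split_lines, `[[`, character(1), 2L)
  rd <- function(sub, id) {
    tr <- read_phn(file.path(dir, sub, paste0(id, ".phn")))
    list(features = read_feat(file.path(dir, sub, paste0(id, ".feat"))),
         transcription = tr, phone_seq = tr$label)
  }
  structure(list(
    target = lapply(ids, function(id) rd("target", id)),
    source = lapply(ids, function(id) rd("source", id)),
    split = split,
    model = load_model(file.path(dir, "speaker_model.json")),
    spec = load_model(file.path(dir, "distortion_spec.json"))),
    class = "parallel_corpus")
}
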