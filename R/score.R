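# Phone-string scoring: minimum-edit-distance alignment of reference
# and hypothesis, yielding substitution/deletion/insertion counts and
# the Accuracy / Correct percentages
#   Accuracy = (N - S - D - I) / N,  Correct = (N - S - D) / N.

#' Score a hypothesis phone string against a reference
#'
#' Aligns the two strings by dynamic programming (unit costs by default;
#' the HTK 10/7/7 substitution/deletion/insertion weighting is available
#' for comparability) and counts substitutions, deletions and
#' insertions. `Correct` ignores insertions; `Accuracy` penalizes them,
#' so `Accuracy <= Correct` always.
#'
#' @param reference Character vector: the correct phone string (non-empty).
#' @param hypothesis Character vector: the recognized phone string.
#' @param weights Length-3 numeric: substitution, deletion, insertion
#'   alignment costs.
#' @return An object of class `score_report` with fields `N`, `S`, `D`,
#'   `I`, `accuracy`, `correct` (percent).
#' @export
score_phones <- function(reference, hypothesis,
                         weights = c(sub = 1, del = 1, ins = 1)) {
  reference <- as.character(reference)
  hypothesis <- as.character(hypothesis)
  n <- length(reference); m <- length(hypothesis)
  if (n == 0L) stop("empty reference")
  ws <- weights[1]; wd <- weights[2]; wi <- weights[3]
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1] <- (0:n) * wd
  D[1, ] <- (0:m) * wi
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- D[i, j] + if (reference[i] == hypothesis[j]) 0 else ws
      D[i + 1, j + 1] <- min(sub, D[i, j + 1] + wd, D[i + 1, j] + wi)
    }
  }
  # backtrace (diagonal preferred, then deletion, then insertion)
  S <- 0L; Dc <- 0L; Ic <- 0L
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      sub_cost <- if (reference[i] == hypothesis[j]) 0 else ws
      if (D[i + 1, j + 1] == D[i, j] + sub_cost) {
        if (sub_cost > 0) S <- S + 1L
        i <- i - 1L; j <- j - 1L
        next
      }
    }
    if (i > 0L && D[i + 1, j + 1] == D[i, j + 1] + wd) {
      Dc <- Dc + 1L; i <- i - 1L
    } else {
      Ic <- Ic + 1L; j <- j - 1L
    }
  }
  score_report(n, S, Dc, Ic)
}

score_report <- function(N, S, D, I) {
  structure(list(N = as.integer(N), S = as.integer(S), D = as.integer(D),
                 I = as.integer(I),
                 accuracy = 100 * (N - S - D - I) / N,
                 correct = 100 * (N - S - D) / N),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("N=%d  S=%d  D=%d  I=%d\nAccuracy = %.2f %%   Correct = %.2f %%\n",
              x$N, x$S, x$D, x$I, x$accuracy, x$correct))
  invisible(x)
}

#' Score a whole corpus of phone strings
#'
#' Sums the alignment counts over utterance pairs and reports corpus
#' Accuracy and Correct.
#'
#' @param references,hypotheses Parallel lists of phone-label vectors.
#' @param weights Alignment costs, as in [score_phones()].
#' @return A `score_report` over the pooled counts.
#' @export
score_corpus <- function(references, hypotheses,
                         weights = c(sub = 1, del = 1, ins = 1)) {
  if (length(references) != length(hypotheses))
    stop("references and hypotheses must be parallel lists")
  tot <- c(N = 0L, S = 0L, D = 0L, I = 0L)
  for (u in seq_along(references)) {
    r <- score_phones(references[[u]], hypotheses[[u]], weights)
    tot <- tot + c(r$N, r$S, r$D, r$I)
  }
  score_report(tot[[1]], tot[[2]], tot[[3]], tot[[4]])
}
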