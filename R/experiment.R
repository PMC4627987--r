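# Top-level experiment driver: voice conversion -> derivative stacking
# -> optional HLDA -> monophone HMM training -> bigram-weighted Viterbi
# decoding -> edit-distance scoring. The three feature configurations
# mirror the study design: 39-dim (statics + delta + delta-delta),
# 52-dim (adding the third derivative), and HLDA 52 -> 39.

#' Experiment configuration
#'
#' @param mode Feature configuration: `"mfcc39"` (order-2 derivatives),
#'   `"mfcc52"` (order-3), or `"hlda"` (order-3 then HLDA 52 -> 39).
#' @param conversion Apply voice conversion to the pathological features
#'   before recognition (requires a parallel conversion corpus).
#' @param G Number of joint-GMM components for conversion.
#' @param n_outer Outer alignment/estimation iterations for conversion.
#' @param n_mix Gaussians per HMM state after mixture splitting.
#' @param iters_per_stage Baum-Welch iterations per training stage.
#' @param hlda_sweeps Maximum HLDA row-update sweeps.
#' @param lm_k Add-k smoothing for the bigram model.
#' @param lm_scale,ins_penalty Decoder language-model scale and
#'   per-phone insertion penalty.
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("hlda", "mfcc39", "mfcc52"),
                              conversion = TRUE, G = 16L, n_outer = 3L,
                              n_mix = 2L, iters_per_stage = 3L,
                              hlda_sweeps = 100L, lm_k = 1, lm_scale = 1,
                              ins_penalty = 0, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, conversion = conversion, G = as.integer(G),
                 n_outer = as.integer(n_outer), n_mix = as.integer(n_mix),
                 iters_per_stage = as.integer(iters_per_stage),
                 hlda_sweeps = as.integer(hlda_sweeps), lm_k = lm_k,
                 lm_scale = lm_scale, ins_penalty = ins_penalty,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run one recognition experiment end to end
#'
#' Trains (optionally) the voice-conversion function on a parallel
#' corpus, converts the recognition corpus's pathological features,
#' stacks derivative coefficients, optionally estimates and applies the
#' HLDA projection (statistics from the training split, classes = the
#' phones), trains the monophone recognizer and bigram model on the
#' training split, decodes the test split and scores it.
#'
#' @param recog A `parallel_corpus`: recognition train/test sentences
#'   (the `source` side is decoded; transcriptions supply labels).
#' @param conv A `parallel_corpus` of conversion-training sentence pairs
#'   (required when `cfg$conversion` is `TRUE`).
#' @param cfg An [experiment_config()].
#' @return An object of class `experiment_report`: the test-set
#'   `score_report` plus per-stage artifacts and traces.
#' @export
run_experiment <- function(recog, conv = NULL, cfg = experiment_config()) {
  if (!inherits(recog, "parallel_corpus")) stop("recog must be a parallel_corpus")
  fn <- NULL
  if (cfg$conversion) {
    if (is.null(conv)) stop("conversion requested but no conversion corpus given")
    fn <- train_conversion(lapply(conv$source, `[[`, "features"),
                           lapply(conv$target, `[[`, "features"),
                           G = cfg$G, n_outer = cfg$n_outer, seed = cfg$seed)
  }
  order_ <- if (cfg$mode == "mfcc39") 2L else 3L
  prep <- lapply(recog$source, function(u) {
    stat <- if (is.null(fn)) u$features else convert(fn, u$features)
    stack_derivatives(stat, order = order_)
  })
  is_train <- recog$split == "train"
  hl <- NULL
  if (cfg$mode == "hlda") {
    labels <- unlist(lapply(which(is_train), function(s) {
      u <- recog$source[[s]]
      frame_labels(u$transcription, nrow(u$features), shift = 160L, window = 160L)
    }))
    stats <- accumulate_stats(prep[is_train], labels)
    hl <- estimate_hlda(stats, p = 39L, n_iters = cfg$hlda_sweeps)
    prep <- lapply(prep, function(X) hlda_project(hl, X))
  }
  phones <- recog$model$phones
  trans <- lapply(recog$source, `[[`, "phone_seq")
  hset <- train_recognizer(prep[is_train], trans[is_train], phones,
                           n_mix = cfg$n_mix,
                           iters_per_stage = cfg$iters_per_stage)
  lm <- train_bigram(trans[is_train], phones, k = cfg$lm_k)
  test_idx <- which(!is_train)
  hyps <- lapply(test_idx, function(s)
    viterbi_decode(hset, prep[[s]], lm, cfg$lm_scale, cfg$ins_penalty))
  refs <- trans[test_idx]
  sc <- score_corpus(refs, hyps)
  structure(list(score = sc, config = cfg, dim = ncol(prep[[1]]),
                 conversion = fn, hlda = hl, models = hset, lm = lm,
                 hypotheses = hyps, references = refs),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment: %s%s (recognizer input dim %d)\n",
              x$config$mode,
              if (x$config$conversion) " + voice conversion" else " (no conversion)",
              x$dim))
  print(x$score)
  invisible(x)
}
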