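Package: esorec
Title: Voice Conversion and Phone Recognition for Esophageal Speech
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A hybrid pipeline for improving automatic phone recognition of
    esophageal (post-laryngectomy) speech. Provides an MFCC front-end with
    HTK-style delta coefficients, dynamic-time-warping alignment of parallel
    utterances, joint-density Gaussian-mixture voice conversion estimated
    directly from vector-quantized data, heteroscedastic linear discriminant
    analysis (HLDA) for 52-to-39 dimensionality reduction, a monophone
    HMM/GMM phone recognizer with bigram-weighted Viterbi decoding and
    edit-distance scoring, and a synthetic parallel-corpus generator so the
    whole pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
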