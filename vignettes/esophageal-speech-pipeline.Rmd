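---
title: "Voice conversion and phone recognition for esophageal speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voice conversion and phone recognition for esophageal speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esorec)
```

## The problem

After a total laryngectomy the vocal folds are removed; patients who learn
esophageal speech produce voice by expelling air through the esophagus.
The resulting signal is hoarse and unstable, with spectral envelopes and
noise characteristics far from laryngeal speech, and automatic phone
recognizers trained for it perform poorly. `esorec` implements a hybrid
enhancement strategy that operates entirely in the cepstral feature
domain — no waveform is ever resynthesized:

1. **Voice conversion.** A mapping `F(x)` from pathological static
   cepstra to the healthy speaker's feature space is learned from a small
   parallel corpus (the same sentences uttered by both speakers).
2. **Derivative stacking.** HTK-style regression coefficients of order
   1–3 are appended to the *converted* statics (13 → 39 or 52
   dimensions).
3. **HLDA.** A heteroscedastic linear discriminant projection reduces the
   52-dimensional vectors to 39 while preserving class-dependent
   variance structure.
4. **Recognition.** Monophone 5-state HMMs (3 emitting states, diagonal
   GMM emissions) are trained by embedded Baum-Welch and decoded by
   Viterbi over a bigram-weighted phone loop; hypotheses are scored by
   minimum-edit-distance alignment, reporting
   `Accuracy = (N - S - D - I)/N` and `Correct = (N - S - D)/N`.

## The conversion model

Aligned source/target frame pairs are concatenated into joint vectors
`z = [x, y]` (13 + 13 statics). The joint density is a G-component
Gaussian mixture,

$$p(z) = \sum_{i=1}^{G} \alpha_i \, \mathcal N(z; \mu_i, \Sigma_i),
\qquad
\mu_i = \begin{bmatrix}\mu_i^x\\ \mu_i^y\end{bmatrix},\quad
\Sigma_i = \begin{bmatrix}\Sigma_i^{xx} & \Sigma_i^{xy}\\
\Sigma_i^{yx} & \Sigma_i^{yy}\end{bmatrix},$$

whose parameters are estimated *directly from vector-quantized data*
rather than by EM: joint vectors are classified by k-means, and each
class contributes its occupancy ratio (`alpha_i`), sample means and full
joint sample covariance (population 1/N convention). Hard re-assignment
to the nearest class mean alternates with re-estimation until the
partition stabilizes (at most 20 passes). The conversion function is the
conditional expectation

$$F(x) = E[y \mid x] = \sum_{i=1}^{G} p(i \mid x)\,
\bigl(\mu_i^y + \Sigma_i^{yx} (\Sigma_i^{xx})^{-1} (x - \mu_i^x)\bigr),$$

a posterior-weighted mixture of per-class linear regressions. Posteriors
are computed in the log domain.

**Alignment loop.** Parallel sentences are aligned by dynamic time
warping over the 13 statics (Euclidean distance, steps (1,0), (0,1),
(1,1), no band by default; ties in the backtrace prefer the diagonal,
then the target step). On the first outer iteration the raw source is
aligned with the target; from the second iteration the *converted*
source is aligned with the target, refining the mapping list before
re-estimation. The outer loop runs `n_outer` times (default 3) or stops
when the relative improvement of the mean squared conversion error falls
below 1e-4; the model with the lowest error is kept.

**Numerical choices.** Class covariance diagonals are floored at
1e-4 of the global variance — a lower bound rather than an additive
load, so well-conditioned classes keep their exact sample covariance and
the G = 1 case reproduces ordinary least squares to machine precision.
Empty k-means classes are re-seeded from the point farthest from its
centroid, guaranteeing G live classes. Energy is included in the DTW
distance (it carries alignment information); derivatives are computed
*after* conversion, never converted themselves.

## The HLDA projection

Classes are the phones (per-frame labels from the transcriptions). In
the transformed space the first `p` rows of the square matrix `Theta`
carry class-dependent diagonal variances and the remaining `n - p` rows
a single shared distribution: maximizing the data log-likelihood in
`Theta` concentrates discriminative structure in the retained rows. The
estimator is the standard generalized-EM row update: each row is
replaced by its cofactor direction scaled through the weighted-
covariance matrix `G_j`, which is the exact maximizer with all other
rows fixed, so the objective never decreases. Initialization is the LDA
eigenbasis (eigenvalue order, ties by index); covariances get a diagonal
load of 1e-6 x trace/n before inversion; iteration stops after 100
sweeps or a relative change below 1e-6. The objective is evaluated from
sufficient statistics only, so estimation never re-reads frames.

Both statistics paths are available: HLDA can be estimated on converted
or on original training features; the experiment driver uses whatever
features feed the recognizer in that configuration.

## The recognizer

Each of the 36 phones (SAMPA inventory, silence included, same topology
for silence) is a 5-state left-to-right HMM whose 3 emitting states
carry diagonal-covariance GMMs with up to 16 components. Flat start ties
every state to the global Gaussian; embedded Baum-Welch concatenates the
phone models of each transcribed utterance into a linear chain and
re-estimates means, variances (floored at 1e-2 of the global variance),
mixture weights and transitions from forward-backward occupancies (log
domain). Mixtures grow by binary splitting (means perturbed by
±0.2 standard deviations, weights halved) on a 1→2→4→8→16 schedule with
re-estimation between increments.

The bigram language model is an add-k-smoothed table of
`P(phone | previous phone)` plus a sentence-initial distribution;
utterance end is handled by the HMM exit transition, not the LM (the
add-k denominator therefore smooths over the 36 phones only). The
decoder token-passes through the phone loop with the arc between phones
weighted by `lm_scale * log P(next|prev) + ins_penalty`
(defaults 1 and 0, both exposed; there are no canonical values); ties resolve to the lowest phone index, making decoding
deterministic.

## The synthetic parallel corpus

No clinical corpus can be redistributed, so the package ships a
generator whose ground truth is known exactly:

* **Healthy speaker** — one Gaussian per phone in the 13-dim static
  space (diagonal variance in 0.8–1.2), shifted-Poisson durations
  (minimum 3 frames, the shortest path through 3 emitting states; mean 8
  frames ≈ 80 ms, a realistic phone duration). Phone means are drawn
  i.i.d. normal with spread 1.2 and can be rescaled to guarantee a
  minimum pairwise separation. The spread default was calibrated once so
  that the *unenhanced* baseline recognizer operates in the accuracy
  band typical of real esophageal-speech recognition (~60–80 %), leaving
  realistic headroom for enhancement; it was not tuned per experiment.
* **Pathological distortion** — a fixed non-singular affine spectral map
  (random orthogonal basis, per-axis scales 0.8–1.25), additive noise
  (sd 0.8), a per-phone per-utterance "instability" offset (sd 0.3)
  emulating the unstable excitation of esophageal voice, and a temporal
  warp (factor 1.4) rescaling phone durations.

Generation happens in feature space by default — the pipeline consumes
features after extraction, so audio realism buys nothing for algorithmic
testing; a crude filtered pulse-train synthesizer exists solely to
exercise the MFCC front-end. What the generator deliberately does *not*
model: spectral dynamics within a phone (frames are i.i.d. given the
phone), coarticulation, prosody/F0, and the heavy-tailed noise bursts of
real esophageal speech. Passing tests therefore demonstrate algorithmic
correctness and the direction of the enhancement effect, not clinical
performance levels.

## The front-end

16 kHz mono PCM, pre-emphasis 0.97 (first sample passed through, HTK
convention), 25 ms Hamming windows every 10 ms, FFT 512, 26 triangular
Mel filters spanning 0–8 kHz, cepstra c1–c12 (c0 discarded), no
liftering by default — FFT size, filterbank edges and liftering are
conventions exposed in `frame_config()`. The 13th coefficient is the
frame log energy normalized over the utterance; the default is
max-normalization (per-utterance maximum maps to 0, so the track is
invariant under global gain), with z-scoring selectable. Deltas use the
five-frame HTK regression with edge replication at the boundaries.

## Study sizes and determinism

The end-to-end synthetic study uses 50 parallel sentences for conversion
training (G = 16 classes, 3 outer iterations) and 120 recognition
sentences split 100/20, with 2 Gaussians per state — a deliberately
scaled-down configuration of the full-scale design (64 conversion
classes and 16 Gaussians per state on hundreds of sentences) chosen so the full
three-experiment comparison runs in minutes on one core while preserving
every structural property of the pipeline. All stochastic stages draw
from seeds derived from a single experiment seed; identical
configuration and seed reproduce every report bit-identically.

## Known limitations

* Conversion maps frames independently; no trajectory or global-variance
  modeling (the natural next step in the literature).
* Monophones only; no triphones, lattices or speaker adaptation.
* The scorer's backtrace picks one of possibly several co-optimal edit
  scripts (diagonal preferred, then deletion); total edit counts are
  always optimal, but the S/D/I split of a tie may differ from other
  tools.
* `length_normalize()` changes speed and pitch together; residual
  misalignment is absorbed by DTW, which is why a tempo-preserving mode
  is unnecessary here.
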