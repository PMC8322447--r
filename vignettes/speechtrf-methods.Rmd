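---
title: "Methods: TRF estimation, component features, and proficiency prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TRF estimation, component features, and proficiency prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechtrf)
```

## The model

`speechtrf` implements an encoding-model pipeline for EEG recorded while
listeners follow continuous natural speech, with the downstream goal of
predicting a behavioural listening-proficiency score from the shape of the
neural response.

The response model is the multivariate temporal response function (mTRF).
Each stimulus feature $i$ of a scheme $c$ is represented as an impulse train
$S_i^c(t)$ with value 1 at the feature's onset samples and 0 elsewhere, and
the EEG at channel $ch$ is modelled as

$$R_{ch}(t) = \sum_{c}\sum_{i=1}^{N^c} (w_i^c * S_i^c)(t) + \varepsilon_{ch}(t),$$

with kernels $w_i^c(\tau)$ defined over lags $\tau \in [-200, 1500]$ ms
(341 lags at 200 Hz).  Unrolling the convolution yields a sparse lagged
design matrix (feature-major columns, lags ascending, zero-padded at trial
boundaries), and the kernels are the ridge solution
$(X^\top X + \lambda I)^{-1} X^\top y$ with an unpenalized intercept.  The
regularizer is the plain identity: the estimator is literal ridge on the
lagged design, with no smoothness prior.  TRFs are estimated per trial and
averaged with equal weight, both inside cross-validation and for the final
per-participant kernels; the alternative (one concatenated fit) was
rejected because per-trial estimation and averaging is what the
trial-rotation validation actually evaluates.

Four stimulus schemes are built from the same speech annotation: word class
(open/closed), word position (beginning/middle/end tertiles by word ordinal,
with trial-final interrogative sentences excluded), speech rate (fast/slow
at an inclusive 230 syllables-per-minute boundary, computed per sentence
with syllables counted as vowel-nucleus phonemes), and 14 parts of speech
(the 15-class inventory minus "others").  Every scheme is augmented with
the 9 articulatory phoneme classes and sentence beginning/ending rows so
that acoustic-onset and prosodic-boundary responses are absorbed by their
own kernels rather than contaminating the word kernels.

Two choices here were genuinely open.  Position tertiles are assigned by
word ordinal rather than time because "position" is otherwise metric-free
and the ordinal rule is exactly reproducible; boundaries sit at
$\lceil n/3\rceil$ and $\lceil 2n/3\rceil$.  The speech-rate scheme pools
open- and closed-class words when building matrices (both are rate-classed
sentence-wise), while the late-component *features* for speech rate are
read from open-class-style windows; a configuration flag
(`rate_word_classes`) restricts the matrix to open-class words when wanted.

## Regularization-weight selection

$\lambda$ is selected from the grid $\{1, 10, 10^2, 10^3, 10^4\}$ by trial
rotation: per candidate, single-trial TRFs are fit on the training trials,
averaged, and used to predict the held-out trial; MSEs are averaged over
rotations, channels and participants, and the arg-min wins (ties to the
smaller value).  Downstream feature extraction uses one shared
grid-selected $\lambda$ (default $10^2$).

The informative regime for this selector is the one the full pipeline
actually lives in: per-trial designs are *underdetermined* (features
$\times$ lags exceeds the samples in a trial), so unregularized single-trial
fits are non-identifiable and noise forces the selector up the grid.  The
package's verification uses a cohort that preserves this geometry at desk
scale: 6 trials of 16 s at 100 Hz with the 13-row word-class scheme
(2 word rows + 9 phoneme rows + 2 sentence rows; $p = 2223 > n = 1600$).
On noiseless data the smallest grid value wins (pure shrinkage bias); at
0 dB the selected $\lambda$ exceeds it.

## Preprocessing

The conditioning chain is fixed: re-reference to the mean of the earlobe
references, 0.5–50 Hz bandpass FIR (order 3300, designed at the 500 Hz
acquisition rate), resample to 200 Hz, 7 Hz low-pass FIR (order 1320,
designed at 200 Hz).  Filters are linear-phase windowed-sinc (Hamming)
designs; since the pipeline's core outputs are latencies, they are applied
zero-phase by default (the constant group delay of order/2 samples is
compensated), with a causal mode available because the original phase
handling is not knowable.  The bandpass taps are additionally nulled at DC
exactly (the 0.5 Hz edge leaves DC in the transition band of a Hamming
design, and drift must not leak through).  Synthetic recordings are already
band-limited, so the simulation path may skip filtering.

## Component features

Component windows are N1 90–140 ms (negative), P2 190–250 ms (positive),
late component 300–600 ms for open-class features (N400-like) and
500–800 ms for closed-class features (slow negativity).  Amplitudes are
inclusive window means.  Latencies are transferred from the grand average:
the grand-average peak is the polarity-consistent extremum in the window
(ties to the earlier lag; a sign-inconsistent extremum is "no peak" and the
feature becomes missing, as in the original analysis where peakless grand
averages were dropped); each individual TRF is then aligned to the grand
average by dynamic time warping and the individual samples matched to the
grand-peak sample are collected, their lower-median index giving the
individual latency.

DTW uses steps $\{(1,0),(0,1),(1,1)\}$ with absolute amplitude difference
as local cost, no band constraint by default, and operates on z-normalized
series restricted to lags $\ge 0$ — amplitude scale must not dominate the
temporal alignment, and the normalization makes the latency transfer
invariant to kernel gain.  The warping path is deterministic under ties
(diagonal preferred, then the vertical predecessor).

Latency-transfer accuracy is resolution-limited by peak sharpness.  For
early-component widths (~20–30 ms Gaussian SD) planted shifts of up to
±50 ms are recovered within ±1 sample (5 ms) in ≥95% of simulations at
10 dB; for the broad late component (~80 ms) the *true* noisy extremum
itself wanders tens of ms under the same noise, and DTW faithfully tracks
it — the limit is the component's curvature, not the alignment.  The
verification suite therefore plants shifts on a sharp component; the noise
added to simulated TRF series is 7 Hz low-passed, because estimated TRFs
inherit the 0.5–7 Hz band of the preprocessed EEG.

### The 117-entry feature manifest

The published feature count (117) is not accompanied by an enumeration, so
the package fixes one documented reading: three midline electrodes
(Fz, Cz, Pz) × [word class: 2 × 3 components × 2 measures = 36; speech
rate: 2 × late × 2 = 12; word position: 3 pairwise contrasts × late × 2 =
18; parts of speech: 10 late amplitudes = 30 and 7 late latencies = 21],
total 117.  Word-position begin/middle/end values are intermediates only —
the position *contrasts* are the features — which is also the only reading
of the stated exclusions that lands exactly on 117.  Exclusions: latency is
dropped for pronouns, BE verbs and auxiliary verbs (no clear grand-average
peak), and numbers, interrogative words, relative pronouns and conjunctions
carry no late component at all.

## Screening and prediction

Per feature and electrode, Pearson r against the score is computed;
features with $|r| \ge 0.2$ (inclusive) on any electrode are kept,
represented by their best electrode.  "Best" is implemented as max $|r|$
(every reported correlation in the source analysis is negative, so "highest
r" is read as magnitude; the literal most-positive-r alternative is
selectable via `use_abs = FALSE`).  Features are z-scored (SD with
denominator $n-1$) over the full sample — this replicates the original
procedure and is a mild form of leakage; a `zscore = "train"` mode
recomputes the scaling inside each training split, and the package's tests
document that train-only scaling does not outperform full-sample scaling.
Missing feature values (no-peak participants) are median-imputed before
prediction, a choice made here because the original handling is unstated
and the median leaves z-scores stable.

The predictor is the LASSO with loss

$$\mathcal{L}(\beta) = \frac{1}{2N}\sum_{i=1}^N (y_i - \beta_0 -
x_i^\top\beta)^2 + \lambda\sum_{j=1}^M |\beta_j|,$$

minimized exactly as written (intercept unpenalized) by cyclic coordinate
descent with soft-thresholding, convergence when the largest coefficient
change falls below $10^{-7}$.  $\lambda$ comes from 500 evenly spaced
values in $[0, 5]$; that grid literally contains 0, where coordinate
descent is replaced by exact least squares (pseudoinverse if
rank-deficient).  Evaluation is nested: the outer loop leaves one
participant out, the inner loop scores each $\lambda$ by pooled 10-fold
RMSE on the training remainder (folds are a deterministic shuffle derived
from the run seed; RMSE ties go to the smaller $\lambda$, i.e. less
shrinkage), the winning $\lambda$ is refit on the full training split, and
the held-out participant is predicted.  Reported metrics are the Pearson
correlation between true and out-of-fold predicted scores and the mean ±
SD absolute difference; feature contributions are the across-model mean
coefficients, absolute and max-normalized to $[0,1]$.

## What the synthetic cohort emulates — and what it does not

The generator plants everything downstream stages must recover.  Words
arrive by a renewal process with lognormal inter-word intervals (mean set
by the word rate, default 2.5 words/s) — crude, but it creates realistic
impulse overlap inside the 1.7 s lag window, which is the property that
matters for the lagged regression.  Sentences tile each trial; phonemes
give every word at least one vowel nucleus so syllable rates are
computable; POS tags are drawn from a fixed frequency table weighted
toward nouns/verbs/determiners/prepositions (the source materials publish
no frequencies).  Proficiency scores are drawn from a normal distribution
truncated to [328, 687] whose parent parameters are moment-matched so the
*truncated* draw has mean 539.1 and SD 67.4 — the published values
describe the observed, range-limited scores.

Kernels are sums of Gaussian bumps: an N1 (negative, 120 ms base), P2
(positive, 215 ms) and late negativity (455 ms), with latencies and
amplitudes moving linearly with the standardized score.  Default slopes
(−2, −12, −45 ms/SD; amplitude −0, −0.15, −0.10 per SD) are scaled from
the reported contrast between high- and low-proficiency subgroups, whose
means sit roughly 2.5 score-SD apart.  Channels share one kernel shape
scaled by a fixed topography (Cz/Pz largest), matching the midline
dominance of the reported effects.  EEG is rendered as impulse trains
convolved with kernels plus noise — by default a 50/50 power mixture of
1/f and white noise — scaled so the clean-signal/noise variance ratio over
the whole trial hits the requested SNR exactly.

None of this claims physiological fidelity: there are no ocular artifacts,
no acoustic envelope, no syntax, and kernel variation across participants
is strictly the planted linear trend plus jitter.  Passing the recovery
suite therefore demonstrates that the estimator, the latency transfer and
the screening/prediction stack are *correct*, not that real EEG meets
their assumptions.  In particular the planted-correlation cohort
(5 informative features with true $|r| = 0.3$ among 112 noise features,
$n = 100$) mimics the dimensionality of the real feature table, but real
features are mutually correlated in ways the generator does not model.

## Numerical choices and problem sizes

Onsets are discretized by rounding half away from zero (deterministic and
symmetric, unlike banker's rounding); colliding impulses clip at 1; sample
indices are 0-based with time 0 at trial start.  Ridge systems are solved
by Cholesky on the normal equations (designs are sparse 0/1 matrices, so
$X^\top X$ is cheap and well-scaled once $\lambda > 0$); a singular system
at $\lambda = 0$ is an error, not a silent pseudo-inverse.  The verification
suite runs at deliberately reduced sizes chosen to preserve the governing
ratios rather than raw scale: kernel recovery uses the full 33 trials ×
30 s at 10 dB (correlation with planted kernels ≥ 0.95), the λ-selection
check uses the underdetermined 6 × 16 s geometry described above, DTW
recovery uses 200 simulated TRFs, and the end-to-end prediction check uses
100 participants × 117 features with the full 500-value λ grid and 10
inner folds.

## Known limitations

* The published 117-feature enumeration cannot be verified; the manifest
  here is one consistent reading.
* Artifact removal (subspace reconstruction, ICA) is out of scope; real
  recordings must arrive cleaned.
* The late component's DTW latency is intrinsically noisy for broad peaks;
  treat late-latency features as lower-precision than early ones.
* Full-sample z-scoring is reproduced deliberately and leaks scale
  information across CV folds; use `zscore = "train"` for honest
  generalization estimates.
* The forward model is linear; saturation, adaptation and attention-state
  changes are all outside it.
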