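---
title: "Decoding a continuously tagged social emotion from EEG band power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a continuously tagged social emotion from EEG band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevdec)
```

## The problem

Moral elevation — the warm, uplifting feeling of watching someone act
kindly or courageously — fluctuates on the scale of seconds while a viewer
watches a video. `elevdec` implements a complete pipeline for decoding
such a continuously varying social emotion from scalp EEG:

1. **Crowd tagging.** Time-stamped viewer comments (danmaku, the overlay
   comments of East-Asian video platforms) are scored against an emotion
   lexicon to produce one emotion score per second of video.
2. **EEG features.** Multichannel EEG recorded while participants watch
   the same videos is reduced to per-second band power in the canonical
   theta/alpha/beta/gamma bands, then averaged over participants.
3. **Decoding.** A LASSO-regularized linear model maps the 128 group-level
   features to the per-second score, evaluated by repeated nested
   cross-validation.

Because the human data this kind of study uses are not generally
redistributable, the package ships a synthetic-data module that generates
comment streams, sliding-bar self-report traces and multi-participant EEG
from a known latent trajectory with known feature couplings, so every
stage can be validated by parameter recovery.

## Lexicon scoring of comment streams

The dictionary maps terms to integer scores 0, 1 or 2. When a dictionary
is built from rated terms (7-point Likert ratings averaged over raters and
over the touched-feeling and elevation dimensions), ratings are re-coded
as: below 2.5 → 0, in the closed band [2.5, 5.5] → 1, above 5.5 → 2. The
band boundaries are included in the middle score so the three rules are
exhaustive and mutually exclusive.

Each comment is scanned left to right with greedy longest-match against
the union of all lexicon terms; unmatched spans are skipped, which makes
the same scanner work for both spaced (English-like) and unspaced
(Chinese) text. A pluggable tokenizer is unnecessary for the shipped
synthetic vocabulary, but the matching layer (`match_lexicon`) is a single
internal function that an external segmenter could replace without
touching the scoring contract.

Modifiers attach forward: every negator (weight × −1) and degree word
(weight × its multiplier, defaults 0.75 / 1.25 / 1.5 / 2) matched since the
last entry term composes multiplicatively into the weight of the next
entry term, so "not very touching" carries weight −1.5 on "touching".
Trailing modifiers contribute nothing. This is the simplest rule
consistent with how negators and degree words behave in the motivating
examples.

The per-second score of second $i$ of a video is

$$\mathrm{score}_i \;=\; \frac{\sum_{j} w_j \, s_j}{N},$$

where the sum runs over all scored tokens of all comments whose timestamp
falls in the half-open window $[i, i+1)$, $s_j \in \{0,1,2\}$ is the
dictionary score, $w_j$ the modifier weight, and $N$ is the total number
of comments in that whole video. Dividing by the per-video comment total
(rather than the per-second count) keeps videos with different audience
sizes on a comparable scale while letting denser comment seconds score
higher. Timestamps at integer boundaries belong to the later window, so
windows never overlap. Finally the concatenation of all videos' raw
series is z-scored jointly (population SD, so the result has SD exactly 1)
to put videos on one scale; the affine parameters are kept so the raw
series is exactly recoverable. No smoothing is applied by default; an
optional centered moving average (`smooth_score_series`) is exposed.

## EEG band-power features

Preprocessing is a zero-phase 50-Hz notch (RBJ biquad, quality factor 30)
followed by a zero-phase 4th-order Butterworth band-pass at 0.05–47 Hz.
The filter family and order are not dictated by the scientific model; they
are standard EEG practice and are fixed here so results are bit-for-bit
reproducible. All zero-phase filtering uses forward–backward application
with odd-reflection edge padding; the first and last seconds are retained.
An optional `artifact_hook` accepts an ICA-based ocular cleaner; none is
applied by default (the synthetic data contain no ocular artifacts, and
component selection is inherently manual).

The preprocessed signal is band-pass filtered into theta (4–7 Hz), alpha
(8–13 Hz), beta (14–29 Hz) and gamma (30–47 Hz). For every non-overlapping
1-s window the feature is the sum of squares of the `fs` samples, giving
channels × bands = 32 × 4 = 128 features per second under the default
montage. Columns are ordered channel-major (`Fp1_theta`, `Fp1_alpha`, …)
and the order is written into every output header. Trailing samples that
do not fill a second are dropped. Powers are used raw by default; a
`log10_power` switch exists but all shipped validation runs under the
default. Per-participant feature matrices are averaged element-wise into
the group-level matrix; no per-participant normalization precedes the
average.

## LASSO decoding with repeated nested cross-validation

The decoder solves

$$\hat w = \arg\min_w \; \lVert y - Xw - b \rVert^2 + \lambda \lVert w \rVert_1$$

by cyclic coordinate descent on the Gram matrix of the centered design
(compiled code, warm starts along a descending penalty path). Under this
objective the exact all-zero threshold is
$\lambda_{\max} = 2\,\max_j |x_j^{c\top} y^c|$, which
`lasso_lambda_max()` returns. The penalty grid is 50 log-spaced values
from $\lambda_{\max}$ down to $10^{-3}\lambda_{\max}$, recomputed on each
standardized training fold.

Evaluation is a 5-fold cross-validation repeated 100 times (defaults).
Within each training fold, features are z-scored with training statistics
only, and the penalty is chosen by an inner 5-fold cross-validation on the
training portion, minimizing NMSE; exact ties resolve toward the larger
penalty. Selecting the penalty by *in-sample* training error would
degenerate to the smallest penalty on every fold, so the inner-CV reading
is the only self-consistent interpretation of "the penalty that minimizes
training NMSE". NMSE is the test MSE divided by the population variance of
the test targets — the one normalization under which predicting the test
mean scores exactly 1, consistent with NMSE values just below 1 appearing
next to moderate correlations.

Per fold we record test Pearson r, NMSE, the selected penalty and the
coefficient support. When a fold's targets or predictions are constant
(on null data the inner CV frequently selects the null model, whose
prediction is flat), that fold's r is undefined: it is recorded as `NA`,
excluded from aggregates and counted in a warning. Aggregates are
reported both over all fold-level values (500 under the defaults) and
over per-repeat means, since "mean ± SD over 100 repetitions" can be read
either way. A single master seed derives per-repeat seeds, so any repeat
is reproducible in isolation and the whole result is bitwise reproducible.

The univariate analysis (`correlation_map`) computes each feature's
Pearson correlation with the score series and flags significance at
$\alpha / 128$ (Bonferroni).

## What the synthetic data emulate

`gen_latent` draws, per video, Gaussian-kernel-smoothed white noise
(smoothing SD 4 s, lag-1 autocorrelation ≈ 0.98) plus 2–4 positive bumps
of 5–10 s width — the slow multi-bump structure typical of continuous
emotion traces — standardized to mean 0, SD 1 over the concatenated 300 s
(videos of 136, 84 and 80 s).

`gen_comments` posts Poisson(60)/s comments (60/s mirrors the selection
threshold for heavily commented videos). Each comment holds 1–3 entry
terms whose score category follows a multinomial-logit link in the latent
value ($u_0 = e^{-\beta \ell}$, $u_1 = 1.5$, $u_2 = e^{\beta \ell}$,
$\beta = 0.8$), so higher latent values monotonically favor score-2 terms.
Negators and degree words precede a term with probabilities 0.05 and 0.10.
These constants were chosen once as realistic and are config-exposed.

`gen_eeg` builds each channel as a sum of four band-limited Gaussian noise
components (single-pass Butterworth-filtered white noise, unit variance),
plus broadband sensor noise (SD 0.5 relative to the band components' SD 1)
and 50-Hz line interference with random phase. For a planted coupling the
band component's per-second envelope is $1 + g \cdot \mathrm{sign} \cdot
\ell_i$. The default couplings plant negative beta/gamma effects at Fz,
F4, FC2 and the temporo-parietal pair T5/T6 (the older 10-20 labels for
P7/P8), with effect sizes 0.22–0.28.

**Calibration of $g$.** Writing $S_c(f)$ for the coupled component's
spectral density after the feature chain (each zero-phase filter
contributes its $|H(f)|^4$ power gain) and $S_{tot}(f)$ for the total
in-feature density, the per-second power has mean slope
$2 g f_s v_c$ per unit latent with $v_c = \int S_c$, and — for a Gaussian
process observed over 1-s windows — noise SD
$f_s \sqrt{\smash{\int S_{tot}^2}\,/\,n}$ after averaging $n$
participants. Setting the ratio to the target effect gives

$$g \;=\; \frac{r}{\sqrt{1 - r^2}} \cdot
   \frac{\sqrt{\int S_{tot}^2 \, df \, / \, n}}{2 \int S_c \, df}.$$

All integrals are evaluated numerically from the actual filter responses,
so the calibration is closed-form, not tuned. A 20-dataset recovery study
(the acceptance suite) finds the mean recovered F4-beta correlation within
the stated ±0.1 of the planted −0.23; the slight overshoot (≈0.03) comes
from the second-order $(1+g\ell)^2$ term and leakage from the co-planted
gamma coupling at the same channel, both ignored by the first-order
formula. The scaling with participants is exact: the calibrated $g$
shrinks like $1/\sqrt{n}$.

`gen_selfreport` lags the latent through a 2-s causal boxcar, maps it onto
a 0–10 bar (gain 1.5 around midpoint 5), adds white noise (SD 1) and
clips; five raters are averaged.

What the generator does **not** emulate: volume conduction and sensor
covariance (channels are independent), ocular/muscle artifacts,
non-stationary alpha blocking, comment herding, or real language — so a
passing recovery says the *pipeline* is correct and calibrated, not that
real EEG carries this much signal.

## Null calibration and autocorrelation

With zero planted couplings the pipeline should report nothing. Two
findings from the null studies deserve spelling out, because both carry
over to real data.

First, on any one *fixed* dataset the repeated-cross-validated mean r is
not centered at zero: with 128 candidate features and 300 s, the inner
selection latches onto whichever features are spuriously correlated with
the target in that dataset, and the resulting repeated-CV mean r has a
dataset-level spread of roughly ±0.08 that no number of CV repetitions
removes (measured: per-dataset means from −0.11 to +0.12 across null
datasets, grand mean ≈ 0). Repetition only averages away the *split*
noise. Consequently the calibration check runs across independent null
simulations — the grand mean over 50 null datasets is required to sit
within 2 SE (SE across datasets) of zero — and, equally, a real study
cannot certify its decoding r against zero from internal CV repetition
alone; a permutation or independent-data null is needed.

Second, the univariate Bonferroni map's familywise false-positive rate
against the smooth danmaku target measures ≈ 0.10 (11 of 110 null
datasets across two independent runs) instead of the nominal ≤ 0.05. The
nominal Pearson p-values assume exchangeable samples; a target with
autocorrelation ≈ 0.8 at 1 s has fewer effective degrees of freedom than
seconds, roughly doubling the familywise rate even under Bonferroni.
(With an exchangeable iid target the same map is well controlled —
measured ≤ 0.05 over 60 draws — so the inflation is attributable to the
target's smoothness, not the machinery.) The corresponding acceptance
check is deliberately left failing rather than loosened: the map's
p-values on smooth continuous targets should be read as descriptive
ranking, not exact familywise control.

The null familywise study averages 5 simulated participants per dataset
rather than 23: under zero couplings the group average of exchangeable
noise has the same null correlation distribution regardless of the number
averaged, and the smaller count keeps the 50-dataset study inside a few
minutes. The coupling-recovery study simulates only the five coupled
channels, which is distributionally identical for those features because
channels are generated independently.

## Numerical choices and degenerate inputs

- Coordinate descent converges on the maximum absolute coefficient change
  (default 1e-10 for single fits, 1e-8 inside cross-validation); the
  solution matches an independent reference (glmnet) to 1e-5.
- Constant feature columns get standardization scale 1; their centered
  values are zero, so they can never enter the model. Constant targets
  raise errors at z-scoring, NMSE and penalty selection.
- The 0.05–47 Hz band-pass is numerically stable at 250 Hz in transfer
  function form (largest pole modulus 0.9995, verified); band filters are
  likewise applied as stable direct-form recursions.
- Zero-phase filtering pads with odd reflection (10× the filter order)
  before the forward-backward pass, suppressing edge transients without
  discarding data.
- Band noise generation prepends 2 s of warm-up noise that is discarded,
  so the first retained second is already stationary.

## Problem sizes used in validation

The shipped validation runs at the default study dimensions where that is
cheap (single 23-participant datasets for decoding checks; 100 CV repeats
in the acceptance script) and at deliberately reduced sizes where a study
loops over many datasets: 20 CV repeats for the planted-recovery decode,
50 null datasets of 5 participants (2-repeat CV each) for the null
calibration and familywise studies, and 5-channel montages for the
20-dataset coupling recovery. These sizes are the package's own choices,
stated here so they can be scaled up.

## Limitations

- The dictionary pipeline assumes the lexicon's scores are valid for the
  audience that wrote the comments; no spam filtering or topic modelling
  is attempted.
- Decoding is a single linear model family (LASSO); alternative decoders
  are out of scope by design.
- The EDF reader common in EEG toolchains is not bundled; delimited
  matrices with a JSON sidecar are the supported raw-EEG interchange.
- Group-level decoding says nothing about single-participant decodability.
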