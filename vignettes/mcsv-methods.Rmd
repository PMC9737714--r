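---
title: "Critical spectral verge features for multichannel seizure classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical spectral verge features for multichannel seizure classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsv)
```

## The problem

Epileptic seizures appear in scalp EEG as abnormal rhythmic activity, often
accompanied by high-frequency oscillations (HFOs, here activity above roughly
120 Hz) in the channels overlying the seizure focus. Reviewing hours of
21-channel recordings by eye is slow, and most automated detectors either
work on a single channel (losing the spatial information needed to localize
the focus) or use features with no frequency interpretation. This package
implements a channel-wise, segment-wise classification pipeline whose
feature — the *critical spectral verge* (CSV) — is a frequency in Hz, so a
detection can be read directly as "channel T3 showed sustained activity near
130 Hz in this 4-second window".

## The pipeline

For each channel the chain is:

1. **Multiresolution adaptive filtering (MRAF).** The raw channel is
   decomposed with a discrete wavelet transform (db5, four levels by
   default), the detail coefficients are soft-thresholded with a universal
   threshold $T_l = \sigma_l\sqrt{2\ln R}$ ($R$ the sample count), and the
   reconstruction serves as the *desired* signal of a normalized-LMS
   adaptive FIR filter (8 taps, step size $\mu = 0.1$) whose *reference*
   input is the band-passed raw signal. This is run once per frequency band
   (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–Nyquist, and
   the full band), so the output is a set of band-limited, artifact-
   attenuated signals aligned sample-by-sample with the input.
2. **Segmentation.** Each band signal is cut into non-overlapping 4 s
   windows (2 s and 5 s are supported; overlap is configurable). A segment
   is labeled ictal for a channel when annotations covering that channel
   overlap it by at least half a window.
3. **Spectral verge.** Per segment and band, a rectangular-window
   periodogram is computed at the native $1/\mathrm{window}$ Hz resolution.
   The *spectral verge* is the highest frequency bin whose power spectral
   density strictly exceeds the band's average spectral power
   $\mathrm{PS}_{avg}$ (the mean PSD over the band's bins).
4. **Critical spectral verge.** The verge is refined by a flower
   pollination algorithm (FPA): a population of candidate frequencies takes
   global Lévy-flight moves toward the incumbent best
   ($x_i \leftarrow x_i + L\,(g^* - x_i)$) with probability 0.8, and local
   mixing moves ($x_i \leftarrow x_i + \epsilon\,(x_j - x_k)$) otherwise,
   with greedy replacement. The objective rewards the highest frequency
   whose PSD bin beats $\mathrm{PS}_{avg}$; the verge itself seeds the
   population. Because replacement is greedy and the seed is feasible, the
   CSV can never be worse than the verge.
5. **Features and classification.** The six band CSVs of a (channel,
   segment) pair — ordered alpha, beta, gamma, theta, delta, full — form its
   feature vector, plus validity flags for sentinel cells. Features are
   z-scored on each training fold and classified with an RBF-kernel SVM
   (k-NN and 2-class K-Means are available), under stratified 10-fold
   cross-validation. Sensitivity, specificity, accuracy and the average
   detection rate $\mathrm{ADR} = (\mathrm{Sen} + \mathrm{Spe})/2$ are
   reported per fold and aggregated as fold means, alongside pooled
   confusion counts.
6. **Localization.** Each channel's seizure score is the fraction of its
   segments classified ictal; ranking the channels (ties broken by mean
   gamma CSV) points at the focal channels.

A 21×21 channel-pairwise mode is also provided: for a given band and
segment, the matrix of absolute CSV differences (with each channel's CSV on
the diagonal) is reduced by PCA to a 21×1 score vector used as the feature
(`features = "pca"`). The interpretation of the channel matrix as pairwise
CSV differences is this package's construction: it is the simplest
"connectivity" reading that produces the 21×21 → 21×1 shapes, but other
constructions are conceivable. At most two principal components are worth
retaining in practice; beyond that the components carry no separable class
structure.

## Design choices in detail

**Noise scale of the universal threshold.** The threshold
$\sigma\sqrt{2\ln R}$ is only meaningful when $\sigma$ estimates the
*noise* scale. Taking $\sigma_l$ as the plain standard deviation of level
$l$'s coefficients backfires twice: a strong seizure burst inflates its own
level's SD until the threshold exceeds every burst coefficient (the burst
annihilates itself), and a sustained rhythm near a subband edge does the
same to its leakage. A per-level MAD estimate fixes the first failure but
not the second: in a numerical experiment a pure 10 Hz tone sampled at
400 Hz lost about 30% of its power because its leakage into the 12.5–25 Hz
detail level is itself sustained. The default is therefore the classical
VisuShrink estimator — MAD/0.6745 of the *finest* detail level, applied to
every level — which is robust to both transients and sustained rhythms.
Both per-level alternatives remain available through
`decompose_denoise(sigma =)` for comparison.

**Whole-channel versus per-segment denoising.** Thresholds are estimated on
the whole channel, not per analysis window. In a fully ictal 4 s window
*every* coefficient at the burst's level belongs to the burst, so even a
robust estimator would read the burst as noise and remove it; over a whole
recording ictal coefficients are a minority and the estimate stays anchored
to the background.

**Why an adaptive filter at all.** Soft thresholding alone leaves
discontinuities where coefficients cross the threshold. The NLMS stage, fed
the band-passed raw signal and asked to track its denoised counterpart,
produces a smooth output that follows genuine band activity and suppresses
what thresholding identified as artifact. Zero-phase (forward–backward)
4th-order Butterworth band-passes keep every band output aligned with the
annotation clock. With 8 taps and $\mu = 0.1$ the filter converges within a
fraction of a second of signal at clinical sampling rates.

**Band edges.** Delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 Hz are
conventional. Gamma extends from 30 Hz to Nyquist rather than stopping at
~80 Hz because the pipeline's whole point is to capture HFOs above 120 Hz;
at a 400 Hz sampling rate the gamma band is 30–200 Hz. The full band is
0.5 Hz–Nyquist.

**Spectral estimator.** A plain rectangular-window periodogram of the whole
window, no Welch averaging: the verge/CSV definitions index single
frequency points, and averaging would blur exactly the narrow spectral
lines the feature hunts for. The PSD is scaled so its integral over the
grid equals the window's mean square value. The band average
$\mathrm{PS}_{avg}$ is taken over the band's own bins (not the whole grid)
so that the verge condition compares like with like; the grid stops at
Nyquist, where all information of a real signal lives.

**Sentinels.** A perfectly flat band spectrum has no bin strictly above its
mean; the verge is then undefined. Such cells are imputed 0 Hz and carry a
`FALSE` validity flag which is passed to the classifier as an extra binary
feature, so "no verge" is information rather than a crash.

**FPA parameters.** Population 25, at most 100 iterations, stopping after
20 stagnant ones; switch probability 0.8 (the canonical choice); Lévy tail
index $\lambda = 0.5$ by default with $\lambda = 1.5$ (the other common
convention) available; Mantegna's algorithm generates the steps; steps are
scaled by 0.1 of the bound width direction and candidates are clipped to
the band. Bounds default to the band's own frequency range rather than
$[0, f_s]$ so a band's CSV cannot leave its band — a deliberate tightening
that keeps the six feature map rows interpretable. Because the verge seed
is already the feasible optimum of the discrete objective, the optimizer's
practical role is verification and sentinel handling; its value shows when
the objective is replaced or the seed is infeasible, and the elitism
guarantee (never worse than the seed) is what the tests pin down.

**Classifier defaults.** RBF SVM with cost 1 and kernel width $1/d$ on
z-scored features; class weights default to inverse class frequency
because channel-specific seizure labels make the positive class rare (only
focal channels are positive, e.g. ~3% of rows in a 21-channel record with
two focal channels), and an unweighted SVM can collapse to the majority
class. k-NN uses $k = 5$; K-Means uses 2 clusters with 10 seeded restarts
and majority-vote cluster-to-label mapping. Folds are stratified at the
(channel, segment) level; rows are put in a canonical (channel, segment)
order first so results are invariant to the channel order of the input
file. Temporal leakage between folds (adjacent windows of the same
recording landing in different folds) is a known limitation shared with
the segment-level evaluation design.

## The synthetic generator

Real clinical corpora cannot be redistributed, so every stage is exercised
against a generator with known ground truth. Each channel receives $1/f$
pink noise (10 µV RMS) plus a 10 Hz alpha rhythm (20 µV RMS, random phase
per channel). During each configured seizure interval the focal channels
additionally receive a sinusoidal burst at 130 Hz by default whose peak
amplitude is `hfo_amplitude_ratio` (default 3) times the background RMS,
under a Tukey envelope with ~2 s cosine ramps. Blink-like biphasic 1–3 Hz
transients (100 µV) land on frontal channels at 4 events/minute.
Annotations record the exact intervals and focal channels.

Two envelope decisions matter. The ramps are *time*-scaled (2 s, capped at
20% of the interval) rather than fraction-scaled: a fade lasting a fixed
fraction of a long seizure would leave many annotated seconds with
essentially no activity, which is physiologically wrong and makes the
affected windows unlearnable by construction. And the envelope is flat in
the middle rather than a full Hann arch for the same reason: the annotated
extent of an event should actually contain the event.

What the generator does *not* emulate: electrode artifacts other than
blinks, muscle EMG, non-stationary background, inter-channel leakage of
the burst (real HFOs appear attenuated on neighbouring channels), and
realistic seizure morphology (chirps, spike-wave complexes). Passing the
recovery tests therefore shows the pipeline is internally consistent and
recovers planted structure under realistic amplitude ratios — not that it
reaches any particular performance on clinical data.

## Problem sizes and numerical choices

The test-suite and acceptance runs use 21-channel records of 40–198 s at
400 Hz: a 198 s record yields 49 four-second windows per channel (1029
scored rows), matching the largest per-record workload the pipeline is
designed around, and 40 s records are used where many seeded repetitions
are needed. The DWT uses periodized boundaries, which make the transform
exactly orthogonal (coefficient energy equals signal energy) and perfectly
invertible — properties the tests assert to 1e-10; odd lengths are evened
by repeating the last sample and trimmed on reconstruction. Verge
comparisons use strict inequality, so a flat spectrum yields a sentinel
rather than an arbitrary bin. Sample indices are 0-based with half-open
segment bounds; annotation times convert to samples by rounding half away
from zero. EDF output quantizes to 16 bits with per-channel physical
ranges, and all randomness flows from a single integer seed through
deterministic sub-seed derivation (per channel name, band and segment), so
identical configurations reproduce identical feature maps, folds and
reports bit for bit.

## A worked example

```{r example, eval = FALSE}
rec <- generate_recording(synthetic_config(
  n_channels = 21, fs = 400, duration_s = 60,
  seizure_intervals = list(list(start_s = 10, end_s = 30,
                                channels = c("T3", "T4"))),
  rng_seed = 42))
res <- run_pipeline(rec, pipeline_config(seed = 7))
res$report
head(res$localization, 3)
```

On this record the cross-validated report reaches Sen/Spe/Acc of 100 and
the localization map ranks T4 and T3 first and second — the injected focal
channels. The `csv_gamma` column of `res$features` sits at ~130 Hz for
every ictal row, which is the HFO frequency the generator planted.

## Known limitations

* The CSV is scale-invariant: a near-silent band still has a verge, which
  is why classification uses all six bands plus validity flags instead of
  the gamma verge alone.
* Metrics are segment-level; event-level scoring (one hit per seizure) is
  not implemented.
* The EDF writer/reader covers the common 16-bit, single-rate subset of the
  format; annotations travel in a CSV sidecar rather than an embedded
  EDF+ annotation stream.
* Cross-validation folds ignore temporal adjacency, as noted above.
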