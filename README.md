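# mcsv — multichannel seizure classification with critical spectral verge features

`mcsv` classifies epileptic seizure activity channel-by-channel and
segment-by-segment in multichannel scalp EEG, and localizes the focal
channels. Its feature, the **critical spectral verge (CSV)**, is a frequency
in Hz — the highest frequency point of a segment's band spectrum whose power
spectral density exceeds the band's average spectral power, refined by a
flower pollination algorithm (FPA) — so detections are directly
interpretable ("T3 carried ~130 Hz activity in this window"). It is aimed at
researchers in biomedical signal processing who want a transparent,
frequency-domain alternative to black-box detectors, with every stage
testable against synthetic ground truth.

## Method

For a segment $x_k$ of one channel, band $b$ with power spectrum
$PS_k^b(m)$ over frequency points $m$:

- **MRAF pre-processing** — the channel is wavelet-denoised (db5, 4 levels;
  universal threshold $T_l = \sigma_l \sqrt{2 \ln R}$ with soft
  thresholding of detail coefficients), then a normalized-LMS adaptive FIR
  filter per band tracks the band-passed denoised signal from the
  band-passed raw signal, yielding artifact-attenuated band signals
  $X_o(n)$ per $b$.
- **Spectral verge** — $m_s = \{\, m : PS_k^b(m) > PS_{avg} \,\}$,
  $\mathrm{SV} = \max(m_s)$, with $PS_{avg}$ the band's mean PSD.
- **CSV** — the SV seeds an FPA population; global moves
  $x_i \gets x_i + L\,(g^\* - x_i)$ (Lévy step $L$, $\lambda = 0.5$) with
  probability 0.8, local moves $x_i \gets x_i + \epsilon (x_j - x_k)$
  otherwise, greedy replacement, clipped to the band.
- **Classification** — 6-band CSV vectors per (channel, segment), z-scored,
  RBF-SVM (or k-NN / K-Means) under stratified 10-fold CV; metrics
  $\mathrm{Sen}, \mathrm{Spe}, \mathrm{Acc}$ and
  $\mathrm{ADR} = (\mathrm{Sen}+\mathrm{Spe})/2$.
- **Localization** — per-channel fraction of ictal-classified segments,
  ranked.

The methods vignette (`vignettes/mcsv-methods.Rmd`) documents every design
decision, parameter and limitation.

## Worked example

```r
library(mcsv)

rec <- generate_recording(synthetic_config(
  n_channels = 21, fs = 400, duration_s = 60,
  seizure_intervals = list(list(start_s = 10, end_s = 30,
                                channels = c("T3", "T4"))),
  rng_seed = 42))
rec
#> <eeg_recording> 21 channels x 24000 samples @ 400 Hz (60.0 s), 1 annotation(s)

res <- run_pipeline(rec, pipeline_config(seed = 7))
res$report
#> <eval_report> Sen 100.00%  Spe 100.00%  Acc 100.00%  ADR 100.00%
#>   counts: TP 12  FP 0  TN 303  FN 0

head(res$localization, 3)[, c("channel", "score", "mean_csv_gamma", "rank")]
#>   channel score mean_csv_gamma rank
#> 1      T4   0.4       114.1500    1
#> 2      T3   0.4       110.1667    2
#> 3      P3   0.0       112.2167    3
```

The synthetic record plants a 130 Hz burst on T3/T4 between 10 s and 30 s.
All 12 ictal (channel, segment) rows are recovered (Sen 100%), no clean row
is flagged (Spe 100%), and the two focal channels rank first and second in
the localization map with seizure score 0.4 (6 ictal of 15 windows each).
The ictal rows' gamma-band CSVs sit at 130.0–133.0 Hz — the planted HFO
frequency.

A command-line front end is included:

```sh
Rscript inst/cli/mcsv.R simulate --out rec.edf --seed 42
Rscript inst/cli/mcsv.R run --in rec.edf --out-dir results --seed 7
```

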