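---
title: "Methods: turn-load analysis from heart-rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turn-load analysis from heart-rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During simulated flight, turning manoeuvres load a pilot's working memory
unevenly: a climbing turn demands simultaneous management of pitch, power,
bank and airspeed; a descending turn somewhat less; a level turn least.
That load ordering (climbing > descending > leveling) shows up in the
autonomic nervous system: higher load suppresses vagal activity, lowering
short-term heart-rate variability (HRV) and raising heart rate. `turnload`
implements the full analysis chain that turns a wearable heart-rate stream
and flight telemetry into a per-turn cognitive-load classification, and — in
the absence of a public cockpit dataset — a synthetic-data generator that
emulates both streams so every stage is testable end to end.

## The synthetic cohort

`default_flight_plan()` encodes a nine-turn training circuit (two climbing,
four leveling, three descending turns) as straight legs joined by constant
rate heading ramps. Design choices worth knowing:

* **Turn rate 1.5 deg/s.** Light-aircraft training turns at typical bank
  angles are flown between half and full standard rate (3 deg/s); we use the
  gentler half-standard rate, under which the circuit's turns last 20-120 s
  so that 30-s HRV windows genuinely fit inside turns.
* **Telemetry at 1 Hz** with Gaussian instrument jitter (0.3 deg heading,
  5 ft altitude, 1 kt speed).
* **Per-leg start and end altitudes.** The circuit's turn table implies one
  en-route descent between two turns (3000 to 2500 ft); legs therefore carry
  both a start and an end altitude and may drift linearly in between.

RR intervals are generated by cumulative-interval construction — each beat
time is the previous beat time plus the current interval — rather than a
full integral-pulse-frequency-modulation integrator; at this fidelity the
marginal statistics are identical and the construction is transparent. The
instantaneous interval is

```
rr(t) = 60000 / base_hr + lf_amp sin(2 pi lf_freq t)
        + hf_amp sin(2 pi hf_freq t) + N(0, noise_sd),
```

with parameters switching to the active turn's class inside turns and to a
baseline set outside. The default presets (see `default_class_params()`)
place mean heart rate at 95/90/93 bpm for climbing/leveling/descending —
the published per-class mean-heart-rate ordering for these manoeuvres — and
scale `hf_amp`/`noise_sd` so that window-level rmssd lands in the upper-30s
to upper-40s millisecond range with the ordering climbing < descending <
leveling. The amplitude numbers themselves are free parameters of this
generator, chosen once for realism; no quantitative load-to-HRV effect size
is published, so only the *direction* of class differences is calibrated.
With probability `artifact_prob` (default 0.02) an observed interval is
halved or doubled, mimicking missed/false optical beat detections.

What the generator does **not** emulate: respiratory sinus arrhythmia
coupled to actual breathing, slow drifts in autonomic tone, subject-level
heterogeneity in baseline HRV, or the heavier-tailed artifact structure of
real optical sensors. Passing the end-to-end suite therefore demonstrates
the pipeline's internal correctness and its sensitivity under idealised
class structure — not field performance on real cockpit data.

## Artifact repair

Anomalous intervals are flagged when they deviate more than 20% from a
5-point running median (the interval itself included; see
`detect_artifacts()` for why include-self is the robust edge behaviour).
Flagged runs bracketed by valid intervals `y_i` and `y_(i+n)` are replaced
by the linear interpolant `y_(i+k) = y_i + k (y_(i+n) - y_i) / n`. The
printed source formula for this repair carries an `(n-1)` denominator that,
read literally, fails to reach the right bracketing value at `k = n-1`; the
implementation uses the denominator `n` of standard linear interpolation,
the evident intent. Flagged runs touching either end of the series are
dropped rather than extrapolated — extrapolating artifacts fabricates data.

## Turn segmentation

The segmentation rule is a 20-degree heading-change threshold "between
consecutive data points". At 1 Hz telemetry a gentle turn moves only a few
degrees per sample, so a literal single-step reading would never fire; we
read the threshold as the *accumulated* circular heading change over a
sustained ramp, which preserves its semantics at any logging rate. Samples
whose smoothed heading rate exceeds 0.75 deg/s (half the configured turn
rate, far above the jitter floor) mark turning; nearby runs merge across
gaps under 5 s; a run is kept when its accumulated change reaches 20
degrees. Pre/post headings and altitudes are medians over 5 bordering
stable samples.

Turn typing uses a +-50 ft level band: the circuit's smallest genuine
altitude change during a turn is 100 ft, so the band must sit strictly
below 100 ft while absorbing instrument jitter; 50 ft is the midpoint.
"Relatively constant" altitude is not quantified in the source, so the band
is exposed as a parameter.

Windows map to turns by majority time-overlap with a 0.5 minimum overlap
fraction: a 30-s window must spend at least 15 s inside a turn to inherit
its label, and windows straddling nothing are excluded.

## HRV features

Thirty features per 30-s window, windows advancing by 18 s (40% overlap):
sixteen time-domain statistics, seven spectral, six Poincaré, one
geometric. Conventions, all of which matter at this window length:

* Sample SDs (denominator n-1) throughout, which makes
  `sd1 = sdsd / sqrt(2)` an exact identity.
* `nni_20`/`nni_50` count successive differences *strictly* greater than
  20/50 ms; `pnni_*` are the same as percentages. The printed definition
  table lists pnni_50 with a 20 ms threshold — an evident copy error; 50 ms
  is implemented.
* Spectral estimates interpolate the NN series to 4 Hz, detrend linearly,
  Hann-taper and integrate a one-segment Welch periodogram over VLF
  [0.003, 0.04), LF [0.04, 0.15) and HF [0.15, 0.4) Hz. A 30-s window is
  too short for multi-segment averaging, and holds only a fraction of a VLF
  cycle: `vlf` (and hence `total_power`) are method-sensitive at this
  window length and should not be over-interpreted.
* The triangular index uses the standard 1/128-s histogram bin, bins
  aligned to zero.

## Statistical screening

Each feature is routed by a one-sample Kolmogorov–Smirnov test (reference
normal with estimated mean/SD, significance 0.05) to either one-way ANOVA
(normal) or Kruskal–Wallis (non-normal) across the three classes, selecting
features with p < 0.05. Estimating the K-S reference from the sample biases
the test toward *non-rejection* (the Lilliefors caveat); this mirrors
common statistical-package practice, which the screen deliberately
reproduces, and the routing only switches between two tests whose null
calibration is verified by simulation in the test suite. No
multiple-testing correction is applied by default — again mirroring the
reproduced procedure — with Benjamini–Hochberg available via
`adjust = "BH"`. Windows are pooled across subjects by default;
`unit = "subject"` aggregates first, as a sensitivity analysis for the
pooling choice (which the source procedure leaves unstated).

## Classifiers

Sequence samples are length-3 runs of consecutive overlapping windows
within one turn (the sequence length is this package's choice; nothing is
published about it). The default classifier input is the pipeline's own
screening selection — on real cockpit data that screen produced a short key
list (exported as `key_hrv_features()`); on the synthetic cohort, whose
class effects span rate and variability alike, it typically selects most of
the 30 features. Any explicit feature list can be passed instead.

The LSTM recurrence and the self-attention layer are implemented from
their defining equations (gate recurrences; tanh score, softmax weights,
weighted-sum context), with exact backpropagation verified against finite
differences in the test suite. The published recurrence lists the input
gate twice where the candidate-value equation should appear; the candidate
`a~_t = tanh(W_a [h_(t-1), x_t] + b_a)` is restored from its use in the
cell-state update. The score function is tanh (left abstract in the
source). The architecture is LSTM(10, sequences) -> LSTM(10, sequences) ->
self-attention pooled context concatenated onto each hidden state ->
LSTM(20, final state) -> dense(6, ReLU) -> dense(3, softmax).

Training follows the published regimen: min-max scaling fitted on training
data, up-sampling to balance classes, 70/30 stratified split, Adam at
learning rate 0.005, batch 150, at most 50 epochs, early stopping. Package
choices where the regimen is silent: validation fraction 0.15, patience 5,
best-validation weights restored. Two deliberate deviations:

* **Split before balancing** (the source balances first, which leaks
  duplicated samples across the split); balancing is applied to the
  training set only. The published order remains available by balancing
  `samples` before calling `split_samples()`.
* **L2 scope.** The source sentence describing regularisation is
  grammatically ambiguous between "L2 on the LSTM kernels and the dense
  layers" and "L2 on the fully connected layers". At this model size
  (~5000 parameters) a 0.01 penalty over every LSTM kernel exceeds the
  cross-entropy loss at initialisation and reliably collapses training to
  the uniform predictor; the dense-only scope trains stably. The default is
  `l2_scope = "dense"` with `"all"` available, and the 0.01 factor is kept
  as published in both scopes.

Baselines: k-nearest neighbours (vote-fraction probabilities over the
flattened sequence features) and a random forest, plus the plain LSTM
(identical architecture minus attention/concatenation).

One caveat the evaluation design inherits from the sampling scheme:
consecutive sequence samples overlap in their constituent windows, and the
prescribed stratified *sample-level* split places near-duplicates on both
sides of the train/test divide. Flat memorisers (KNN especially) benefit
from this more than the recurrent models do, so on cleanly separable
synthetic data all four models sit within a few test samples of perfect and
their ranking is only meaningful in aggregate over seeds.

## Evaluation

Macro-averaged precision/recall/F1 (the unweighted mean over classes; the
source does not state its averaging, and macro is the standard choice under
imbalance when F1 is the headline metric), one-vs-rest ROC per class with
trapezoid AUC (verified against pair-counting), and an F1-first ranking
with AUC tie-break.

## Problem sizes

The test-suite and acceptance computations run the generator at the
28-subject cohort size with 120-s legs (roughly 2500 beats and 90 feature
windows per subject, about 450 sequence samples), 5 seeds for the model
comparison, and 1000 replicates for screening calibration — sizes chosen so
the full pipeline remains comfortably reproducible on a laptop while
keeping every statistical check adequately powered.

## Known limitations

* The generator's class effects are stylised; no claim is made that
  published per-feature means or model scores are reproduced — they belong
  to a human dataset that is not publicly deposited.
* VLF and triangular-index values at 30-s windows are method-sensitive.
* The screening's K-S routing inherits the estimated-parameter bias; a
  Lilliefors-corrected test would reject normality more often and shift
  features toward Kruskal–Wallis.
* Attention weights are reported per sample but no attribution analysis is
  provided.
* Macro-F1 is ill-conditioned at exact chance: a model whose class
  probabilities are nearly uniform (e.g. an early-stopped network trained
  on permuted labels) produces a near-constant argmax, and a constant
  predictor's macro-F1 on an unbalanced test set is ~0.10-0.17, not the
  1/3 a uniform-random guesser would score. Label-permutation nulls should
  therefore be read as "far below trained performance", not as "exactly
  one third".
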