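---
title: "Cost-sensitive heartbeat classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive heartbeat classification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgcsl)
```

## The problem

Ambulatory ECG recordings contain on the order of 10^5 beats per day, of
which only a small fraction are the arrhythmic beats a cardiologist cares
about. Under the AAMI grouping the five beat classes N (normal and
bundle-branch-block), S (supraventricular ectopic), V (ventricular ectopic),
F (fusion) and Q (unclassifiable) occur in the MIT-BIH arrhythmia database at
roughly 89976 : 2774 : 7002 : 802 : 15 — a 6000-fold spread. A classifier
trained with an unweighted loss on such data collapses toward the majority
class: overall accuracy stays high while the sensitivity for the classes of
clinical interest goes to zero. `ecgcsl` implements a complete pipeline —
denoising, beat segmentation, a 1-D convolutional network with multi-kernel
*temporal transition* modules, and a per-batch *dynamic cost-sensitive loss*
— together with the two standard evaluation paradigms:

* **intra-patient**: beats from all records pooled, stratified 10-fold
  cross-validation (every patient contributes to both training and test
  folds);
* **inter-patient**: disjoint patient sets DS1 (training) and DS2 (test),
  the 22 + 22 record split of the 44 usable MIT-BIH records (paced records
  102, 104, 107, 217 excluded).

## Preprocessing

Baseline wander is estimated by two cascaded sliding medians — a 200 ms
window that flattens the P wave and QRS complex, then a 600 ms window that
removes the T wave — and subtracted from the raw trace. Window lengths are
`round(0.2*fs)` and `round(0.6*fs)` samples forced odd (73 and 217 at
360 Hz), so the median is an exact order statistic; edges are
reflection-padded, which avoids the step artefacts zero padding introduces.
High-frequency and powerline noise is attenuated with an order-12 linear-phase
FIR low-pass (Hamming window design, 35 Hz cutoff, unity DC gain) applied
with group-delay compensation, so all fiducial indices live in raw-signal
coordinates. An order-12 filter at 360 Hz rolls off gently: 50/60 Hz
components are attenuated relative to the passband, not notched out, and the
tests assert exactly that relative ordering.

One caveat worth knowing: re-applying the baseline stage changes the output
by well under 1% RMS when the rhythm is slow enough that the 600 ms window
sees mostly isoelectric samples (measured 0.8% at 50 bpm on synthetic
records), but at 60–80 bpm the T wave occupies enough of the window to bias
the estimate by 2–3%. This is a property of the dual-median method itself;
the implementation agrees with a brute-force sliding-median oracle to
machine precision.

## Segmentation

R peaks are detected with the Pan–Tompkins algorithm using its published
constants: 5–15 Hz band-pass, five-point derivative, squaring, 150 ms
moving-window integration, dual adaptive thresholds with a 200 ms refractory
period, the 360 ms T-wave discrimination rule (slope ratio 0.5), and a
search-back pass at half threshold when a beat is overdue at 1.66 times the
running RR average. Detections are refined to the largest absolute excursion
of the band-passed signal inside the integration window.

T points — for which no published rule exists in this pipeline's sources —
are taken as the sample of maximum absolute amplitude in the window from
80 ms after the R peak to `min(400 ms, 0.7*RR)`; absolute amplitude handles
inverted (discordant) T waves of ventricular beats.

The classifier input is **two consecutive T-to-T intervals**: for a beat
whose R peak falls in the interval `(T[k-1], T[k])`, the preceding interval
`T[k-2] -> T[k-1]` and the target interval `T[k-1] -> T[k]` are each rescaled
to 200 samples by linear interpolation and concatenated into a 400-sample
vector. A beat exactly on a T boundary belongs to the interval starting
there. Beats without a full preceding interval (the first beats of a record)
are dropped and counted, never silently discarded. No amplitude
normalization is applied to segments.

## The network

The model is a 1-D CNN over the 400-sample segment. Each *convolution block*
is convolution (same padding) → batch normalization → rectifier → dropout.
After the first block a max pool reduces the temporal dimension. A *temporal
transition module* runs three parallel convolutions with kernel sizes 1, 3
and 11 (each followed by batch normalization and a rectifier) and
concatenates their outputs along the channel axis, so one level of the
network sees QRS-scale and wave-to-wave-scale morphology simultaneously;
kernel 11 is the default for the wide branch, with 15 and 21 selectable. The
default architecture is

```
conv(16, k5) -> maxpool(2,2) -> transition(8,8,16) -> conv(32, k5)
  -> transition(16,16,32) -> conv(64, k5) -> global average pool
  -> dense(64, dropout 0.75) -> softmax(5)
```

with rectified-linear activations, L2 weight decay 0.003 on convolution and
dense weights, dropout 0.75 at the fully connected layer (the ceiling; 0.2
inside convolution blocks), and plain SGD at learning rate 0.01. The depth,
filter counts and transition placement are configurable
(`model_config()`); setting `transition_filters = NULL` gives the plain-CNN
ablation baseline. All layers — im2col convolution, batch-norm, pooling with
arg-max routing, and their gradients — are implemented in the package and
verified against numerical differentiation to ~1e-8 relative error.

`model_config_small()` (one transition module, 8/16 filters, pool 4,
32 hidden units, ~3000 parameters) is the desk-scale configuration used by
the benchmark experiments below; it exists so that multi-seed paired
training runs complete in minutes on one CPU.

## The dynamic cost-sensitive loss

For every mini-batch of size M with C = 5 classes:

1. **Class weights.** Inverse-frequency balanced weights
   `w_c = n_total / (C * n_c)` are computed on the batch (`CW_b`) and once on
   the whole training set (`CW_D`). A class at its balanced share gets
   weight 1. A class absent from the batch inherits its dataset weight.
2. **Blend.** `CW = sqrt((CW_b^2 + CW_D^2)/2)` — the quadratic mean —
   anchors the batch's possibly erratic class mix to the dataset
   distribution.
3. **Performance term.** From the model's own arg-max predictions on the
   current batch, per-class one-vs-rest false-positive and false-negative
   rates are computed, and combined as an epsilon-smoothed harmonic mean
   `HM_b = ((FPR^-1 + FNR^-1)/2)^-1` (`eps = 1e-7` inside the reciprocals;
   defined as 0 when either rate is 0, the continuous limit, so an
   error-free class incurs no penalty). The two rates are complementary:
   FNR alone would over-reward the minority classes, FPR alone would let the
   model park everything in class N.
4. **Cost.** `phi = CW + HM_b`, one value per class, applied to each sample
   through its true label: `loss = mean_i phi[y_i] * (-log p_i[y_i])`
   (natural log, probabilities clamped at 1e-12). `phi` is a batch
   statistic — no gradient flows through it — and is not renormalized; an
   optional `phi_max` cap is available but off by default.

With balanced data and perfect predictions `phi` is identically 1 and the
loss is exactly the unweighted cross-entropy, which is the degenerate case
the tests pin at 1e-9.

Two readings of the source material were genuinely open and are resolved
here as follows. The class-weight formula is never stated explicitly;
inverse-frequency weighting is adopted because it is the standard
cost-sensitive choice and degrades gracefully to 1 under balance. FPR/FNR
are treated as per-class vectors rather than batch scalars, because the
final cost must differ across classes for the weighting to rebalance
anything.

## Synthetic data

The generator renders each beat as a sum of five Gaussian waves (P, Q, R, S,
T) with class-conditional parameters: canonical P-QRS-T for N;
premature timing (preceding RR shortened 30%) with a flattened P for S; a
wide, high-amplitude QRS with absent P and inverted T for V; the N/V
midpoint for F; and a broad random morphology for Q (real "unclassifiable"
beats have no morphology to emulate). Gaussian parameterization was chosen
over an oscillator model because it yields analytic ground-truth fiducials
(R and T positions are known exactly), which is what closed-loop detector
tests need. Records add a baseline sinusoid, a powerline sinusoid and white
noise, all seeded; annotations carry MIT-BIH symbols so the AAMI mapping is
exercised end to end.

Inter-patient variation is emulated by per-"subject" multiplicative
perturbations (±15%) of wave amplitudes and widths, plus ±5–8% beat-to-beat
jitter. `imbalanced_benchmark()` draws ~5,000 training and ~2,000 test
segments at the full-database class proportions (Q floor-clamped to 2 per
split) with *distinct* subject parameters for the two splits.

What the generator does **not** emulate: real morphological families within
each AAMI class (e.g. bundle-branch-block QRS shapes), non-stationary noise,
electrode motion artefacts, rhythm context beyond the premature-S rule, and
record-level label noise. Tests passing on this generator therefore
demonstrate algorithmic correctness and the qualitative behaviour of the
loss under imbalance — not clinical-grade performance.

## Evaluation and reported numbers

Metrics follow the one-vs-rest definitions: sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)`, positive productivity `TP/(TP+FP)`, accuracy
`(TP+TN)/total`. *Macro* rows are unweighted means over the five classes;
*aggregate* rows are micro statistics from classwise-summed counts — the
package's documented reading of "aggregated" metrics, under which, for any
square confusion matrix, micro sensitivity equals micro positive
productivity. Published aggregate rows for this problem cannot all be
re-derived from their own printed matrices under any simple micro/binary
formula we tried; the per-class and macro rows can, exactly, and those are
what the package validates against (the bundled `reference_confusion()`
matrices reproduce every per-class and macro percentage at 2-decimal
half-away-from-zero rounding, with a ±0.02 allowance on one S row whose
printed value is internally inconsistent with its own matrix). Internal
computation is full precision; rounding is display-only.

The k-fold protocol stratifies beat-wise (the intra-patient paradigm is
defined by beats of every patient appearing on both sides), sums the k test
confusion matrices, and reports metrics from the pooled matrix — classes too
rare for every fold (Q) are assessed only there. The inter-patient runner
asserts record-set disjointness before training. `compare_losses()` trains
cost-sensitive and cross-entropy arms with identical seeds, architecture and
schedule, and reports per-metric differences.

## Experiment sizes and numerical choices

The standard desk-scale experiment (`cs_efficacy_experiment()`) uses 5
replicates × 2 arms of the compact model for 6 epochs (batch 128, SGD 0.01)
on the 5,000/2,000 benchmark — sizes chosen so the full suite runs
comfortably on a single CPU while still exhibiting the phenomenon of
interest: under these conditions the cross-entropy arm typically collapses
to near-zero minority sensitivity while the cost-sensitive arm recovers a
substantial fraction of ventricular beats, mirroring at desk scale the
direction of the published full-scale comparison (sensitivity
76.4→88.8% intra-patient, 52.1→70.6% inter-patient). Full-scale headline
accuracies require the external database and long training and are out of
scope; the package substitutes the exact metric-table reproductions and
these behavioural properties.

Other numerical choices: He-normal weight initialization; batch-norm
momentum 0.9, eps 1e-5; ties in arg-max predictions resolved to the first
class; stratified fold assignment by seeded per-class shuffling; all
randomness in a run keyed off one integer seed (weights, shuffling, dropout,
generator).

## Known limitations

* The WFDB reader covers headers and format-212 signals (the MIT-BIH
  encoding) with annotations as a text sidecar; binary `.atr` annotation
  parsing is not implemented.
* The dual-median baseline stage is heart-rate dependent, as noted above.
* Training is CPU-bound R; the default full architecture is desk-trainable
  but slow — the compact configuration is the practical default for
  experimentation.
* The cost-sensitive loss's class-weight formula is this package's
  documented reading, not a verbatim published formula.
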