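---
title: "Detecting aspiration from pre/post-swallow vowel changes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aspiration from pre/post-swallow vowel changes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Aspiration — food or liquid entering the airway below the vocal folds
during swallowing — leaves acoustic traces on phonation: residue on or
near the vocal folds raises cycle-to-cycle period perturbation (jitter),
amplitude perturbation (shimmer) and breath noise (lower
harmonics-to-noise ratio, HNR). `vowelscreen` implements a screening
pipeline built on that observation: a subject phonates a sustained "ah"
before and after swallowing, and a convolutional network classifies the
*change* between the two recordings as normal or aspiration-like.

The classifier is a paired-input (Siamese by default) convolutional
network over log-power Mel spectrograms:

1. **Encoder.** A width-scalable stack of inverted-residual blocks
   (expansion 1x1 convolution, depthwise 3x3, projection 1x1, batch
   normalization after every convolution, ReLU activations, residual
   connection when stride is 1 and channel counts match). The same
   encoder weights process the pre- and post-swallow spectrograms
   (`shared_encoder = TRUE`); independent branch encoders are available
   by flag. Every channel count scales with `width_multiplier`; the
   reference width is 2.0, the desk default 0.25.
2. **Fusion and decoder.** The two branch feature maps are concatenated
   along channels (decoder input = 2 x encoder output channels), then a
   channel-expanding decoder applies 1x1 convolutions that widen the
   representation x6 and then x2 — a total x12 expansion of its input
   channel budget — before the head.
3. **Head.** Fully convolutional: global mean pooling followed by a 1x1
   convolution emitting a single logit. `sigmoid(logit)` is
   P(aspiration); the decision rule calls a sample *normal* only when
   P(normal) strictly exceeds 0.5, so ties go to the clinically
   conservative side.

Training uses Adam (default moments, no weight decay), binary
cross-entropy with logits, batch size 16 or 32, and a piecewise
learning-rate schedule: constant at `lr0` (reference values 5.00e-5 or
3.00e-5 over 150 epochs), linearly decaying between epochs 100 and 105
to `0.01 * lr0`, then constant. `lrAtEpoch()` is the closed form;
the trainer's per-epoch trace equals it pointwise.

The network, its backward pass, and the optimizer are implemented in the
package itself (R orchestration over RcppArmadillo kernels for
convolution, batch normalization and the short-time Fourier transform).
Analytic gradients are verified against central finite differences in
the test suite.

## Audio standardization

Raw captures are heterogeneous (wav/mp3/m4a, mono or stereo, typically
44.1 kHz). The standardization stages are:

* endpoint trimming — caller-supplied lead/trail cuts plus an optional
  automatic trimmer that removes head/tail frames whose RMS falls below
  1% of the peak frame RMS (20-ms frames);
* stereo split into left/right mono takes;
* band-limited polyphase resampling to the 32-kHz analysis rate
  (output length exactly `round(n * to/from)`);
* segmentation into consecutive, non-overlapping 2-s windows starting
  at the first sample, discarding any sub-2-s tail. Non-overlapping
  windows avoid manufacturing correlated samples; subject-grouped folds
  already prevent within-subject leakage, but there is no reason to
  inflate the pair count artificially;
* clip encoding. The default codec is 16-bit PCM (`pcm16`), the capture
  bit depth; constant-64-kbps mono mp3 encoding is supported through an
  external encoder (ffmpeg or lame) when one is on the PATH and raises
  an explicit environment error otherwise. Decoding restores the
  nominal duration (codec padding trimmed).

## Front end

`MelConfig()` pins the analysis front end: 128 mel bands, 32 kHz,
640-sample (20 ms) periodic Hann window, 320-sample (10 ms) hop,
640-point FFT, centered framing with reflect padding, power magnitude,
Slaney-spaced triangular filterbank from 0 Hz to Nyquist with area
normalization (HTK spacing available by flag), and log compression
floored at `1e-10`. A waveform of `n` samples yields
`1 + floor(n/320)` frames, so a 2-s clip maps to a (128, 201) matrix.
The pre-emphasis coefficient is 0.97, the conventional value for this
front end. Before entering the network each spectrogram is
z-normalized (zero mean, unit variance) so recording level and device
gain cancel; the same normalization is applied at training and
inference time.

`melCosineSimilarity()` implements the device-bias audit (cosine of the
angle between flattened spectrogram matrices). Its published audit
values depend on the study's private recordings, so the operation is
validated by its identities (self = 1, negation = -1, orthogonal = 0).

## Augmentation

Training samples (never test samples) pass through a dynamic
augmentation: exactly two of seven waveform transforms, drawn uniformly
without replacement, applied in draw order with parameters drawn
uniformly from configured ranges — Gaussian noise (sigma
0.0005-0.005), noise at a target SNR (20-40 dB), gain (-12..+12 dB),
polarity
inversion, tanh soft clipping (drive 1-4), a contiguous time mask
(2-20% of samples), and time stretch (rate 0.8-1.25, center-cropped or
zero-padded back to length). The ranges are the package's own choices,
set to be audible but label-preserving — and "label-preserving" has
teeth here: when the class signal lives in the breathiness floor (HNR),
additive noise injected at or below that floor overwrites the label
instead of augmenting the sample. The default noise ranges therefore
sit 5-15 dB above typical phonation noise floors. Time stretching uses
linear-interpolation resampling: augmentation needs plausible temporal
distortion, not archival fidelity, and a polyphase filter redesign per
random draw would dominate the training budget.

## Dataset construction

Pairs are the model's input atoms: within each subject (and within a
substance session when that metadata exists), every pre segment is
paired with every post segment. Fold assignment is at the subject
level — an anonymized identifier never appears in both the training and
test side of any fold — and label-stratified: within each class,
shuffled subjects are dealt round-robin into the k folds. Stratification
is a deliberate strengthening of plain grouped folds: with few
minority-class subjects, unstratified folds can lose a class entirely
from a test split. Random oversampling duplicates minority-label
training pairs (uniformly, with replacement) to exact parity; it is
applied per fold, to training splits only, with an optional
female-only scope mirroring the combined-model convention of balancing
within the scarcer stratum. The store is a single HDF5 file
(`/fold{i}/train` and `/fold{i}/test`, parallel arrays of ids, labels,
sex and byte payloads, with root attributes for the seed, segment
length, rate, codec and bitrate); payload round-trips are byte-exact.

## The synthetic cohort generator

No public recordings exist for this task, so the package ships a fully
parametric source-filter vowel generator: a glottal pulse train with
per-cycle period jitter `N(0, (jitter%/100 * T0)^2)` and amplitude
shimmer `N(0, (shimmer%/100)^2)`, shaped by three second-order
resonators near 800/1200/2500 Hz (the /a/ configuration), plus breath
noise (white noise through the same resonators) scaled to a target HNR,
peak-normalized to 0.9. Baseline parameters describe a healthy
sustained vowel (jitter 0.5%, shimmer 3%, HNR 25 dB; f0 100-140 Hz male,
180-230 Hz female). Each synthetic subject keeps one f0 across phases.
The class signal is placed *only* in the pre-to-post change:
aspiration-group post recordings receive `post_delta` (default +2
percentage points jitter, +6 shimmer, -10 dB HNR), while both groups'
pre recordings and the normal group's post recordings share the
baseline. This specifically exercises the paired architecture — a
single-recording classifier has nothing to learn from the baseline
voice.

What the generator does **not** emulate: real vocal-tract variability
between subjects beyond f0, formant dynamics, room and device coloring,
non-stationary phonation, or the clinical heterogeneity of dysphagia.
Passing the integrity suite therefore demonstrates that the pipeline is
correct and leak-free and that the architecture can learn a pre/post
acoustic divergence — not that the model reaches any particular
clinical accuracy.

## Evaluation

Per fold, on the untouched test split: AUC (midrank Mann-Whitney
formulation, verified in tests against exhaustive pair counting and an
established ROC package), accuracy, sensitivity, specificity, PPV, NPV
(as percentages), F1, and mean BCE loss, plus the final-epoch training
accuracy and loss. Summaries report per-metric mean, a t-distribution
95% CI (`mean +/- t(0.975, k-1) * sd / sqrt(k)`), and the maximum.
Intervals are deliberately not clipped to the metric's natural range:
published fold summaries of this kind print intervals exceeding 100,
which identifies the unclipped normal/t construction. The positive
class is aspiration throughout. Metrics with empty denominators are
reported as undefined (`NA`), never as zero.

## Cohort statistics

`chiSquareTable()` (a thin wrapper over the standard Pearson test)
reproduces the study-population comparisons: the 2x2 sex table with the
Yates continuity correction (statistic 30.76, df 1) and the 2x6
comorbidity tables uncorrected (36.10, 18.54, 8.31; df 5). The
correction choice is identified numerically: the uncorrected 2x2
statistic would be about 32.4, so the published value pins Yates for the
2x2 and no correction elsewhere. `participantFlow()` checks the
enrollment arithmetic (212/73 enrolled, minus age and audio-quality
exclusions, leaving 128/70 = 198). `cohenKappa()` provides the
rater-agreement coefficient; the study's raw ratings are unavailable,
so the published 0.87 is context, not a test value.

## Desk-scale protocol and problem sizes

The reference training protocol (width 2.0, 150 epochs, lr 5e-5/3e-5)
targets GPU hardware and private clinical audio. The package's
integrity runs use a scaled protocol chosen once and fixed:

* cohorts of 100 synthetic subjects (25 per group x sex cell), 2.5-s
  recordings synthesized directly at 32 kHz, one pre/post pair per
  subject;
* 10 subject-grouped stratified folds; width 0.25; batch 16; 15 epochs
  at lr 3e-3 with linear decay over the last five epochs (the
  reference rates are tied to a 150-epoch budget; a 15-epoch run needs
  a proportionally larger step).

Two sizing decisions deserve explanation. First, the learning rate:
Adam from random initialization makes almost no progress in 15 epochs
at 5e-5 (a 15-epoch fold takes only ~90 optimizer steps); a sweep on
three folds of the separable cohort showed clear underfitting below
2e-3; 3e-3 reaches a stable fit within the epoch budget. Second, subjects versus pairs: fold AUC is a rank statistic
over *subjects* (within-subject pairs are strongly correlated), so the
sampling error of the null-cohort mean AUC is governed by subjects per
fold, not by pairs. Five-second recordings give four pairs per subject
but no extra subjects; halving the recording to one pair per subject
and spending the compute on 4x the subjects brings the null mean's
standard error from ~0.14 down to ~0.06, which is what makes "mean AUC
near 0.5 on a label-free cohort" a usable leakage detector. The
5-s, four-pairs-per-subject path stays covered by unit tests.

Under this protocol the three integrity runs behave as designed: the
null cohort (post_delta = 0) stays near chance, the strongly separated
cohort (jitter +2, shimmer +6, HNR -10 dB) is learned essentially
perfectly, and the mean AUC is non-decreasing across
{null, small, large} divergences.

## Numerical choices and degenerate inputs

* Batch-norm uses biased variance for normalization and unbiased for
  running statistics (momentum 0.1, eps 1e-5); evaluation mode uses
  running statistics.
* He-normal weight initialization, seeded; two builds from one seed
  have identical parameters, and a full training run is reproducible
  bit-for-bit given the store and the seed.
* The log floor (1e-10) makes silence map to a constant spectrogram
  (z-normalization then returns all zeros rather than dividing by a
  zero standard deviation).
* Empty waveforms, single-class AUC inputs, zero-norm cosine inputs,
  zero chi-square marginals, sub-2-s inference clips and out-of-range
  schedule epochs all raise explicit errors; metrics with zero
  denominators return `NA`.
* Recordings shorter than one segment yield an empty segment list with
  a warning (not an error), matching the batch-processing setting where
  one bad capture should not abort a cohort.

## Known limitations

* The encoder follows the inverted-residual design at reduced depth; it
  is width-compatible with, but not a per-block reproduction of, the
  large mobile audio-tagging encoders it is modeled on, and no
  pretrained audio weights are used (none are distributable here).
* mp3 support requires an external encoder; environments without one
  use PCM payloads (byte-exact, larger on disk).
* The synthetic generator is a test harness, not a clinical voice
  simulator; no clinical performance claim follows from it.
* Whether the expansion decoder should widen the concatenated channels
  or each branch's channels is ambiguous in prose descriptions of this
  architecture family; this implementation pins "after concatenation"
  and records the choice in the checkpoint.
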