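---
title: "Methods: MI detection and localization from 12-lead ECG beats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MI detection and localization from 12-lead ECG beats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ecgmi` is an end-to-end pipeline for beat-level myocardial infarction (MI)
analysis on standard 12-lead electrocardiograms: a 2-class *detection* task
(healthy control vs MI) and a 6-class *locating* task (healthy control plus
five infarction territories: anterolateral ALMI, anterior AMI, anteroseptal
ASMI, inferolateral ILMI, inferior IMI). This vignette documents the model,
the protocol constants, the synthetic data generator and the numerical
choices, in enough detail to re-derive every number the package produces.

## The network

Every beat window is a 12 × 400 matrix: 12 leads, 400 samples at 100 Hz
(50 samples before the R peak, the R sample, 349 after). The classifier is a
*multi-lead, multi-scale, feature-concatenate* convolutional network:

* **Per-lead branches.** Each of the 12 leads has its own branch with
  independent weights. No information is mixed across leads until the final
  classifier, so each branch learns lead-specific morphology — which is what
  makes territory localization work, since MI classes differ precisely in
  *which* leads are deformed.
* **Scale paths.** A branch holds `S` parallel paths. Path `s` first applies
  `s − 1` *learnable pooling convolutions* (kernel = stride = 2, `F`
  filters, ReLU), each halving the temporal axis, then two unpadded
  kernel-3 convolutions (`F` filters, ReLU), each shortening the axis by
  exactly 2, then global average pooling, producing `F` features. `S = 1`
  is the single-scale N-Net; `S > 1` the multi-scale MSN-Net.
* **Head.** The `12 · S · F` pooled features are concatenated, passed
  through dropout (rate 0.5) and a single soft-max layer with `C` units
  (2 for detection, 6 for locating).

The trainable parameter count has a closed form, per lead and scale path:
`(s − 1)` pooling convolutions at `(2·c_in + 1)·F`, two kernel-3
convolutions at `(3·c_in + 1)·F` (where `c_in` is 1 at the path entry and
`F` afterwards), plus `(12·S·F + 1)·C` for the head. For `S = 1, F = 9,
C = 2` this gives 3674 parameters; the smallest network (`S = 1, F = 1,
C = 2`) has 122. The package computes this count by two independent routes
(the closed form in `count_parameters()` and the layer table in
`build_model_spec()`) and the test suite additionally counts the elements
of instantiated weight arrays; all three must agree on every grid
configuration.

```{r}
library(ecgmi)
count_parameters(model_config(scales = 1, filters = 9, classes = 2))
summary_spec <- build_model_spec(model_config(scales = 3, filters = 4, classes = 6))
print(summary_spec)
```

## Training protocol

`mi_net()` is the single fitting entry point. The full-scale protocol is:
Adam (learning rate 0.001, β₁ = 0.9, β₂ = 0.999), categorical
cross-entropy, parameter updates every 300 inputs, at most 200 epochs,
early stopping with patience 20. The monitored quantity defaults to the
*training* loss: under subject-disjoint cross-validation the held-out fold
must not steer training, and no inner validation split is carved out of the
small per-fold subject pools. Validation monitoring is available through
the `validation` argument when an honest third split exists.

The convolution forward/backward kernels are implemented in C (an im2col
patch matrix feeding a BLAS `dgemm`, with the ReLU fused); pure-R
reference implementations of the same kernels ship alongside them, and the
test suite asserts bitwise agreement between the two on a range of layer
shapes, plus numerical-gradient checks through the whole network.

Determinism: the weight-initialization/dropout seed and the within-epoch
data-order seed are separate arguments. The grid search gives every
configuration the *same* order seed per repeat, so configurations see
identical batch sequences and their accuracy differences are paired, not
confounded with data order.

### Input scaling

Beat windows carry microvolt amplitudes (±1500 µV around the R wave). Fed
raw to He-initialized convolutions, the logits saturate and training stalls
at chance. `model_config(input_scale = 1e-3)` presents the input in
millivolt — the unit clinical ECG instruments report — keeping activations
near unit scale. This is a fixed physical unit conversion, not a
data-dependent normalization, so no statistics leak from test folds.

### Problem sizes for examples and tests

The full study shape (240 records, 7200 locating pieces, 5-fold CV × 15
repeats, 50–55 grid configurations) is what the package defaults encode,
but it is hours of CPU. Examples and the test suite run a scaled-down
study that this package defines as follows (`preset_cohort("tiny")`):
5 subjects and 10 records per class, 40-second records, a 10 × 10 selection
plan with 2 detection pieces per MI record (600 locating / 200 detection
pieces), 3-fold CV, 3 repeats. Two protocol constants are rescaled with
the data, on explicitly stated grounds:

* **Batch size 20.** The full protocol performs ⌈1920/300⌉ ≈ 6.4 updates
  per epoch. With ~134 training pieces per tiny fold, batch 300 would
  degenerate to one update per epoch; batch 20 restores the update density.
* **Epoch cap 60.** Train-loss patience rarely fires once Adam keeps
  strictly improving the loss; on strongly separable tiny data the model
  converges around epoch 20, so a 60-epoch cap is a pure wall-clock bound,
  about three times the observed convergence horizon.

## The synthetic cohort generator

No clinical waveforms ship with the package. The generator produces
PTB-like records that are *structurally* faithful — 12 standard leads,
1000 Hz, 16-bit quantization at 0.5 µV/LSB, header/signal file pairs,
subject-to-record multiplicity — and *morphologically* schematic.

A beat is a sum of five Gaussians (P, Q, R, S, T) on a reference channel,
projected through a fixed per-lead scaling vector. Two variability levels
with strictly separated RNG streams:

* **RIV (patient level, `riv_sd`)** — one draw per subject jitters wave
  amplitudes, centers and widths, the heart rate, and the per-lead T-wave
  inversion indicators. Scoped by the patient seed, so all records of a
  subject share a template.
* **AIV (beat level, `aiv_sd`)** — every beat jitters RR intervals and wave
  amplitudes. Scoped by the beat seed, together with baseline wander (two
  random sinusoids per lead in 0.15–0.40 Hz) and white measurement noise.

MI classes perturb only their territory leads (e.g. IMI: II, III, aVF):
a constant ST-segment plateau shift (default 150 µV, with 20 ms cosine
ramps so the plateau mean equals the configured shift exactly), Q-wave
amplification (×3) and probabilistic T-wave inversion (0.5).
`default_class_effects(effect_scale =)` scales all three jointly, giving a
single class-separability dial: at 0 the class label is provably
independent of the signal (records of different classes under the same
seeds are bit-identical), at 1 the default study conditions hold.

**Realism limits.** The generator makes no attempt at realistic QRS
micro-structure, respiratory modulation, ectopy, electrode artifacts, or
inter-lead correlation beyond the fixed scaling vector. It exists so that
the pipeline has ground truth: known R-peak positions, known class
mechanism, known subject boundaries. Published accuracies on clinical data
cannot be reproduced on it, and none are claimed; what *is* reproduced is
the arithmetic of the protocol and the qualitative learnability ordering.

## Preprocessing

1. **Anti-aliased decimation 1000 → 100 Hz.** A zero-phase odd-length FIR
   low-pass (cutoff 0.8 × the target Nyquist, unit DC gain, reflection
   padding) evaluated only at retained samples. DC passes exactly; content
   above the new Nyquist is attenuated by more than 20 dB.
2. **Baseline removal.** Subtraction of a running median with a 0.857 s
   window (one cardiac cycle at 70 bpm), rounded to an odd sample count;
   constants map to exactly zero.
3. **R-peak detection.** A Christov-style adaptive threshold on a
   "complex lead" (smooth → differentiate → rectify → smooth) built from
   lead II: a steep-slope component M with post-QRS hold and linear decay,
   an integrating noise floor F, and a beat-expectation component R that
   lowers the threshold as the next beat becomes due. Detections are
   relocated to the raw-lead absolute maximum within ±50 ms.
4. **Segmentation.** One 12 × 400 window per R peak (50 + R + 349);
   windows crossing record boundaries are dropped and counted, never
   padded.

## Dataset construction

Balance is enforced by seeded random undersampling at two levels: 40
records per class, then 30 beat windows ("pieces") per record, giving
7200 locating pieces (1200 per class). The detection dataset reuses the
same selection: every HC piece is kept and each MI record contributes 6
pieces, so 1200 HC vs 5 × 240 = 1200 MI. Balance is asserted, not
silently repaired.

Cross-validation folds are assigned to *subjects*, never records or
pieces: within each class, patients are shuffled (seeded) and placed on
the lightest fold by piece count. `audit_leakage()` asserts patient
disjointness on every split and runs automatically inside `repeated_cv()`.

## Evaluation and statistics

Clinical indexes from the pooled per-repeat confusion matrix: ACC, SEN,
SPE, F1 (percent); zero denominators yield `NA` rather than errors. The
AUC is the Mann–Whitney rank statistic (probability a random positive
outscores a random negative, ties counting one half), which is identical
to U/(n⁺·n⁻) — the test suite asserts that identity and agreement with
pROC. Model comparison uses the Mann–Whitney U test on per-repeat index
vectors: exact p-values by full enumeration of the null distribution
(subset-sum dynamic programming) when both samples have ≤ 20 observations
and no ties, otherwise the normal approximation with tie and continuity
corrections; stars at p < 0.05/0.01/0.001.

## Reproducibility model

Everything is a pure function of explicit seeds. A master cohort seed
derives per-subject and per-record seeds; selection plans, fold splits,
weight initialization, dropout and batch order each take their own seed or
derive one from a base seed by a labelled multiplicative hash
(`derive_seed`). No global RNG state is consumed or mutated: every seeded
operation saves and restores `.Random.seed`.

```{r}
b <- build_dataset(preset_cohort("tiny", seed = 3), "detection",
                   selection_plan(10, 10, 2, seed = 3), k = 3, seed = 1)
cv <- repeated_cv(model_config(1, 4, 2), b, k = 3, repeats = 3,
                  base_seed = 11,
                  train = train_config(batch_size = 20, max_epochs = 60))
print(cv)
```
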