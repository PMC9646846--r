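---
title: "Decoding action concepts from multi-subject EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding action concepts from multi-subject EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When many people watch the same short video that evokes an action concept
(*cooking*, *flying*, ...), their EEG responses differ — each brain encodes
the concept through its own idiosyncratic lens — yet they also share
something: a common notion of what the stimulus is, and especially of what
it is *not*. This package studies that shared component computationally.
Per-subject classifiers are trained to decode the action class from single
EEG epochs; their class-score (logit) vectors for the same stimulus are then
averaged across subjects before the decision is taken. This *subjects'
consensus* suppresses subject-specific errors, and the resulting
high-quality predictions can supervise a *video-only* model through
generalized distillation — EEG acts as privileged information, available at
training time but not at test time.

Because no public recording of this kind is available, the package ships a
seeded simulator that reproduces the statistical structure the analysis
assumes, and every claim the package makes is verified end-to-end on that
simulator.

## The generative model

`generator_config()` / `generate_world()` implement a hierarchical latent
model:

* each class $k$ has a concept vector $c_k \sim \mathcal N(0, I_d)$
  (default $d = 12$);
* stimulus $j$ of class $k$ has latent
  $v_j = c_k + \varepsilon_j$, $\varepsilon_j \sim \mathcal N(0,
  \sigma_{\text{stim}}^2 I)$;
* subject $s$ observes through a fixed bias transform
  $B_s = I + \beta R_s$ with $R_s$ a random matrix
  ($\mathbb E\lVert R_s v\rVert \approx \lVert v \rVert$), so the trial
  latent is $u_{sj} = B_s v_j + \eta_{sj}$ with small per-trial jitter;
* channel signals are sums of four band-limited carriers (6, 10, 22, 45 Hz —
  one representative frequency per canonical band, placed exactly on DFT
  bins so band-power recovery is unambiguous) whose per-channel amplitudes
  are a fixed linear readout $A = \max(a_0 + W_b\, u_{sj},\ 0.05)$,
  plus white sensor noise; the 1 s pre-stimulus segment contains noise only;
* the video descriptor of stimulus $j$ is a different linear readout
  $M v_j + \nu_j$ with its own (by default larger) noise.

Every subject watches all stimuli of half of the classes, one trial per
stimulus; with the default 50 subjects each stimulus is seen by exactly 25.
All randomness flows from one seed through a fixed stream-splitting scheme
(`derive_seed()`), so identical configurations are bit-identical, epochs can
be regenerated individually, and large designs never need to be held in
memory (`dataset_de_features()` streams one epoch at a time).

### Why these defaults

The default noise scales (`stimulus_noise_scale = 1.8`,
`eeg_noise_scale = 0.3`, `subject_bias_scale = 2.0`,
`video_noise_scale = 4.0`) were fixed once, to place the simulated study in
the regime the analysis is about (chance 10%, single-model EEG accuracy
around 40–50%, video clearly weaker than EEG), and they divide the error
budget deliberately:

* **stimulus noise is shared** across subjects — no amount of consensus can
  average it away, so it sets the accuracy ceiling;
* **subject bias** is the dominant source of inter-subject diversity; each
  subject's model errs differently on the same test stimulus, and averaging
  logits cancels exactly this component — with `subject_bias_scale = 0` the
  subject models effectively coincide and the consensus curve is flat;
* **trial/sensor noise is small**, so it neither masks the bias mechanism
  nor creates a large consensus gain of its own;
* **video noise exceeds EEG noise**, encoding the premise that the concept
  is more accessible in the EEG than in these deliberately indirect videos.

The generator is a statistical stand-in, not a physiological simulation: no
1/f background spectrum, no artifacts, no volume conduction, one carrier
per band, linear readouts. Tests passing on it show that the *pipeline*
recovers the effects its design injects — not that the effects exist in any
particular real recording.

## Preprocessing

Each epoch is a 62 × 1000 matrix (1 s baseline + 3 s stimulus at 250 Hz).
`normalize_channels()` rescales each channel linearly to $[-1, 1]$
(a constant channel maps to zeros — bounded output, no division blow-up);
`extract_analysis_window()` cuts the 750-sample stimulus window and keeps
the baseline for the wavelet path. Normalisation precedes filtering and
feature extraction — the conventional order, exposed rather than hard-wired.

`bandpass()` realises the band restriction as a zero-phase DFT mask by
default: exact rejection outside the passband, exactly zero phase, and
vectorised across channels, which is what makes streaming feature
extraction over thousands of epochs cheap. A forward–backward Butterworth
realisation (`method = "iir"`) is provided for users who prefer a
conventional filter; the contract both must satisfy is the attenuation
post-condition (≥ 20 dB one octave outside the passband), not a filter
family. Two band tables coexist (`band_table()`): the hand-crafted table
(theta 5–7, alpha 8–13, beta 14–30, gamma 31–60 Hz) used by the FFT/DE/
wavelet encoders, and the image table (4–7, 8–13, 13–30 Hz) used by the
topographic maps. The conventional recording chain for real data
(downsample, 0.5–100 Hz, 50 Hz notch, first-second baseline) is available
as optional steps; the simulator emits already-clean epochs.

## The four encodings

**FFT band features.** Per channel, the DFT of the 750-sample window;
the magnitudes of the bins falling inside the band (a 750-sample window at
250 Hz puts frequency $f$ in bin $3f$) are concatenated channel-major.
Magnitudes, not complex parts, feed the classifiers.

**Differential entropy (DE).** For a Gaussian variable,
$h = \tfrac12 \log(2\pi e \sigma^2)$ nats. With the per-sample variance of
a band-passed channel estimated as $P_n / 750$, where
$P_n = \sum_{t=1}^{750} \tilde x_t^{(n)2}$,

$$h_n = \tfrac12 \log(P_n) + \tfrac12 \log\!\left(\frac{2\pi e}{750}\right).$$

Natural logarithms throughout. Zero band power raises an explicit error
rather than returning $-\infty$. `de_feature_matrix()` computes all bands
from one FFT via Parseval — identical (to ~1e−10) to filtering then summing
squares, and an order of magnitude faster.

**Morlet wavelet power.** Complex Morlet convolution with cycle count
linear in frequency from 3.5 cycles at 2 Hz to 18 cycles at 60 Hz; 0.2 s
zero padding on both sides; power evaluated on a time grid decimated by 3;
absolute baseline (mean power in $[-900, -300]$ ms) subtracted per channel
and frequency; band-averaged power concatenated across channels. Only
total (mixed) power is computed — separating induced from evoked power
needs multiple trials per condition, which the per-trial contract rules
out.

**Topographic EEG images.** Electrode positions are projected from the
sphere by the azimuthal-equidistant ("polar") projection (vertex → origin,
equator → radius $\pi/2$), per-band spectral power (sum of squared FFT
magnitudes over the positive-frequency bins of the image band table) is
interpolated onto a 32 × 32 mesh with a thin-plate spline (exact at the
electrodes, smooth in between, 0 outside the scalp disc), and the three
bands are stacked as the image planes in the order theta, alpha, beta. The
interpolation scheme is a deliberate, recorded choice; any smooth scattered
interpolant would do, and the tests only rely on exactness at the nodes
plus smoothness. The shipped montage (`make_montage()`) is a synthetic
spherical-cap layout, not a standard 10-10 cap.

## Classifiers

`train_classifier()` covers three kinds behind one contract — `logits()`
plus argmax prediction with ties broken to the lowest class index:

* **`de_mlp`** — one hidden layer of 248 rectified linear units, dropout
  0.5 (training only; inference deterministic), softmax output; trained
  with Adam on cross-entropy, seed-controlled initialisation and shuffling.
  Epochs/learning rate/batch size are configuration with fixed defaults; a
  fixed epoch budget replaces early stopping because per-subject validation
  sets (~20 epochs) are too small to stop on reliably — dropout and weight
  decay do the regularising.
* **`linear_svm`** — libSVM linear kernel at the default cost $C = 1$
  (via e1071). Pairwise decision values are aggregated into per-class
  scores to honour the logits contract.
* **`linear_student`** — a linear softmax classifier trained by the same
  Adam loop; the distillation student.

Per-subject training is the default (one model per subject on that
subject's epochs); pooled training is a degenerate case of the same
function.

## Subjects' consensus

For one stimulus, `consensus_predict()` averages the chosen subjects'
logit vectors and applies the softmax; logits-averaging is primary, with
probability-averaging available for comparison (the two differ only through
Jensen's inequality; their argmax rarely disagrees in practice).
`accuracy_vs_n_subjects()` resamples random size-$n$ subject subsets per
stimulus (uniform, seeded; the full-subject point is deterministic) and
reports mean ± SD accuracy per $n$. `per_class_roc()` computes one-vs-rest
trapezoidal AUC per class from the softmax scores — equal to the tie-aware
concordance count — and the macro average; classes absent from the test
labels yield flagged `NA`s.

## Distillation

The teacher is the consensus over all subjects who watched each training
stimulus; its soft labels are $s_i = \mathrm{softmax}(\bar z_i / T)$.
The student minimises

$$\frac1n \sum_i \big[(1-\lambda)\, \ell(y_i, \sigma(f(x_i))) +
\lambda\, \ell(s_i, \sigma(f(x_i)))\big]$$

with $\ell$ the (soft-target) cross-entropy. Because cross-entropy is
linear in the target, the objective is trained *exactly* by using the mixed
target $(1-\lambda)\,\mathrm{onehot}(y_i) + \lambda s_i$ — no approximation
is involved, and the $\lambda = 0$ / $\lambda = 1$ limits reduce
mechanically to the pure losses. The temperature is applied to the teacher
only (the student's softmax runs at $T = 1$), following the form of the
soft-label definition; the conventional both-sides variant would only
rescale gradients here. Teacher soft labels are computed once per dataset
and reused across runs — the teacher is deterministic at inference.
`run_grid()` sweeps $T \in \{1, 2, 5, 10, 20, 50\}$,
$\lambda \in \{0.25, 0.5, 0.75, 1\}$ with $n$ independent runs per cell and
selects the reported cell by validation accuracy.

## Fusion and the split protocol

`make_split()` assigns stimuli to train/validation/test in the canonical
140-40-60 proportion (rescaled for other designs), stratified by class via
largest-remainder apportionment (per-class counts within ±1 of exact
proportionality) — plain random splitting can starve a class's test set at
24 stimuli per class. The EEG split is induced by the stimulus split, so no
stimulus's epochs ever straddle splits. Feature standardisation statistics
come from the training split only.

`kernel_fusion()` standardises each feature block, averages the per-block
linear Gram matrices and trains a kernel SVM (kernlab, precomputed kernel,
$C = 1$); averaging linear Grams equals the linear kernel of the
concatenated blocks scaled by $1/\#\text{blocks}$, which the tests verify
to 1e−10. `logit_fusion()` averages two models' logit vectors
element-wise. In the packaged fusion study the blocks are the
subject-averaged DE features (stimulus-level EEG) and the video
descriptors, with the video noise set so the two modalities have comparable
single-modality quality — the complementary-information condition under
which fusion is expected not to fall below the best single modality.

## Numerical choices and degenerate inputs

* Argmax ties break to the lowest class index, everywhere.
* Softmax is computed with the max-shift; shift invariance holds to 1e−12.
* Constant channels normalise to zeros; zero band power errors out.
* The fused Gram must be PSD within `-1e-8` × its largest eigenvalue.
* The thin-plate solve carries a 1e−10 ridge for conditioning.
* Sub-seeds derive from the master seed by a fixed integer-keyed stream
  scheme, never from call order; all derived seeds stay below $2^{31}$.

## Problem sizes used by the tests and scripts

The test suite exercises the full default design (50 subjects, 240
stimuli, 62 channels) for the study-level checks — consensus curve, AUC
gain, distillation direction — with 10 curve resamples and 5 distillation
runs per grid cell, and reduced designs (6–20 subjects, 8–32 channels) for
unit-level checks; `scripts/acceptance.R` re-runs the default design once
plus a three-seed fusion study. These sizes are the package's choice of a
desk-scale experiment: large enough for the effects to be stable, small
enough to re-run routinely.

## Known limitations

* The simulator's linear-Gaussian latent structure makes linear probes
  nearly optimal; learned-feature rankings on it do not transfer to real
  EEG.
* The distillation protocol has the teacher score its own training
  stimuli. A teacher that is (near-)perfect in-sample emits soft labels
  close to the one-hot truth, and since the mixed objective with one-hot
  soft labels is identically the plain cross-entropy, distillation then
  collapses toward temperature-based label smoothing — a weak effect for
  shallow students. Cross-fitted (out-of-sample) teacher labels would
  avoid this but are a different protocol, so they are not the default.
* Wavelet features implement mixed power only.
* The SVM logits are aggregated pairwise decision values, not calibrated
  scores; they are used for prediction, never for consensus averaging.
* Consensus requires multiple subjects per *test* stimulus; designs
  without overlap degenerate to single-subject prediction.
* The JSON dataset container is for desk-scale interchange; large designs
  should be regenerated from their configuration (which is bit-exact).
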