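---
title: "Silent-speech decoding from biaxial strain gauges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silent-speech decoding from biaxial strain gauges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A silent-speech interface (SSI) decodes intended words from non-acoustic
biosignals recorded while a user mouths words without voicing them. This
package implements, end to end and at desk scale, an SSI built on epidermal
piezoresistive strain gauges: four biaxial sensors (a horizontal and a
vertical gauge per site, eight channels in all) track facial skin deformation
at 300 samples/s for 2 s per utterance, and a three-dimensional convolutional
network classifies the resulting spatiotemporal tensor into word classes.
Because the real recordings require human subjects and fabricated devices,
the package ships a synthetic-data generator that emulates the statistical
structure of such recordings; every protocol (cross-validation, learning
curves, channel ablation, transfer adaptation, relevance mapping) runs
identically on simulated or on-disk data.

# Transduction model

A strain gauge converts strain $\varepsilon = \Delta L/L$ into a relative
resistance change $\Delta R/R$ with gauge factor

$$G = \frac{\Delta R/R}{\Delta L/L} = 1 + 2\nu + \pi E,$$

where $\nu$ is the Poisson ratio, $\pi$ the piezoresistive coefficient and
$E$ the Young's modulus. For metals ($\pi \approx 0$) the geometric term caps
$G$ near 2; for doped single-crystalline silicon the $\pi E$ term dominates
and $G \sim 100$, which is what makes sub-millimetre gauges usable for this
task. The viscoelastic relaxation time is $T = \eta / E$; a stiff membrane
relaxes in milliseconds and can track articulation. The transduction is
linearised as $\Delta R/R = G\,\varepsilon$ over the elastic range
$|\varepsilon| \le 0.3$: the constant-$G$ model is the simplest one
consistent with a material-level gauge factor, and the package enforces the
range rather than extrapolating.

The voltage divider places the gauge on the supply side with a fixed resistor
$R_f$ to ground and reads $V_{in} = V_s R_f / (R + R_f)$ across the fixed
resistor, from a 3 V supply by default. The divider topology, $R_0$
and $R_f$ are not dictated by the physics; they are configuration-level free
parameters, and
both conversion directions share one topology so the round trip is exact to
floating point.

# Synthetic recordings

Each word class owns a `word_template`: per channel, $K = 3$ Gaussian bumps
(centers $\mu$, widths $\sigma \in [0.05, 0.2]$ s, signed amplitudes up to
1 in $\Delta R/R$ units). Gaussians are the minimal smooth parametric family
for the smooth multi-peak traces this emulates. Paired channels $2s-1, 2s$ of
one site share bump centers and widths, and their amplitudes share sign, so
the two gauges of a biaxial sensor co-deform — this is what makes the
"paired channels correlate more within a site than across sites" property
hold.

A recorded repetition applies, in order: one timing shift
$\Delta \sim N(0, 0.05\,\mathrm{s})$ shared by all channels (articulation
shifts the whole utterance, not individual channels), one relative amplitude
factor $1 + A$, $A \sim N(0, 0.1)$, per-channel slow sinusoidal baseline
drift (amplitude $\le 0.05$, 0.1-0.5 Hz) and white noise
($\sigma = 0.02$ by default). Subjects receive independently perturbed
template copies: per-channel amplitude factors $N(1, 0.15)$ and per-site
center offsets $N(0, 0.03\,\mathrm{s})$, emulating user and placement
dependency. The defaults correspond to the emulated study's conditions
(100 words, two subjects, 100 repetitions per word in total, 2 s at 300 Hz);
the jitter magnitudes are fixed desk-scale choices justified by producing
realistically overlapping repetitions, not by matching any real dataset's
statistics — no quantitative inter-repetition variability was available to
match.

Reproducibility discipline: one root seed; every record, fold, epoch and
repeat derives its own child stream through a deterministic hash
(`derive_seed`), so any record can be regenerated in isolation and the whole
dataset is a pure function of its configuration.

## The planted-window fixture

`plant_discriminative_window()` builds templates that are identical across
classes except inside a chosen time window on chosen channels. It is the
ground-truth fixture for two experiments: channel-information recovery by
ablation, and relevance-map localization. Three design points matter, all
discovered by measurement during development:

1. **Normalization anchors.** Per-channel min-max normalization uses the
   channel's extremes. If a class-specific bump sets a channel's maximum,
   the *entire* background is rescaled class-specifically and class
   information leaks out of the window (we measured out-of-window tensor
   differences of 0.76 between classes whose raw waveforms differed by
   2e-4 there). The shared background therefore carries two large anchor
   bumps (amplitude ±2.5) outside the window that pin every channel's
   extremes identically for all classes; the residual out-of-window
   difference drops to noise level.
2. **Positive landmarks per class.** With randomly signed planted bumps, a
   classifier can encode one class as the *absence* of the other's features;
   that class's relevance map is then structurally diffuse. Planted bumps
   instead sit on evenly spaced slots assigned round-robin to classes, with
   positive amplitudes (0.5-1.0), so every class owns positive in-window
   evidence.
3. **Quiet background.** The shared background is drawn at amplitudes
   0.1-0.3 so the planted structure dominates the waveform inside the
   window while the background still exercises smoothing and normalization.

# Preprocessing

Per channel: min-max normalization to $[0,1]$ (constant traces map to zeros
and are flagged as degenerate), Savitzky-Golay smoothing, and linear
resampling onto a fixed grid; the eight channels then form the model input
$X \in \mathbb{R}^{1 \times 2 \times 4 \times T}$ with row 1 the horizontal
gauges of sites S1-S4 and row 2 the vertical gauges, so spatially adjacent
tensor cells are physically adjacent sensors. The exact channel-to-cell map
is a convention of this package and is recorded in the tensor's
`channel_map`.

Design points that were genuinely open, fixed here:

* **Stage order.** Normalization before smoothing by default, with
  the smoothed trace clipped back into $[0,1]$ and the clipped fraction
  recorded; `normalize_first = FALSE` gives the smooth-then-normalize
  variant whose range is exact without clipping.
* **Filter parameters.** Window 15 samples (50 ms at 300 Hz), polynomial
  order 3: strong noise suppression while preserving ~100 ms articulation
  bumps. Exposed in `preprocess_config()`.
* **Edges.** Mirror padding (reflection without repeating the end sample),
  which avoids endpoint bias and reduces the filter to one convolution with
  the central least-squares weights.
* **Resampling convention.** Output sample $j$ sits at
  $(j-1)\,\mathrm{duration}/\mathrm{out\_len}$, matching the acquisition
  convention, so resampling a trace onto its own grid is the identity.

The pipeline is *not* a projection: smoothing pulls sharp peaks inward and
renormalization re-stretches the range by a few percent, so applying it
twice does not reproduce the first output exactly (pointwise drift up to
~0.1 on sharp peaks). The test suite asserts stability (correlation
> 0.995, bounded drift) rather than exact idempotence.

# The 3D CNN

Seven 3D convolution layers, each followed by instance normalization
(per-sample, per-feature statistics over $H \times W \times T$,
$\epsilon = 10^{-5}$, no affine parameters) and ReLU; no pooling, to
preserve localized spatial information. All layers use kernel (3,3,3),
padding (1,1,1), stride (1,1,1) except Conv3 — kernel (3,1,3), padding
(1,0,1), stride (2,1,2) — which downsamples H from 2 to 1 and T by half
while preserving the four sensor-site columns. The kernel-triple-to-axis
mapping follows the input ordering $(H, W, T)$; because the opposite
convention is also common, the alternative $(T, H, W)$ reading is available via
`conv_spec(axis_order = "THW")`. Conv7's output is flattened into three
fully connected layers (ReLU between FC1/FC2, linear FC3) and trained with
softmax cross-entropy under mini-batch Adam.

Unprinted details fixed here as CPU-scale defaults, all overridable:
channel widths (8,16,16,32,32,64,64), FC sizes (256,128,$n$), learning rate
$10^{-3}$, batch 16, epochs 50. The experiments in the tests and the
acceptance script use a compact variant — widths (4,8,8,8,8,16,16), FC
(64,32), 60- or 300-sample grids, 8-20 epochs — sized so a full study trains
in tens of seconds on one core; the architecture geometry (seven conv
layers, the Conv3 exception, norm/activation placement) is identical at
every size.

The implementation is plain R: convolutions evaluate as a precomputed
im2col gather followed by one BLAS matrix multiply per layer and batch, the
backward pass is the exact adjoint (verified against central finite
differences to ~1e-10), and training is bit-reproducible given a seed.
Ties in argmax predictions break toward the lowest class id everywhere.

# Baselines

* **Correlation classifier:** assign each query the class of the cosine-most
  similar reference signal (flattened preprocessed tensors). The group
  protocol (`correlation_cv`) uses each repetition-group as the reference
  set in turn and averages the per-group accuracies; inside k-fold CV the
  entire training fold serves as references.
* **SVM:** one-vs-rest linear kernel, $C = 1$ (via e1071), on the same
  flattened features — the conservative conventional baseline.

# Evaluation protocols

Cross-validation stratifies folds by class (plain random mixing risks
chance class absence at desk scale) and
reports per-fold accuracies, their arithmetic mean — which is the headline
number and differs from pooled accuracy when folds are unequal — and the
pooled confusion matrix. The learning curve fixes the last fold of the
record groups as a test set and trains on n randomly drawn groups. Channel
ablation enumerates all $\binom{8}{n}$ channel subsets, zeroes the
complement in the raw records (a zeroed channel normalizes to a constant
zero trace), retrains per subset on one fixed stratified split and averages
the subset accuracies; retraining is the reading consistent with reporting
per-subset accuracies, and inference-only masking is available as the cheap
variant. Transfer adaptation freezes the seven conv layers and fine-tunes
the FC stack at one tenth of the learning rate (20 epochs by default),
reporting held-out shifted-domain accuracy as a function of adaptation-set
size including size zero. SNR is defined as the RMS ratio of an active
window to a quiescent window — a simple, assumption-free definition.

# Explainability

`extract_features()` returns FC2 activations; `tsne_embed()` maps them to
2-D with an exact $O(n^2)$ t-SNE (per-point bandwidths matched to the target
perplexity by bisection, symmetrized affinities, early exaggeration,
momentum descent — no t-SNE package exists in this R environment, so the
standard recipe is implemented here and is adequate at desk-scale n);
`silhouette_score()` quantifies class grouping, with singleton-cluster
widths scored 0 by convention.

`rcam()` attributes a prediction to signal regions. Relevance-weighted
class activation mapping exists in several standard instantiations, so two are provided and flagged in the
output: epsilon-rule layer-wise relevance propagation of a *contrastive*
class score (target logit against the mean competitor), channel-summed at
the chosen conv layer (`method = "lrp"`, default), and the gradient of the
target softmax probability weighting the activations elementwise
(`method = "grad"`). Two design points were forced by measurement:

* A *global* per-channel weighting (classic CAM) produces near-uniform maps
  under this architecture, because instance normalization makes every
  position's activation depend on whole-signal statistics; position-resolved
  weighting is required for the maps to mean anything.
* A *non-contrastive* score (the raw target logit) attributes mostly
  class-shared signal; the contrastive score isolates what separates the
  class.

Instance normalization and ReLU are treated as relevance-pass-through
(diagonal maps), the standard treatment for normalization layers. Maps are
positive-part, linearly upsampled along T, broadcast across collapsed
spatial axes, and min-max normalized.

For the localization experiment the map is read at Conv7 with a 300-sample
input grid. Two effects dictate this: the temporal receptive field of the
deep stack is ~23 input samples, which at a 60-sample grid spans a third of
the utterance and smears any window, while at 300 samples it spans ~0.15 s;
and instance normalization leaks a small amount of class information into
every position's statistics, which the deepest, most class-specific layer
keeps best separated from background activity. Even so, roughly 40-50% of
relevance mass legitimately sits outside a window occupying 20% of the
duration — the leak through normalization statistics is a property of the
architecture, not an attribution artifact — so the localization margin over
the 0.5 criterion is structurally thin.

# Experiment sizes

The test suite and the acceptance script run: the separability/chance
studies at 5 classes × 20 repetitions (100 records, 60-sample grids, 8-10
epochs); the localization study at 2 classes × 50 repetitions (300-sample
grids, 20 epochs); transfer at 3 classes × 16 repetitions × 2 subjects;
ablation with the correlation pipeline over all 28 two-channel subsets.
These sizes keep each experiment in the tens-of-seconds-to-minutes range on
a single core while leaving every statistical conclusion (ceiling at 100%,
chance floor inside the binomial CI, sign tests at p < 0.01) well
determined.

# Known limitations

* The generator produces smooth Gaussian-bump waveforms with stationary
  white noise; real strain recordings have articulation-correlated
  non-stationarities, sensor drift across sessions and inter-word timing
  structure that it does not emulate. Passing tests demonstrate correctness
  of the pipeline and the claimed properties on this family, not
  performance on real recordings.
* Accuracy and SNR figures obtainable only with real hardware and human
  recordings are out of scope by design; the protocols, not any particular
  measured values, are implemented.
* Exact t-SNE is $O(n^2)$ and intended for hundreds of points.
* The relevance-map variants are standard but cannot be certified as the
  exact variant used by any particular prior system (see above).
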