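---
title: "Adversarial decoding of motor-imagery EEG: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial decoding of motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sgdal)
```

## The decoding problem

Motor imagery modulates sensorimotor rhythms: imagining a left-hand
movement attenuates mu-band (8–12 Hz) power over the contralateral (right)
central cortex — event-related desynchronization (ERD). A motor-imagery
brain–computer interface must recover the imagined class from a few dozen
labeled trials of multi-channel EEG, a regime in which convolutional
decoders overfit badly. This package implements a semi-supervised
generative and discriminative adversarial learning framework (GDAL, and
its semi-supervised extension SGDAL) for that regime: a convolutional
feature extractor $\mathcal{F}$ and classifier $\mathcal{C}$ are trained
jointly as a discriminator with $M + 1$ output units ($M$ class scores
plus one realness unit), against a generator $\mathcal{G}$ that maps a
100-dimensional Gaussian noise vector to an artificial trial window. The
realness unit lets the discriminator consume generated windows — and, in
SGDAL mode, real unlabeled windows — so that feature learning is driven by
more data than the labeled set alone.

## Objectives

The supervised term is the softmax cross-entropy over the $M$ class units.
Two adversarial forms are implemented, selected by
`loss_config(adv_form = ...)`:

* **Wasserstein with gradient penalty** (`"wasserstein"`). The realness
  unit's pre-activation acts as a critic $c(x)$; the discriminator
  minimizes $-[\,\bar c(x_\text{real}) - \bar c(\tilde x)\,] + \lambda\,
  \overline{(\lVert\nabla_{\hat x} c(\hat x)\rVert_2 - 1)^2}$ with
  interpolates $\hat x = \epsilon x + (1-\epsilon)\tilde x$,
  $\epsilon \sim U[0,1]$ per sample, and $\lambda = 10$. In SGDAL mode the
  unlabeled windows contribute $-\bar c(x_u)$. This is the only sign
  convention under which the penalty regularizes the critic rather than
  rewarding gradient blow-up.
* **Bounded log-realness** (`"log"`). The realness unit is read through a
  sigmoid $\sigma$, and the adversarial terms are the classic GAN
  log-likelihoods $-\overline{\log\sigma(c(x_\text{real}))} -
  \overline{\log(1-\sigma(c(\tilde x)))}$ (plus
  $-\overline{\log\sigma(c(x_u))}$ for unlabeled windows), with the
  non-saturating generator form $-\overline{\log\sigma(c(\tilde x))}$.

The generator additionally minimizes feature matching,
$\lVert \bar f(x_\text{real}) - \bar f(\mathcal{G}(z)) \rVert_2^2$, on the
feature extractor's output.

Why two forms? The Wasserstein critic's gradients do not decay as it wins;
on large problems this is what stabilizes generator training, but at small
problem sizes the persistent critic pull continuously rewrites the shared
feature extractor and measurably damages the classifier sharing it. The
log form's gradients saturate once real and generated windows are well
separated, so the adversarial game perturbs the feature extractor only
while it carries information. The reduced desk-scale protocol therefore
trains with the log form; both forms are exposed, exact, and tested, and
the gradient-penalty machinery is independently verified against
finite-difference oracles.

At desk scale, one further variance-reduction choice matters: the
real-side adversarial expectation is estimated on the labeled mini-batch
plus one extra labeled draw of the same size (the class loss and feature
matching stay on the labeled batch proper). Semi-supervised runs
effectively enjoy this for free through their unlabeled batch; giving the
supervised adversarial mode the same real-side batch size removes a purely
statistical asymmetry between the two.

## Architectures

Three discriminator families are provided, each ending in $M + 1$ units:

* `shallow_convnet_spec()` — temporal convolution (linear), spatial
  convolution spanning all channels with a squaring activation, mean
  pooling, log: a trainable band-power feature extractor. Published-scale
  defaults (40 maps, 1×25 kernel, 75/15 pooling) with size arguments for
  reduced variants.
* `deep_convnet_spec()` — five convolutions (temporal, spatial, then three
  temporal blocks with mean pooling, ELU activations).
* `rstnn_spec()` — one or three spatio-temporal modules, each three 1×9
  temporal convolutions (an unrolled recurrent convolution stack) plus a
  spatial convolution, leaky-ReLU activations, and a tanh dense hidden
  classifier layer. The original dense widths are not published in the
  text available to us; 64 tanh units is a best-effort constant.

Mean pooling is used everywhere (including where a published variant used
max pooling) so that the package has one exactly differentiable pooling
primitive; batch normalization is not used by any variant.

`reverse_to_generator()` turns any feature extractor into its generator:
convolutions are emitted in reverse order, pooling layers are dropped,
each convolution becomes a bilinear time-resize to the forward layer's
input extent followed by a same-padded convolution (or a channel-expansion
map where a spatial convolution collapsed the channel axis), activations
become ReLU with a final tanh, and a dense stem maps $z \in \mathbb{R}^{100}$
to the innermost feature shape. Resize-then-convolve (rather than
zero-insertion deconvolution) avoids checkerboard artifacts in the
generated signals. Same-padding in the generator is required for shape
closure: a valid convolution after the resize would undo it.

## Training loop and numerics

Per mini-batch the discriminator takes one Adam step on the summed
objective; every `n_critic`-th batch the generator takes one step (the
critic/generator cadence of standard adversarial training). All updates
derive from exact backward passes written against finite-difference
oracles; the one approximation is the gradient penalty's parameter
gradient, which needs second-order information and is computed as a
central directional finite difference of the critic's parameter gradient
(Pearlmutter-style curvature approximation, relative error around 1e-6 at
the step size used). The penalty value itself and the input-gradient norms
are exact. The penalty expectation is estimated on a 32-interpolate
subsample of the batch — unbiased, at half the cost.

The published optimizer protocol (Adam, learning rate $3\times10^{-2}$
decaying by $\exp(-10^{-3} t)$ per epoch, batch 64, 100 epochs) is the
`train_config()` default. Seeded runs are bitwise reproducible: every
stochastic element (initialization, shuffling, noise draws, dropout,
interpolation) draws from R's RNG under `config$seed`.

Inference follows the windowed voting rule: every sliding window of a
trial is scored, the argmax over the $M$ class units (the realness unit is
ignored) gives a window vote, and the trial label is the majority vote
with deterministic smallest-index tie-breaking. A 700-sample trial at
window 512 and stride 1 yields the canonical 189 votes.

## Preprocessing

`preprocess_set()` chains: large Laplacian (each channel minus the mean of
its up-to-4 nearest neighbours, where a neighbour qualifies within 1.5×
the montage's median nearest-neighbour spacing — boundary electrodes fall
back to the available ones); zero-phase 4th-order Butterworth band-pass
1–50 Hz; integer-factor anti-aliased decimation to 250 Hz; baseline
correction against the pre-cue second; channel-wise standardization with
statistics fitted on training trials only; extraction of the 4-s post-cue
task segment with 0.6 s trimmed per end, yielding the canonical 22×700
trial. Baseline correction precedes normalization (narrative order of the
standard pipeline). Degenerate (constant) channels are a hard error rather
than a silent `sd <- 1`, to surface broken inputs.

## The simulator

`simulate_trials()` provides ground truth for every downstream test. Five
mu-band sources (band-limited Gaussian noise, 8–12 Hz) are placed over
right-central, left-central, midline and bilateral-temporal cortex and
mixed into the 22-electrode montage through Gaussian spatial profiles with
unit-norm columns — a known linear forward model. Class $k$ multiplies
each source's post-cue amplitude by that source's `class_gain[k]`; the
default 0.3 is a strong ERD, chosen so that a linear band-power decoder
solves the 4-class task at SNR 10 (the reference separability oracle) —
the left-hand class desynchronizes the right-central source and so on,
mirroring the canonical contralateral organization. Background noise is
0.8 parts 1/f-shaped plus 0.2 parts white, scaled per trial so the
baseline source-to-noise power ratio equals the configured `snr` exactly.

What the simulator does *not* emulate: volume-conduction head geometry
(the Gaussian spread is not a BEM), ocular/muscle artifacts, inter-trial
non-stationarity, electrode drift, or inter-subject variability. Passing
tests on this generator therefore demonstrate implementation correctness
and the qualitative semi-supervision ordering under clean conditions, not
performance claims about recorded EEG.

## Interpretation

A trained spatial filter $w$ answers "how do I extract the source", not
"where is the source". `activation_patterns()` applies the forward-model
transform $A = \Sigma_\text{input} W \Sigma_\text{output}^{-1}$, with
$\Sigma_\text{input}$ estimated from the representation actually presented
at the spatial layer's input (after the preceding temporal convolutions)
and a ridge-regularized inverse ($\varepsilon = 10^{-6}\,\text{tr}/k$)
against near-collinear trained filters. Per-class maps are produced by
estimating the covariances over windows of one class at a time.
`topomap()` renders a pattern column by thin-plate-spline interpolation on
the unit disc; the interpolant reproduces the electrode values exactly.
On the simulator's linear ground truth, patterns recover the true mixing
column with $|\cos| \ge 0.95$ at SNR 10 and degrade monotonically with
SNR, and the single-filter closed form
$\Sigma w / (w^\top \Sigma w)$ is matched exactly.

## The reduced benchmark protocol

`mi_benchmark()` runs the package's end-to-end semi-supervision
comparison at desk scale, sized for a single CPU: per seed, a fresh
simulated dataset (40 training / 20 test trials per class, SNR 10, ERD
0.3) is preprocessed; a reduced Shallow ConvNet (8 maps, 1×13 kernel,
35/7 pooling) is trained for 15 epochs on 64-sample windows cut at stride
24 (mini-batch 16, Adam 3e-3 with betas 0.9/0.999, one generator update
per four discriminator updates, log-realness adversarial form) as vanilla
(25% labels), GDAL (25% labels + generator) and SGDAL (25% labels + the
remaining 75% unlabeled); test trials are scored by majority vote at
window stride 32. Each seed is a full replicate: dataset, label subset and
initialization are all redrawn. The optimizer settings of this reduced
protocol were chosen for stable convergence at these problem sizes (the
published full-scale rate of 3e-2 over 100 epochs is aggressive for
360-window epochs) and differ deliberately from the `train_config()`
defaults.

## Known limitations

* The network engine is CPU-bound R/BLAS plus two compiled kernels; the
  published full-scale protocol (100 epochs, stride-1 windowing of whole
  competition datasets) is out of desk-scale reach, which is why the
  benchmark above is the supported experiment.
* The Wasserstein adversarial form is faithful and tested but not the
  recommended training mode at small problem sizes (see Objectives).
* Recurrent convolutions in the RSTNN variant are unrolled once, i.e.
  realized as stacked convolutions.
* Native competition file formats (GDF/EDF) are not read; data enter
  through the documented plain-text trial archive.
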