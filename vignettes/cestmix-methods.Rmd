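---
title: "Spatial-spectral CEST analysis with cestmix: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-spectral CEST analysis with cestmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chemical exchange saturation transfer (CEST) MRI acquires one image per
saturation frequency offset; each voxel carries a Z-spectrum `Z(offset) =
S/M0` whose dips encode exchangeable-proton pools (amide protons around
+3.5 ppm, aliphatic protons via NOE around -3.5 ppm, creatine near +2.0
ppm, a glucose-related component near +1.2 ppm, and a broad semi-solid MT
background). `cestmix` implements a two-stage pipeline over such data:
whole-image tumor segmentation, then patch-wise binary genotype prediction
inside the segmented region, aggregated to a per-patient probability mean
(`P_mean`) and a majority vote. Both stages share one trainable network; a
phantom generator makes the whole pipeline testable without clinical data.

## The network

The model is a four-stage U-Net-shaped encoder-decoder over `H x W x C`
stacks (`C` = number of offsets, 41 by default). Encoder stages are stacks
of *mixing blocks* with depths `(2, 2, 4, 2)` and widths `W0 * (2, 4, 8,
16)`. A mixing block runs two branches in parallel on the same
layer-normalized input:

* a **depthwise 3x3 convolution** (channel-separable, spectrally selective,
  spatially local), and
* **windowed multi-head self-attention** (4x4 windows, scaled dot-product
  attention computed independently per window; no cross-window leakage).

With bi-directional interactions enabled, the convolution branch produces a
per-channel gate (global average pool, two 1x1 projections with a 4x
bottleneck, sigmoid) applied to the attention output, while the attention
branch produces a per-pixel gate (1x1 reduction to one channel, sigmoid)
applied to the convolution output. Branch outputs are concatenated and
fused by a two-layer GELU feed-forward network (expansion ratio 4) inside a
residual connection. Downsampling is a strided 2x2 convolution with channel
doubling; the decoder mirrors it with 2x2 transposed convolutions, skip
concatenation, and double 3x3 convolutions; a 1x1 convolution + softmax
emits per-pixel class probabilities. Single-branch and no-interaction
ablations, a swapped gate direction, and decoder-side mixing blocks are all
configuration switches of `network_config()`.

Every layer's forward *and* reverse pass is hand-written on base-R matrix
algebra (no deep-learning framework exists in the target environment); the
test suite validates all gradients against central finite differences on
tiny configurations, which is the load-bearing correctness check for the
whole training stack.

### Choices the architecture description leaves open

* **Stage widths.** The channel-expansion rule `2C..16C` is ambiguous about
  whether `C` is the input channel count. Literal `41`-multiples make head
  divisibility awkward, so the default widths are `W0 * (2,4,8,16)` with a
  configurable base width `W0` (32 at full scale, 8 in the reduced test
  models); `literal_widths = TRUE` restores the literal reading.
* **Heads, FFN ratio, normalization.** Heads default to `width/16` (min 1),
  FFN expansion to 4, and pre-norm layer normalization is used inside each
  block — the usual conventions for hybrid conv/attention blocks; none of
  these is pinned by the protocol the package follows.
* **Mixing-block placement.** Blocks live in the encoder only; the decoder
  uses plain double convolutions. `decoder_mixing = TRUE` provides the
  alternate reading.
* **Residual connections** around each block are required for trainability
  at depth 10 and are always on.
* **Input standardization.** Z-values sit near 1 with informative contrast
  of a few percent. Each input stack is standardized (one scalar mean/sd
  per sample) before the stem; without this, desk-scale SGD stalls. The
  spectral-MLP baseline sees raw spectra, since its signal lives in
  absolute Z-amplitudes.

## Training protocol

`train_config()` defaults encode the reference protocol: SGD (momentum 0.9,
weight decay 1e-4), initial learning rate 1e-4, batch size 8
(segmentation) / 128 (genotype), up to 500 epochs with early-stopping
patience 30, 10 linear warmup epochs (factor 0.001) and cosine annealing
(factor 0.001), segmentation class weights 9:1 tumor:background, genotype
class weights equal to inverse class frequencies (normalized to mean 1),
and rotation/flip augmentation. The loss is `alpha * BCE + beta * Dice`
with `alpha = beta = 1` ("weighted combination" is otherwise unspecified);
with a two-class softmax head the binary cross-entropy on the foreground
probability already equals the full two-class cross-entropy, so it is
computed once. "Improvement" for early stopping means a strict change of at
least `1e-5` in the monitored direction.

For genotype training, patches (48x48, stride 12) are cut from the tumor
mask's bounding box; pixels outside the tumor receive `NA` labels and are
excluded from both loss terms and from `P_mean` — the aggregation statistic
is defined over ROI pixels only, and training mirrors that definition.

**Desk-scale schedules.** The clinical protocol (lr 1e-4, 500 epochs,
batches of 128, tens of thousands of SGD updates) is not reachable on one
CPU in minutes. The smoke-scale runs used by the tests and the acceptance
script keep the optimizer family (SGD + momentum + weight decay) and the
warmup/cosine schedule shape but use a peak learning rate of 0.05, global
gradient-norm clipping at 1 (`clip_norm`; plain SGD at large steps
otherwise diverges to NaN on this architecture), full-cohort batches
(small-batch gradient noise combined with momentum 0.9 makes tiny-cohort
runs oscillate between all-foreground and all-background solutions), 3
warmup epochs, tens of epochs, no augmentation, and milder segmentation
class weights (2:1) — at 48x48 with one-patch tumors the background:tumor
imbalance is an order of magnitude smaller than at clinical 240x240, so
the clinical 9:1 weighting over-predicts foreground. These are scale
adaptations chosen once and recorded here; the package defaults remain the
reference protocol.

## Patch geometry

`overlap_fraction(size, stride) = (1 - stride/size) * 100` — 75% at the
default 48/12. Grids anchor at the region's bounding-box top-left with a
final origin per axis clamped so the far edge is covered; regions smaller
than one patch inflate to a single patch about their centroid (so every
non-empty tumor yields at least one patch). Coordinates are 0-based,
row-major, half-open. At stitch time each patch contributes its central
window (crop = stride by default); patches at the grid border keep their
uncropped outer edge so coverage is exact, and overlaps are averaged
uniformly (no Gaussian weighting — the simplest scheme consistent with
"central region" cropping). With `crop <= (size - stride) / 2` satisfied by
the 48/12/12 default, an identity predictor reconstructs its input exactly;
the suite asserts this pixel-for-pixel.

## Phantom: the stated world

`generate_phantom()` draws, per patient: a brain ellipse split into
gray/white matter by a smooth random field, one connected tumor blob
(thresholded smoothed noise, largest component kept), and Z-spectra from a
6-pool Lorentzian forward model `Z = 1 - sum_p A_p (G_p/2)^2 / ((G_p/2)^2 +
(offset - d_p)^2)` on the 41-point grid from -5 to +5 ppm (0.25 ppm
spacing; the M0 reference is saturation-free by convention). Defaults:
white matter gets the strongest NOE (myelin) and MT; tumors get elevated
APT and reduced NOE. Class-1 tumors (IDH-mutant / MGMT-methylated
analogue) receive `+apt_effect` APT and `-noe_effect` NOE relative to
class-0 — the direction follows the cohort description this package
emulates; since external literature is not unanimous, `flip_effect`
reverses it. Degradations are applied in acquisition order: a smooth B0
field displaces each voxel's spectrum (a field value `f` means the true
resonance sits at `f`, implemented by resampling the spectrum at `offset -
f`, edge-clamped and flagged), then Rician noise replaces each channel
value `v` by `sqrt((v + n1)^2 + n2^2)` with independent Gaussian `n1, n2`
(per-channel independence — magnitude-image physics at the fidelity the
tests need).

What the phantom does **not** emulate: Bloch-McConnell exchange dynamics
and saturation-pulse physics, partial-volume mixtures, anatomy beyond a
single ellipse, spatially correlated noise, motion. A green phantom test
therefore establishes that the pipeline's machinery is correct and that the
method recovers planted, well-separated effects — not clinical performance.

## Quantification

`mtr_asym()` computes `Z(-target) - Z(+target)` (APT-weighted at 3.5 ppm),
linearly interpolating off-grid targets (the grid is dense at 0.25 ppm).
`lorentzian_fit()` is bounded nonlinear least squares (L-BFGS-B) with
amplitudes in `[0, 1)`, widths in `[0.1, 60]` ppm, and centers fixed at
nominal positions except water (free within ±0.3 ppm) — fixed-center
fitting is the most stable desk-scale choice, standing in for an
unspecified full protocol. The reported parameters are the best seen across
all objective evaluations, so the reported residual is monotone in the
accepted-iterate sense; on noiseless phantom spectra the fit recovers the
generating amplitudes to better than 1e-4.

## Statistics

Patient-level inference mirrors the reference analysis: percentile
bootstrap CIs from stratified resampling at the patient level (B = 2000 by
default; stratified by genotype class for prediction metrics, unstratified
for segmentation — the stratification variable is otherwise unspecified),
two-sided paired Wilcoxon signed-rank tests (zeros dropped, midranks for
ties; exact by dynamic programming over doubled midranks up to 25
informative pairs — exact even under ties — normal approximation with tie
and continuity correction above), Holm-Bonferroni step-down adjustment, and
the coefficient of variation `100 * sd/mean` (n-1 denominator) across
folds. F1 treats class 1 (mutant/methylated analogue) as positive.
Majority-vote ties (exactly half the ROI voting positive) resolve to class
0; a 0.5/0.5 segmentation posterior resolves to background. Both tie rules
are pinned by tests.

## Numerical and degenerate-input policy

Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside the cross-entropy;
the soft Dice uses an `eps = 1e-7` guard. Empty predicted masks are
excluded from genotype metrics and tallied (`evaluate_cohort()$excluded`).
`P_mean` and the vote error on an empty ROI rather than guessing. Both-empty
masks give Dice/IoU of 1 by convention. All stochastic stages (phantom,
splits, training order, augmentation, bootstrap) draw from explicit seeds
derived from a single run seed, and every such function restores the
caller's RNG state.

## Known limitations

* Training in plain R is ~1 s per 48x48 sample per gradient step; the
  package is a faithful desk-scale implementation, not a GPU training
  stack. Test-scale runs use small cohorts and short schedules, chosen
  once (and recorded above), not tuned per run.
* The phantom's pool amplitudes are plausible configuration, not fitted to
  any cohort; absolute metric values on phantoms say nothing about
  clinical values.
* The exact Wilcoxon p-value is exact under ties, but with heavy ties and
  tiny n the test is conservative, as usual for rank tests.
* `read_nifti()` implements the NIfTI-1 subset the package writes
  (single-file, little-endian, no extensions); it is not a general-purpose
  NIfTI reader.
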