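# cestmix

Spatial-spectral deep learning for CEST MRI: glioma segmentation and
binary genotype prediction from multi-offset Z-spectrum stacks, in pure R.

## What it does and for whom

CEST (chemical exchange saturation transfer) MRI records one image per
saturation offset; every voxel carries a Z-spectrum `Z(Δω) = S/M0` whose
dips encode exchangeable-proton pools (APT at +3.5 ppm, NOE at −3.5 ppm,
creatine at +2.0 ppm, a broad semi-solid MT background, …). `cestmix` is
aimed at quantitative-MRI researchers who want a fully inspectable,
dependency-light implementation of a two-stage pipeline over such data:

1. **Segmentation** — a four-stage U-Net-shaped network whose encoder
   stages are *mixing blocks*: a depthwise 3×3 convolution branch
   (spectrally selective) and a windowed multi-head self-attention branch
   (4×4 windows, spatially global within a window) run in parallel and
   exchange bi-directional gates — a per-channel gate (GAP → 1×1 →
   sigmoid) from the conv branch onto the attention output, and a
   per-pixel gate (1×1 → sigmoid) from the attention branch onto the conv
   output — fused by a GELU feed-forward network in a residual block.
2. **Genotype prediction** — the same architecture trained on 48×48
   patches (stride 12; overlap `(1 − stride/size)·100 = 75%`) cut from the
   segmented tumor, stitched back with crop = stride, and aggregated per
   patient as the probability mean over the N ROI pixels,
   `P_mean(C) = (1/N) Σ_i P_i(C)`, plus a majority vote (threshold 0.5).

Everything is implemented from scratch on base-R matrix algebra — forward
*and* backward passes (validated against finite differences in the test
suite) — because no deep-learning framework is assumed. Around the
network, the package provides a 6-pool Lorentzian phantom generator with
Rician-noise and B0-shift degradation operators, MTRasym and bounded
multi-pool Lorentzian-fit quantification, stratified patient-level splits,
bootstrap confidence intervals, exact paired Wilcoxon signed-rank tests,
Holm–Bonferroni correction, a minimal NIfTI-1 reader/writer, and a CLI
(`inst/exec/cest`).

## Worked example

```r
library(cestmix)

# a synthetic cohort: 12 patients, 48x48, high-contrast tumors
records <- generate_phantom(phantom_config(
  n_patients = 12, image_size = 48, tumor_radius = c(9, 14),
  tumor_apt = 0.12, apt_effect = 0.03, noise_sigma = 0.01, seed = 42))

plan <- make_splits(vapply(records, function(r) r$genotype, 0L),
                    k = 3, seed = 42)
records <- apply_splits(records, plan)

net <- build_network(network_config(in_channels = 41, base_width = 8))
fit <- cest_train(net, records, "segmentation",
                  train_config(lr = 0.05, max_epochs = 70, patience = 69,
                               batch_size = 64, warmup_epochs = 3,
                               seg_class_weights = c(1, 2), clip_norm = 1,
                               augment = FALSE),
                  val_fold = 1)
print(fit)
#> <cest_fit> task = segmentation, 70 epochs trained, best epoch 55
#>   best validation Dice: 0.9041

holdout <- records[sapply(records, function(r) identical(r$split, "holdout"))]
dice(segment_patient(holdout[[1]]$volume, fit), holdout[[1]]$mask)
#> [1] 0.9676259

overlap_fraction(48, 12)   # patch overlap of the default geometry
#> [1] 75
```

The printed Dice (~0.97 on an easy, high-contrast phantom; a few CPU
minutes of training) says the trained two-branch network recovers the
planted tumor; `overlap_fraction` is the analytic patch-overlap rule used
throughout the patching module.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch at smoke
scale — phantom simulation, stratified splitting, training of both tasks,
two-stage holdout inference, patient-level evaluation — and writes the
machine-readable result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/phantom.R` — Lorentzian pools, tissue presets, cohort generator,
  Rician/B0 degradations
* `R/quant.R` — MTRasym, bounded multi-pool Lorentzian fitting
* `R/patching.R` — shift-window grids, extraction, crop-and-stitch
* `R/layers.R`, `R/attention.R`, `R/network.R` — the network and its
  hand-written gradients
* `R/training.R` — losses, LR schedule, early stopping, splits, SGD loop
* `R/pipeline.R` — segmentation → patch → stitch → `P_mean` / vote
* `R/evaluation.R` — metrics, bootstrap, Wilcoxon, Holm, CoV
* `R/nifti.R`, `R/run.R` — I/O and the end-to-end experiment driver

See `vignettes/cestmix-methods.Rmd` for the model, the open design choices
and what phantom-scale results do and do not establish.
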