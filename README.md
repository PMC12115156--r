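# seanet

One-stage, anchor-free object detection for **low-contrast, multi-scale
scenes** — the regime of underwater survey imagery, where camouflaged
organisms differ only marginally from their background and object sizes in
one frame span two orders of magnitude. The package implements the full
detector on the CPU in R (a built-in reverse-mode autodiff engine with
compiled convolution kernels — no deep-learning framework), together with a
parametric generator of annotated low-contrast scenes and a noise/blur
robustness benchmark, so the whole pipeline is reproducible without any
external dataset.

## The model

Three components target the low-contrast regime:

* **MDAM** (multi-scale detail amplification): a five-branch block at the
  backbone's stride-4 stage. Branch *i* ∈ {2,3,4} applies *k*×1 and 1×*k*
  asymmetric convolutions followed by a 3×3 convolution dilated at rate
  *k*, with *k* = 2*i* − 1 (so 3, 5, 7); branch 1 carries the reduced
  input, branch 5 a 1×1 transform of the raw input. Concatenation of
  branches 2–5 is added to branch 1. One-axis receptive extents of the
  dilated branches are 3*k* + 2 = 11, 17, 23 pixels.
* **SE-FPN**: the three backbone taps (strides 8/16/32) are fused by plain
  concatenation through four **Contrast Enhancement Modules**. Each CEM
  runs spatial-channel attention, then a **fore-background contrast
  (FBC)** branch: a sigmoid activation map `Ff` splits the features into
  foreground and background pools `vf, vb` (flattened matrix products),
  which are gated and contrasted, rescaling channels by `cf − cb`;
  three BottleRep residual blocks run alongside and everything is merged
  by a 1×1 block.
* **Composite loss**: `total = 7.5·box + 0.5·cls + 1.5·dfl` with CIoU box
  loss, BCE classification against task-aligned soft targets, and
  distribution focal loss over 16 offset bins, normalised by
  `max(Σ target_scores, 1)`.

See `vignette("seanet-methods")` for the full model description,
assumptions and design decisions.

## Worked example

The tiny CPU profile (160-pixel scenes, width multiplier 0.25) trains in
about six minutes on one core:

```r
library(seanet)

# 200 annotated scenes: low-contrast shapes on textured seabeds, 1-15 each
spec   <- scene_spec(image_size = 160L, contrast_delta = 0.6)
scenes <- generate_dataset(200, spec, seed = 1)
val    <- generate_dataset(50, spec, seed = 500)

model <- seanet_train(scenes, run_config("tiny", seed = 0L))
print(model)
ev <- seanet_evaluate(model, val)
print(ev)
```

```
Semantic enhancement detector
  classes: 3   width multiplier: 0.25   parameters: 311,937
  strides: 8/16/32   DFL bins: 16   trained epochs: 30
Detection evaluation (478 ground-truth boxes)
  AP    0.342
  AP50  0.545
  AP75  0.375
  P 0.601  R 0.606  F1 0.603 (macro, best-F1 operating point)
```

AP is the COCO-style average precision over IoU thresholds 0.50–0.95, AP50
at the forgiving 0.5 threshold; P/R/F1 are macro-averages at the
best-F1 operating point. On this easy split (mean-intensity contrast 0.6)
the tiny model finds and classes most instances; the same protocol at
contrast 0.15 degrades markedly, which is the difficulty axis the
architecture targets. `predict(model, image)` returns a data frame of
boxes with classes and confidences; `robustness_sweep(model, val)`
evaluates the 2 × 5 noise/blur degradation ladder (Gaussian σ ∈
{10..50}/255, motion-blur kernels {5..21}).

A thin command-line front end over the same functions lives in
`inst/cli/seanet.R` (`synth`, `train`, `eval`, `sweep` subcommands).

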