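---
title: "Quantifying immune morphology in lymph nodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune morphology in lymph nodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nodemorph)
```

## The problem

Axillary lymph nodes (LNs) excised for breast-cancer staging are usually
read only for metastatic deposits, yet their morphology also records the
patient's systemic immune response: germinal centres (GCs) — organized
follicular foci where B cells mature — and the lymph-conducting sinus
network, including the subcapsular sinus (SCS) directly beneath the
capsule. nodemorph quantifies these structures on digitised H&E slides and
relates the resulting per-node features to time-to-event outcomes in
triple-negative breast cancer (TNBC) cohorts.

The pipeline has six stages: (1) slide acquisition (here: synthesis),
(2) LN-section detection by Otsu thresholding and contouring, (3) the
involvement label as an input, (4) tile-based GC/sinus segmentation with
fully convolutional networks and stitched whole-section masks,
(5) morphometric quantification, and (6) outcome analysis.

## Segmentation models

All three variants are encoder-decoder fully convolutional networks built
from 'same' stride-1 convolutions, ReLU, 2x2 max-pooling, nearest-neighbour
upsampling and skip concatenation, ending in a 1x1 convolution that yields
one logit per pixel:

* **U-Net** — two 3x3 convolutions per level; channels double per level.
* **Attention U-Net** — additive attention gates on the skip connections:
  a 1x1-projected sum of skip and decoder features passes through ReLU and
  a sigmoid-activated 1x1 map that reweights the skip features.
* **Multiscale U-Net** — the first convolution of every encoder level is
  replaced by parallel *atrous* (dilated) branches at rates 1, 2 and 4,
  concatenated and fused by a 1x1 convolution. A dilation-rate-f branch has
  the receptive field of a plain convolution on an f-fold-downsampled
  image, so one forward pass assimilates fields of view corresponding to
  x10, x5 and x2.5 magnification. We chose this single-pass realization
  over feeding three image pyramids because it keeps the architecture a
  drop-in replacement for the plain U-Net encoder; the pyramid-input
  alternative can be emulated by training separate models per
  magnification tag.

The engine is written in R with the convolution inner loops in C++
(im2col gather plus one matrix multiply; the backward pass re-expresses
the input gradient as a convolution with spatially flipped weights). A
finite-difference check of every parameter gradient across all three
variants is part of the development history; determinism is guaranteed by
driving weight initialization, shuffling and augmentation from explicit
seeds and single-threaded execution.

Training minimizes an equally weighted sum of pixel binary cross-entropy
and soft Dice (the loss of the original work is unavailable, so the choice
is exposed in `train_config()`); the optimizer is Adam at learning rate
1e-3, batch 8. Validation Dice — computed with the same `dice()` operation
used for concordance analysis — selects the returned checkpoint. The
section-level train/validation/test split guarantees that no section
contributes tiles to two partitions.

## The synthetic benchmark

The generator (`slide_spec()` / `generate_slide()`) renders white-background
slides with 1-10 irregular elliptical tissue sections. Each section gets a
thin darker fibrous capsule line, a pale SCS rim directly beneath it, a
branching tree of intranodal sinus channels, and non-overlapping basophilic
GC ellipses. Colours are flat class colours plus Gaussian pixel noise and a
mild low-frequency intensity field. Ground truth is analytic: section
contours, disjoint GC and sinus masks, per-GC ellipse parameters, and
per-section planted features (GC count, mean area `pi*a*b*mpp^2`, mean
circularity via Ramanujan's perimeter, achieved sinus fraction, rim width).

Defaults were chosen once so planted features land in clinically familiar
ranges at 4 um/px: GC areas 0.02-0.1 mm^2, SCS widths 16-32 um straddling
the 20 um prognostic cut, normalized sinus area targeted at 0.12. The rim
width is capped per section so that the rim alone cannot overshoot the
sinus-fraction target, and sinus branches are added until the achieved
fraction is within +/-20 percent of target.

What the generator does **not** emulate: nuclei-level texture, stain
physics and scanner artifacts, metastatic tissue, and annotator noise.
Passing the benchmark therefore demonstrates that the mechanisms —
detection, tiling, learning, stitching, measurement, inference — are
correct and well-calibrated, not that the shipped configuration reaches
clinical-grade accuracy on real H&E.

The segmentation benchmark (`benchmark_slide_spec()`,
`benchmark_train_config()`, `benchmark_model_spec()`) uses 18 one-section
slides (12/3/3 split), 64 px tiles with 16 px overlap, noise sd 30 (heavier
than the generator default so per-pixel colour alone is an imperfect
classifier and spatial context carries signal), and a depth-3, 8-channel
model trained for 6 epochs — about 90 seconds per model on one CPU. The
`multiscale_gc` variant draws GC radii from 8 to 60 px so structures span
several receptive-field scales; the comparison harness trains the
multiscale and single-scale U-Nets on it under identical conditions. The
full-size configuration (depth 5, 16 base channels, 256 px tiles with 50
percent overlap) remains the `seg_model_spec()` / `train_config()`
default.

## Detection and morphometry choices

* Grayscale is Rec. 601 luminance; tissue is the dark class on bright-field
  H&E. Otsu's threshold maximizes between-class variance over 0..255 with
  the inclusive `value <= t` convention; detection then applies closing and
  opening with a radius-5 disc, hole filling (recovering the pale sinus
  lumina), external contour tracing, and a physical minimum-area filter
  (default 0.5 mm^2, a choice — the original artifact filter is unstated).
  Detection runs at a pyramid level bounding the raster at ~4 megapixels.
* Contours are traced at sub-pixel resolution (marching squares at level
  0.5) and lightly smoothed; perimeters from raw boundary-pixel chains
  would inflate circularity denominators by tens of percent. With this
  tracer a rasterized disk scores circularity 0.985 and a square 0.796
  against the analytic 1 and 0.785.
* GC instances are 8-connected components with holes filled, filtered at
  2000 um^2 (about a 50 um follicle; the published instance filter is
  unstated) and by centroid containment in the LN contour. `area_mm2 =
  polygon_area * mpp^2 / 1e6` everywhere; features computed at x10 and x5
  renderings of the same truth agree within 5 percent.
* The SCS width heuristic operationalizes a manual four-point protocol:
  longest-chord major axis, orthogonal axis through the centroid, and at
  each of the four boundary intersections the longest run of sinus pixels
  while walking inward within a 200 um capsule band (a +/-5 degree search
  recovers rays that just miss; misses contribute 0 with a flag). The
  reported width is the mean of the four values.
* Both the dimensionless normalized sinus area (sinus / LN area) and the
  absolute sinus area in mm^2 are reported, because published cut-off
  tables print the normalized quantity with an area unit; exposing both
  lets either reading be dichotomized.

## Concordance

`dice()` defines both-empty masks as agreement 1 (flagged so means can
exclude such sections). Pairwise annotator agreement averages Dice over
annotator pairs and sections, with the standard error taken across
sections — sections, not pixels, are the replication unit; whether the
published inter-annotator means pooled pixels instead is not stated, so
the per-section choice is documented here. Consensus maps count annotators
per pixel; model-vs-consensus Dice uses the nested `counts >= k`
references.

## Outcome analysis

Survival machinery wraps the survival package: Kaplan-Meier curves,
log-rank tests (with an exact conditional permutation option for very
small samples), and Cox proportional-hazards fits reporting hazard ratios
with Wald CIs and a likelihood-ratio model p. The `tnbc` cut-off preset
encodes the published boundary conventions (GC count 2, >=; mean GC area
0.015 mm^2, >; circularity 0.69, >; normalized sinus 0.13, >; SCS width
20 um, >=). The minimal-p cut-point scan examines every observed value
keeping both groups at or above 10 percent of the sample (the original
constraint is unstated) and returns the cut minimizing the log-rank p.
That minimum is optimistically biased: on null simulations roughly 45
percent of replicates reach p < 0.05 versus the nominal 5 — the scan is a
ranking device, and its p should not be read as confirmatory.

The cohort generator draws exponential survival times (constant baseline
hazard, so proportional hazards hold exactly) with the planted hazard
ratio applied to the dichotomized feature group, plus independent
exponential censoring. Patients with zero LNs in a requested involvement
subset are excluded from that analysis rather than imputed. Grade is
carried as an integer score; treating it as categorical is a
model-formula choice left to the caller.

## Problem sizes and numerical choices

The shipped test and acceptance configurations use 280 px benchmark
slides, 18 sections per benchmark, 20 generator seeds for ground-truth
recovery, 50 replicate cohorts of 400 patients for CI coverage, and
2-epoch tiny models for the pipeline smoke run — sizes we consider
adequate to exercise every mechanism while keeping a full run on a single
CPU in minutes. Binarization threshold defaults to 0.5; overlapping tile
predictions are combined by arithmetic mean (seam-free and testable
against single-pass inference); ties in rank tests use mid-ranks with the
normal approximation (exact for small tie-free groups); Otsu ties break
toward the smallest maximizing threshold.

## Known limitations

Hand-rolled training at this scale is a mechanism demonstration; real WSI
deployments need larger tiles, more capacity and longer schedules. The
generator's flat-colour model makes segmentation easier than real H&E even
under heavy noise — and it blunts the variant comparison: with flat class
colours, structure identity is a locally decidable property, the plain
U-Net's receptive field already suffices, and 64 px tiles cap the context
any model can use, so the multiscale and single-scale variants score
within half a Dice point of each other on the benchmark, with the sign of
the difference flipping across seeds. The multi-magnification advantage
reported on real tissue rests on semantics (nuclear detail versus
architectural context) that this generator deliberately does not emulate,
so benchmark equality should not be read as equality on real slides. The
metastasis classifier of the original pipeline is out of scope —
involvement labels are inputs. Checkpoints store weights as JSON text,
which is portable but not compact.
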