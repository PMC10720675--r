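# nodemorph

Quantitative immune morphology of lymph nodes (LNs) on digitised H&E
slides, for computational-pathology researchers studying systemic immune
responses in breast cancer. Beyond checking nodes for metastatic deposits,
the package measures the structures that record a host response — germinal
centres (GCs) and the sinus network including the subcapsular sinus
(SCS) — and relates those measurements to patient outcome.

The pipeline:

1. **Detection** — LN sections are found by Otsu thresholding of the
   luminance image (tissue is the dark class), morphological cleanup,
   and sub-pixel contour tracing, with a physical minimum-area filter.
2. **Segmentation** — binary GC and sinus masks come from fully
   convolutional encoder-decoder networks applied to overlapping tiles and
   stitched by per-pixel averaging. Three variants are provided: a
   standard U-Net, an attention U-Net, and a **multiscale U-Net** whose
   encoder convolutions run parallel atrous (dilated) branches at rates
   1/2/4, fusing receptive fields that correspond to x10/x5/x2.5
   magnification in a single pass.
3. **Morphometry** — per node: GC count, mean GC area (mm²), mean GC
   circularity (the isoperimetric ratio 4πA/P², from sub-pixel contours),
   total and normalized sinus area, and a four-point SCS width heuristic
   `SCS = (w1 + w2 + w3 + w4) / 4` measured where the longest chord and
   its orthogonal axis cross the capsule.
4. **Concordance** — Dice agreement between annotators, consensus maps,
   and model-vs-consensus comparisons.
5. **Outcome** — per-patient aggregation, dichotomization at published
   TNBC cut-offs (GC count ≥ 2, GC area > 0.015 mm², circularity > 0.69,
   normalized sinus > 0.13, SCS ≥ 20 µm) or at data-driven minimal-p
   cut-points, Kaplan–Meier / log-rank, and Cox proportional-hazards
   models with likelihood-ratio tests.

A synthetic-histology generator with analytic ground truth (sections,
capsule, SCS rim, sinus trees, GC ellipses, planted per-section features,
and survival cohorts with planted hazard ratios) makes the whole pipeline
testable without clinical data.

## Worked example

```r
library(nodemorph)

gen <- generate_slide(slide_spec(n_sections = 3, seed = 42))
gen$slide
#> <nm_slide synthetic-slide-42: 900 x 900 px, 4 um/px, level 1>

sections <- detect_ln_sections(gen$slide, min_area_mm2 = 0.1)
sections[, c("section_id", "area_mm2")]
#>   section_id area_mm2
#> 1 S01           1.17
#> 2 S02           1.15
#> 3 S03           0.760

feats <- quantify_sections(sections, gen$truth$gc_mask,
                           gen$truth$sinus_mask, mpp = gen$slide$mpp)
feats[, c("section_id", "gc_count", "mean_gc_area_mm2",
          "normalized_sinus_area")]
#>   section_id gc_count mean_gc_area_mm2 normalized_sinus_area
#> 1 S01               3           0.0373                 0.124
#> 2 S02               4           0.0487                 0.122
#> 3 S03               5           0.0285                 0.127
```

Each row is one LN section: `gc_count` planted follicles recovered
exactly, mean GC areas in the 0.03–0.05 mm² range typical of reactive
nodes, and ~12 % of each section occupied by sinus — matching the
generator's target fraction.

Outcome analysis on a synthetic cohort with a planted hazard ratio of 0.3
for patients averaging ≥ 2 GCs per node:

```r
coh <- generate_cohort(cohort_spec(n_patients = 400, seed = 1))
pat <- aggregate_patient(coh, mode = "mean")
pat$group <- dichotomize(pat$mean_gc_count, cutoff = 2, orientation = "gte")
cox_ph(pat, ~ group)
#> <nm_cox: n = 400, events = 272, likelihood-ratio p = 1.56e-18>
#>   term      estimate    hr std_error conf_low conf_high   p_wald
#> 1 grouphigh    -1.15 0.316     0.136    0.242     0.413 2.64e-17
```

The fitted hazard ratio 0.316 (95 % CI 0.24–0.41) recovers the planted
0.3: patients whose nodes carry germinal centres live longer, and the
likelihood-ratio p confirms the group split. `autoplot(km_logrank(...))`
draws the corresponding Kaplan–Meier curves.

Model training and whole-section inference follow the same pattern
(`build_model()`, `train()`, `segment_section()`); `run_pipeline()` ties
all stages together with a manifest, and `inst/cli/nodemorph` exposes the
subcommands `synth`, `detect`, `run`, `survive`.

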