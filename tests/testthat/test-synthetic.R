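test_that("slide generation honours the construction contract", {
  spec <- slide_spec(n_sections = 3L, seed = 5L)
  gen <- generate_slide(spec)
  expect_length(gen$truth$section_contours, 3L)
  expect_equal(dim(gen$slide$image)[1:2], dim(gen$truth$gc_mask))
  expect_equal(dim(gen$truth$gc_mask), dim(gen$truth$sinus_mask))
  # structures are disjoint by construction
  expect_false(any(gen$truth$gc_mask & gen$truth$sinus_mask))
  # planted GC count equals number of ellipse records per section
  per_sec <- table(gen$truth$gc_params$section_id)
  expect_equal(as.integer(per_sec[gen$truth$planted$section_id]),
               gen$truth$planted$gc_count)
})

test_that("a fixed GC count is planted exactly and rendered pixels match", {
  spec <- slide_spec(n_sections = 2L, gc_count_per_section = 5L, seed = 11L)
  gen <- generate_slide(spec)
  expect_true(all(gen$truth$planted$gc_count == 5L))
  # GC pixels are drawn with gc_rgb up to noise: check channel means
  gcpix <- gen$slide$image[, , 1][gen$truth$gc_mask]
  expect_lt(abs(mean(gcpix) * 255 - spec$gc_rgb[1]), 3 * spec$noise_sd)
})

test_that("generation is bit-identical for a fixed seed", {
  spec <- slide_spec(n_sections = 2L, seed = 42L)
  g1 <- generate_slide(spec)
  g2 <- generate_slide(spec)
  expect_identical(g1$slide$image, g2$slide$image)
  expect_identical(g1$truth$gc_mask, g2$truth$gc_mask)
  expect_identical(g1$truth$sinus_mask, g2$truth$sinus_mask)
})

test_that("impossible section packing errors with the constraint named", {
  spec <- slide_spec(width_px = 300L, height_px = 300L, n_sections = 6L,
                     section_radius_px = c(110, 130), seed = 1L)
  expect_error(generate_slide(spec), "non-overlapping sections")
})

test_that("per-section sinus fraction stays within 20 percent of target", {
  for (seed in c(3L, 14L, 27L)) {
    gen <- generate_slide(slide_spec(n_sections = 2L, seed = seed))
    tr <- gen$truth
    for (i in seq_len(nrow(tr$planted))) {
      sec <- tr$section_label == i
      frac <- sum(tr$sinus_mask & sec) / sum(sec)
      expect_gt(frac, 0.8 * 0.12)
      expect_lt(frac, 1.2 * 0.12)
    }
  }
})

test_that("ground-truth component count equals planted count per section", {
  for (seed in c(2L, 9L)) {
    gen <- generate_slide(slide_spec(n_sections = 2L, seed = seed))
    tr <- gen$truth
    for (i in seq_len(nrow(tr$planted))) {
      sec_gc <- tr$gc_mask & (tr$section_label == i)
      ncomp <- max(EBImage::bwlabel(sec_gc * 1))
      expect_equal(ncomp, tr$planted$gc_count[i])
    }
  }
})

test_that("render_magnification follows the pyramid arithmetic", {
  slide <- new_slide(array(runif(1024 * 1024 * 3), c(1024, 1024, 3)), mpp = 0.23)
  lo <- render_magnification(slide, 4L)
  expect_equal(dim(lo$image)[1:2], c(256L, 256L))
  expect_equal(lo$mpp, 0.92)
  # odd dimensions round up
  odd <- new_slide(array(0, c(1023, 1022, 3)), mpp = 1)
  expect_equal(dim(render_magnification(odd, 4L)$image)[1:2],
               c(ceiling(1023 / 4), ceiling(1022 / 4)))
  expect_identical(render_magnification(slide, 1L), slide)
  expect_error(render_magnification(slide, 3L), "factor")
})

test_that("cohort generation plants the outcome structure", {
  cs <- cohort_spec(n_patients = 120L, censoring_rate = 0, seed = 3L)
  coh <- generate_cohort(cs)
  expect_true(all(coh$event == 1))      # censoring_rate 0 + long admin window
  pat <- dplyr::distinct(coh, patient_id, .keep_all = TRUE)
  expect_equal(nrow(pat), 120L)
  expect_true(all(coh$time > 0))
  # determinism
  expect_identical(generate_cohort(cs)$time, coh$time)
  # both planted groups populated under the default feature distributions
  expect_true(all(table(pat$high_risk_feature) > 10))
})

test_that("degenerate one-group cohort warns", {
  cs <- cohort_spec(n_patients = 30L,
                    feature_effect = list(feature = "mean_gc_count",
                                          cutoff = 1e6, hr = 0.3),
                    seed = 1L)
  expect_warning(generate_cohort(cs), "one feature group")
})

test_that("spec validation rejects out-of-domain parameters", {
  expect_error(slide_spec(mpp = 0), "mpp")
  expect_error(slide_spec(gc_eccentricity = c(0, 1)), "eccentricity")
  expect_error(slide_spec(sinus_fraction = 0.6), "sinus_fraction")
  expect_error(cohort_spec(n_patients = 1L), "n_patients")
  expect_error(cohort_spec(feature_effect = list(feature = "x", cutoff = 1, hr = 0)),
               "hazard ratio")
})
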