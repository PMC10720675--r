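test_that("circularity of canonical shapes matches analytic values", {
  mpp <- 1
  d <- extract_gc_instances(disk_mask(100L), NULL, mpp, min_area_um2 = 0)
  expect_equal(nrow(d), 1L)
  expect_equal(d$circularity, 1.0, tolerance = 0.05)
  s <- extract_gc_instances(square_mask(100L), NULL, mpp, min_area_um2 = 0)
  expect_equal(s$circularity, pi / 4, tolerance = 0.05 / (pi / 4))
  bar <- matrix(FALSE, 12, 120); bar[6, 11:110] <- TRUE
  b <- extract_gc_instances(bar, NULL, mpp, min_area_um2 = 0)
  expect_lt(b$circularity, 0.2)
  expect_error(circularity(10, 0), "perimeter")
})

test_that("circularity decreases with eccentricity at fixed area", {
  ab <- 120 * 120   # fixed axis product => fixed area
  circs <- vapply(c(0, 0.6, 0.8, 0.92), function(e) {
    a <- sqrt(ab / sqrt(1 - e^2)); b <- ab / a
    extract_gc_instances(ellipse_mask(round(a), round(b)), NULL, 1,
                         min_area_um2 = 0)$circularity
  }, 1)
  expect_true(all(diff(circs) < 0))
})

test_that("instance extraction applies count, size and containment filters", {
  m <- matrix(FALSE, 120, 200)
  m[20:50, 20:50] <- TRUE       # above threshold
  m[80:110, 120:150] <- TRUE    # second blob
  inst <- extract_gc_instances(m, NULL, mpp = 1, min_area_um2 = 100)
  expect_equal(nrow(inst), 2L)
  # min-area filter drops a small blob
  small <- matrix(FALSE, 40, 40); small[10:12, 10:12] <- TRUE
  expect_equal(nrow(extract_gc_instances(small, NULL, 1, min_area_um2 = 100)), 0L)
  # centroid-outside-contour exclusion
  ctr <- cbind(x = c(1, 100, 100, 1), y = c(1, 1, 119, 119))
  inst2 <- extract_gc_instances(m, ctr, mpp = 1, min_area_um2 = 100)
  expect_equal(nrow(inst2), 1L)
})

test_that("ln_features composes counts, means and normalized sinus area", {
  ctr <- cbind(x = c(0.5, 200.5, 200.5, 0.5), y = c(0.5, 0.5, 100.5, 100.5))
  sinus <- matrix(FALSE, 100, 200); sinus[, 1:100] <- TRUE  # half the LN
  f <- ln_features(extract_gc_instances(matrix(FALSE, 100, 200), NULL, 1),
                   sinus, ctr, mpp = 1, scs = FALSE)
  expect_equal(f$normalized_sinus_area, 0.5, tolerance = 0.02)
  expect_equal(f$gc_count, 0L)
  expect_true(is.na(f$mean_gc_area_mm2))   # missing, not zero
  expect_true(is.na(f$mean_gc_circularity))
  f0 <- ln_features(extract_gc_instances(matrix(FALSE, 100, 200), NULL, 1),
                    matrix(FALSE, 100, 200), ctr, mpp = 1, scs = FALSE)
  expect_equal(f0$sinus_area_mm2, 0)
  expect_error(ln_features(extract_gc_instances(matrix(FALSE, 2, 2), NULL, 1),
                           NULL, cbind(c(1, 1, 1), c(1, 1, 1)), 1),
               "area")
})

test_that("SCS width recovers a uniform annulus and the four-point mean", {
  # circle radius 100, annulus of width 15 px just inside the boundary
  outer_m <- disk_mask(100L)
  inner_m <- disk_mask(85L, pad = 25L)   # same canvas center
  annulus <- outer_m & !inner_m
  ctr <- trace_contour(outer_m)
  w <- scs_width(ctr, annulus, mpp = 1)
  expect_equal(w$scs_width_um, 15, tolerance = 1 / 15)
  expect_equal(w$n_missed, 0L)
  # planted widths 10/20/30/40 at the four axis intersections of an ellipse
  em <- ellipse_mask(140L, 90L, pad = 12L)
  cen <- c(153, 153)  # (x, y) of canvas center
  sm <- matrix(FALSE, nrow(em), ncol(em))
  sm[(cen[2] - 8):(cen[2] + 8), (cen[1] + 140 - 9):(cen[1] + 140)] <- TRUE   # +major: 10
  sm[(cen[2] - 8):(cen[2] + 8), (cen[1] - 140):(cen[1] - 140 + 19)] <- TRUE  # -major: 20
  sm[(cen[2] + 90 - 29):(cen[2] + 90), (cen[1] - 8):(cen[1] + 8)] <- TRUE    # minor: 30
  sm[(cen[2] - 90):(cen[2] - 90 + 39), (cen[1] - 8):(cen[1] + 8)] <- TRUE    # minor: 40
  wm <- scs_width(trace_contour(em), sm, mpp = 1)
  expect_equal(sort(round(c(wm$w1, wm$w2, wm$w3, wm$w4))), c(10, 20, 30, 40),
               tolerance = 0.1)
  expect_equal(wm$scs_width_um, 25, tolerance = 0.05)
  # the averaging rule itself is exact
  expect_equal(scs_measurement(c(10, 20, 30, 40))$scs_width_um, 25)
  # empty sinus mask: zero width, all four points flagged
  w0 <- scs_width(ctr, matrix(FALSE, nrow(outer_m), ncol(outer_m)), mpp = 1)
  expect_equal(w0$scs_width_um, 0)
  expect_equal(w0$n_missed, 4L)
})

test_that("GC-count F1 follows the greedy matching conventions", {
  m <- matrix(FALSE, 60, 120)
  m[10:25, 10:25] <- TRUE; m[35:50, 80:100] <- TRUE
  truth <- extract_gc_instances(m, NULL, 1, min_area_um2 = 0)
  expect_equal(gc_count_f1(truth, truth)[, c("precision", "recall", "f1")],
               tibble::tibble(precision = 1, recall = 1, f1 = 1))
  none <- extract_gc_instances(matrix(FALSE, 60, 120), NULL, 1)
  expect_equal(gc_count_f1(none, truth)$f1, 0)
  expect_equal(gc_count_f1(none, truth)$precision, 0)
  # 1 of 2 truths matched, no false positives -> P=1, R=0.5, F1=2/3
  m1 <- matrix(FALSE, 60, 120); m1[10:25, 10:25] <- TRUE
  pred <- extract_gc_instances(m1, NULL, 1, min_area_um2 = 0)
  r <- gc_count_f1(pred, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 2 / 3)
})

test_that("quantifying ground-truth masks recovers planted features", {
  gen <- generate_slide(slide_spec(n_sections = 2L, seed = 31L))
  tr <- gen$truth
  sections <- tibble::tibble(
    section_id = names(tr$section_contours),
    contour = unname(tr$section_contours),
    involvement = "unknown")
  feats <- quantify_sections(sections, tr$gc_mask, tr$sinus_mask, mpp = tr$mpp)
  expect_equal(feats$gc_count, tr$planted$gc_count)
  expect_equal(feats$mean_gc_area_mm2, tr$planted$mean_gc_area_mm2,
               tolerance = 0.05)
  expect_equal(feats$mean_gc_circularity, tr$planted$mean_gc_circularity,
               tolerance = 0.05)
  # sinus area normalization consistent with the planted fraction
  expect_equal(feats$normalized_sinus_area, tr$planted$sinus_fraction,
               tolerance = 0.1)
  # SCS width close to the planted rim width
  expect_equal(feats$scs_width_um, tr$planted$scs_width_um, tolerance = 0.35)
})

test_that("physical features are invariant to rendering scale", {
  gen <- generate_slide(benchmark_slide_spec(seed = 17L))
  tr <- gen$truth
  ctr <- tr$section_contours[[1]]
  inst1 <- extract_gc_instances(tr$gc_mask, ctr, tr$mpp)
  ds <- 2L
  mask2 <- downsample_mask(tr$gc_mask, ds)
  ctr2 <- cbind(x = (ctr[, 1] - 0.5) / ds + 0.5, y = (ctr[, 2] - 0.5) / ds + 0.5)
  inst2 <- extract_gc_instances(mask2, ctr2, tr$mpp * ds)
  expect_equal(nrow(inst1), nrow(inst2))
  expect_equal(mean(inst2$area_mm2), mean(inst1$area_mm2), tolerance = 0.05)
  # pixel counts differ by ~4x even though physical areas agree
  expect_gt(sum(tr$gc_mask) / sum(mask2), 3.5)
})
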