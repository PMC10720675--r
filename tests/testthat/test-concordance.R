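test_that("dice matches brute-force pixel enumeration and its identities", {
  a <- matrix(FALSE, 8, 8); a[1:2, 1:2] <- TRUE          # |A| = 4
  b <- matrix(FALSE, 8, 8); b[2:3, 1:2] <- TRUE          # |B| = 4, overlap 2
  brute <- local({
    inter <- 0; sa <- 0; sb <- 0
    for (i in 1:8) for (j in 1:8) {
      sa <- sa + a[i, j]; sb <- sb + b[i, j]
      inter <- inter + (a[i, j] && b[i, j])
    }
    2 * inter / (sa + sb)
  })
  expect_equal(as.numeric(dice(a, b)), 0.5)
  expect_equal(as.numeric(dice(a, b)), brute)
  expect_equal(as.numeric(dice(a, a)), 1)
  expect_equal(as.numeric(dice(a, b)), as.numeric(dice(b, a)))
  disj <- matrix(FALSE, 8, 8); disj[7:8, 7:8] <- TRUE
  expect_equal(as.numeric(dice(a, disj)), 0)
  e <- matrix(FALSE, 8, 8)
  expect_equal(as.numeric(dice(e, e)), 1)
  expect_true(attr(dice(e, e), "both_empty"))
  expect_error(dice(a, matrix(FALSE, 4, 4)), "dimensions")
})

test_that("pairwise agreement over annotators has the right combinatorics", {
  masks <- withr::with_seed(4, lapply(1:4, function(i) matrix(runif(64) < 0.4, 8, 8)))
  ann <- tibble::tibble(
    ln_id = rep(c("L1", "L2"), each = 4),
    annotator_id = rep(paste0("A", 1:4), 2),
    mask = c(masks, masks))
  pw <- pairwise_dice(ann)
  expect_equal(nrow(pw$pairs), 2 * choose(4, 2))      # 6 unique pairs per LN
  expect_true(isSymmetric(pw$matrix))
  expect_true(all(diag(pw$matrix) == 1))
  expect_true(all(pw$pairs$dice >= 0 & pw$pairs$dice <= 1))
  # identical annotators agree perfectly
  same <- tibble::tibble(ln_id = "L1", annotator_id = paste0("A", 1:3),
                         mask = rep(masks[1], 3))
  expect_true(all(pairwise_dice(same)$pairs$dice == 1))
  expect_error(pairwise_dice(same[1, ]), "2 annotators")
})

test_that("consensus maps count annotators and nest across levels", {
  masks <- withr::with_seed(9, lapply(1:4, function(i) matrix(runif(100) < 0.3, 10, 10)))
  cm <- consensus_map(masks)
  expect_true(all(cm >= 0 & cm <= 4))
  # histogram identity: sum(count * value) = total marked pixel-annotations
  expect_equal(sum(cm), sum(vapply(masks, sum, 1)))
  # identical masks produce only 0 and 4
  cm4 <- consensus_map(rep(masks[1], 4))
  expect_true(all(cm4 %in% c(0L, 4L)))
  # single-annotator pixel counts 1
  solo <- matrix(FALSE, 10, 10); solo[1, 1] <- TRUE
  expect_equal(consensus_map(c(masks[1], list(solo)))[1, 1],
               masks[[1]][1, 1] + 1L)
  # nesting: reference at k is a superset of reference at k+1
  for (k in 1:3) expect_true(all((cm >= k + 1) <= (cm >= k)))
})

test_that("model-vs-consensus Dice equals hand enumeration on a toy case", {
  m1 <- matrix(FALSE, 4, 4); m1[1:2, 1:2] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[1:3, 1:2] <- TRUE
  m3 <- matrix(FALSE, 4, 4); m3[2, 1:2] <- TRUE
  cm <- consensus_map(list(m1, m2, m3))
  model <- m1
  for (k in 1:3) {
    ref <- cm >= k
    byhand <- 2 * sum(model & ref) / (sum(model) + sum(ref))
    expect_equal(model_vs_consensus(model, cm, k), byhand)
  }
  expect_equal(model_vs_consensus(cm >= 3, cm, 3), 1)
  expect_error(model_vs_consensus(model, cm, 5), "out of range")
})

test_that("polygon rasterization agrees with polygon-geometry areas", {
  theta <- seq(0, 2 * pi, length.out = 181)[-181]
  poly <- cbind(x = 60 + 40 * cos(theta), y = 55 + 30 * sin(theta))
  m <- rasterize_polygon(poly, c(120, 120))
  expect_lt(abs(sum(m) - polygon_area(poly)) / polygon_area(poly), 0.02)
  # Dice of two smooth polygons vs an area-overlap oracle on rasters
  poly2 <- cbind(x = 75 + 40 * cos(theta), y = 55 + 30 * sin(theta))
  m2 <- rasterize_polygon(poly2, c(120, 120))
  d <- as.numeric(dice(m, m2))
  expect_gt(d, 0); expect_lt(d, 1)
})

test_that("GeoJSON round-trips polygons and properties", {
  poly <- cbind(x = c(10.5, 50.25, 40, 12), y = c(5, 8, 44.5, 30))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(list(S01 = poly), path,
                properties = data.frame(section_id = "S01", area_mm2 = 1.25,
                                        involvement = "involved"))
  back <- read_geojson(path)
  expect_equal(back$polygon[[1]], poly, ignore_attr = TRUE)
  expect_equal(back$section_id, "S01")
  expect_equal(back$area_mm2, 1.25)
})
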