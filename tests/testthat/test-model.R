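test_that("model construction follows the architectural contract", {
  spec <- seg_model_spec("ms_unet", "gc", base_channels = 4L, depth = 3L, seed = 2L)
  m <- build_model(spec)
  # three parallel atrous branches per encoder level for rates (1,2,4)
  expect_true(all(c("e1.b1", "e1.b2", "e1.b3", "e1.fuse") %in% names(m$params)))
  expect_equal(m$params[["e1.b2"]]$dil, 2L)
  expect_equal(m$params[["e1.b3"]]$dil, 4L)
  # FCN contract: output matches input spatial dims for divisible sizes
  x <- array(runif(32 * 48 * 3), c(32, 48, 3))
  p <- predict_tile(m, x)
  expect_equal(dim(p), c(32L, 48L))
  expect_true(all(p >= 0 & p <= 1))
  # non-divisible input errors
  expect_error(predict_tile(m, array(0, c(33, 32, 3))), "divisible")
  # invalid ms spec
  expect_error(seg_model_spec("ms_unet", scales = 1L), "2 scales")
  expect_error(seg_model_spec("ms_unet", scales = c(1L, 2L),
                              dilation_rates = c(1L, 2L, 4L)), "per scale")
})

test_that("weight init and inference are deterministic in the seed", {
  spec <- seg_model_spec("unet", "gc", base_channels = 4L, depth = 2L, seed = 5L)
  m1 <- build_model(spec); m2 <- build_model(spec)
  expect_identical(m1$params, m2$params)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predict_tile(m1, x), predict_tile(m1, x))
  m3 <- build_model(seg_model_spec("unet", "gc", base_channels = 4L,
                                   depth = 2L, seed = 6L))
  expect_false(identical(m1$params, m3$params))
})

test_that("tile grids follow the overlap arithmetic", {
  # 512 px, tile 256, overlap 128 -> ((512-256)/128 + 1)^2 = 9 tiles
  sec <- list(image = array(0, c(512, 512, 3)), mask = matrix(0, 512, 512), id = "a")
  tl <- nodemorph:::tile_section(sec$image, sec$mask, 256L, 128L, "a")
  expect_length(tl, 9L)
  # adjacent origins differ by tile - overlap
  org <- t(vapply(tl, function(t) t$origin, c(1, 1)))
  expect_equal(sort(unique(org[, 1])), c(1L, 129L, 257L))
  # a section smaller than one tile gives one zero-padded tile with the
  # padding excluded from the loss weight
  small <- nodemorph:::tile_section(array(1, c(40, 40, 3)),
                                    matrix(1, 40, 40), 64L, 32L, "s")
  expect_length(small, 1L)
  expect_equal(dim(small[[1]]$image)[1:2], c(64L, 64L))
  expect_equal(sum(small[[1]]$weight), 1600)
  expect_true(all(small[[1]]$weight[41:64, ] == 0))
})

test_that("dataset splits are section-level with no leakage", {
  secs <- lapply(1:114, function(i) fake_section(8L, sprintf("sec%03d", i)))
  cfg <- train_config(tile_px = 8L, overlap_px = 4L,
                      split = c(100L, 9L, 5L), seed = 3L)
  tiles <- tile_dataset(secs, cfg)
  sp <- tiles$section_split
  expect_equal(sum(sp$partition == "train", na.rm = TRUE), 100L)
  expect_equal(sum(sp$partition == "val", na.rm = TRUE), 9L)
  expect_equal(sum(sp$partition == "test", na.rm = TRUE), 5L)
  ids <- function(set) unique(vapply(set, function(t) t$section_id, ""))
  expect_length(intersect(ids(tiles$train), ids(tiles$val)), 0L)
  expect_length(intersect(ids(tiles$train), ids(tiles$test)), 0L)
  expect_length(intersect(ids(tiles$val), ids(tiles$test)), 0L)
  # too few sections errors
  expect_error(tile_dataset(secs[1:50], cfg), "114|only 50")
})

test_that("training rejects degenerate tasks and records history", {
  secs <- lapply(1:3, function(i) fake_section(16L, sprintf("s%d", i)))
  cfg <- train_config(tile_px = 16L, overlap_px = 8L, epochs = 1L,
                      split = c(1L, 1L, 1L), seed = 1L)
  tiles <- tile_dataset(secs, cfg)
  m <- build_model(seg_model_spec("unet", "gc", base_channels = 2L,
                                  depth = 2L, seed = 1L))
  expect_error(train(m, tiles, cfg), "no positive pixel")
  expect_error(train(m, list(train = list(), val = list()), cfg),
               "empty training set")
  # with a positive mask the history covers every epoch
  secs[[1]]$mask[4:10, 4:10] <- 1
  tiles <- tile_dataset(secs, cfg)
  cfg2 <- train_config(tile_px = 16L, overlap_px = 8L, epochs = 2L,
                       split = c(1L, 1L, 1L), seed = 1L)
  fit <- train(m, tiles, cfg2)
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(c("epoch", "loss", "val_dice") %in% names(fit$history)))
})

test_that("checkpoints round-trip weights and predictions", {
  m <- build_model(seg_model_spec("ms_unet", "sinus", base_channels = 3L,
                                  depth = 2L, seed = 4L))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(predict_tile(m2, x), predict_tile(m, x), tolerance = 1e-12)
  expect_equal(m2$spec$structure, "sinus")
})

test_that("loss decreases over the first epochs for every variant", {
  gen <- generate_slide(benchmark_slide_spec(seed = 44L))
  tr <- gen$truth
  bb <- c(40L, 40L, 231L, 231L)
  sec <- list(image = gen$slide$image[bb[1]:bb[3], bb[2]:bb[4], , drop = FALSE],
              mask = tr$gc_mask[bb[1]:bb[3], bb[2]:bb[4]] * 1, id = "s1")
  cfg <- train_config(tile_px = 64L, overlap_px = 0L, epochs = 3L,
                      split = c(1L, 1L, 1L), seed = 2L, augment = FALSE)
  tiles <- list(train = nodemorph:::tile_section(sec$image, sec$mask, 64L, 64L, "s1"),
                val = list())
  for (variant in c("unet", "atten_unet", "ms_unet")) {
    m <- build_model(seg_model_spec(variant, "gc", base_channels = 4L,
                                    depth = 2L, seed = 3L))
    fit <- train(m, tiles, cfg)
    expect_lt(fit$history$loss[3], fit$history$loss[1],
              label = sprintf("%s epoch-3 loss", variant))
  }
})
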