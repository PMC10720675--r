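#' Threshold a probability raster
#'
#' @param prob numeric matrix in `[0, 1]`.
#' @param threshold scalar in `(0, 1)`.
#' @return logical matrix `prob >= threshold`.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  prob >= threshold
}

#' Segment one lymph-node section with tile stitching
#'
#' Tiles are laid over the section bounding box with the configured overlap
#' (edges reflect-padded so every tile is full size, with padded output
#' discarded), the model is applied per tile, overlapping predictions are
#' averaged per pixel, the probability raster is clipped to the section
#' contour, and thresholded.
#'
#' @param model model accepted by [predict_tile()].
#' @param slide an `nm_slide` at the model's working magnification.
#' @param section one-row slice of a [detect_ln_sections()] tibble (or a
#'   list with `contour`, `bbox`, `section_id`).
#' @param cfg a [train_config()] supplying `tile_px` and `overlap_px`.
#' @param threshold binarization threshold.
#' @return object of class `nm_structure_mask`: list with `structure`,
#'   `prob` and `binary` rasters in the bbox frame, `bbox`, `threshold`,
#'   `section_id`.
#' @export
segment_section <- function(model, slide, section, cfg, threshold = 0.5) {
  bbox <- if (is.list(section$bbox) && !is.numeric(section$bbox)) section$bbox[[1]] else section$bbox
  contour <- if (is.list(section$contour) && !is.matrix(section$contour)) section$contour[[1]] else section$contour
  H <- bbox[3] - bbox[1] + 1L; W <- bbox[4] - bbox[2] + 1L
  if (H < 2L || W < 2L) stop("degenerate section bounding box")
  img <- slide$image[bbox[1]:bbox[3], bbox[2]:bbox[4], , drop = FALSE]
  prob <- stitch_tiles(model, img, cfg$tile_px, cfg$tile_px - cfg$overlap_px)
  local_contour <- cbind(contour[, 1] - bbox[2] + 1, contour[, 2] - bbox[1] + 1)
  inside <- rasterize_polygon(local_contour, c(H, W))
  prob[!inside] <- 0
  structure(list(structure = if (inherits(model, "nm_model")) model$spec$structure else "stub",
                 prob = prob, binary = binarize(prob, threshold),
                 bbox = bbox, threshold = threshold,
                 section_id = section$section_id %||% "S01"),
            class = "nm_structure_mask")
}

# reflect-pad an image on the bottom/right to at least (H2, W2)
reflect_pad <- function(img, H2, W2) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(max(H, H2))]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(max(W, W2))]
  img[ri, ci, , drop = FALSE]
}

#' Apply a tile model across an image and average overlapping predictions
#'
#' @param model model accepted by [predict_tile()].
#' @param img `H x W x C` array.
#' @param tile tile side; `stride` the tile step (`tile - overlap`).
#' @return probability matrix `H x W`; every pixel is covered by at least
#'   one tile.
#' @export
stitch_tiles <- function(model, img, tile, stride) {
  H <- dim(img)[1]; W <- dim(img)[2]
  Hp <- max(H, tile); Wp <- max(W, tile)
  pimg <- if (Hp > H || Wp > W) reflect_pad(img, Hp, Wp) else img
  acc <- matrix(0, Hp, Wp); cnt <- matrix(0, Hp, Wp)
  for (r in tile_origins(Hp, tile, stride)) for (c in tile_origins(Wp, tile, stride)) {
    rr <- r:(r + tile - 1L); cc <- c:(c + tile - 1L)
    p <- predict_tile(model, pimg[rr, cc, , drop = FALSE])
    acc[rr, cc] <- acc[rr, cc] + p
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  (acc / cnt)[seq_len(H), seq_len(W), drop = FALSE]
}

#' Tile coverage count for a bounding box
#'
#' Diagnostic companion to [stitch_tiles()]: how many tiles cover each
#' pixel under the same grid.
#' @param H,W raster dimensions; `tile`, `stride` as in [stitch_tiles()].
#' @return integer matrix of per-pixel tile multiplicities.
#' @export
tile_coverage <- function(H, W, tile, stride) {
  Hp <- max(H, tile); Wp <- max(W, tile)
  cnt <- matrix(0L, Hp, Wp)
  for (r in tile_origins(Hp, tile, stride)) for (c in tile_origins(Wp, tile, stride)) {
    rr <- r:(r + tile - 1L); cc <- c:(c + tile - 1L)
    cnt[rr, cc] <- cnt[rr, cc] + 1L
  }
  cnt[seq_len(H), seq_len(W), drop = FALSE]
}

#' Dice of a structure mask against a ground-truth raster
#'
#' @param mask an `nm_structure_mask`.
#' @param truth_raster binary slide-frame raster.
#' @return Dice within the mask's bounding box.
#' @export
mask_dice <- function(mask, truth_raster) {
  bb <- mask$bbox
  as.numeric(dice(mask$binary, truth_raster[bb[1]:bb[3], bb[2]:bb[4]] > 0))
}

#' Build annotated benchmark sections from the synthetic generator
#'
#' Generates `n` one-section slides from [benchmark_slide_spec()] (seeds
#' `seed_base + 1..n`), crops each section's bounding box and pairs the
#' image with the requested ground-truth mask.
#'
#' @param n number of sections.
#' @param structure `"gc"` or `"sinus"`.
#' @param variant benchmark variant, see [benchmark_slide_spec()].
#' @param seed_base offset for the per-slide seeds.
#' @return list of sections suitable for [tile_dataset()]; each carries the
#'   slide-frame `truth` and `contour` for downstream checks.
#' @export
make_benchmark_sections <- function(n, structure = c("gc", "sinus"),
                                    variant = "standard", seed_base = 0L) {
  structure_ <- match.arg(structure)
  lapply(seq_len(n), function(i) {
    gen <- generate_slide(benchmark_slide_spec(variant, seed = seed_base + i))
    tr <- gen$truth
    msk <- if (structure_ == "gc") tr$gc_mask else tr$sinus_mask
    ctr <- tr$section_contours[[1]]
    bb <- c(max(1L, floor(min(ctr[, 2]))), max(1L, floor(min(ctr[, 1]))),
            min(nrow(msk), ceiling(max(ctr[, 2]))), min(ncol(msk), ceiling(max(ctr[, 1]))))
    list(image = gen$slide$image[bb[1]:bb[3], bb[2]:bb[4], , drop = FALSE],
         mask = msk[bb[1]:bb[3], bb[2]:bb[4]] * 1,
         id = sprintf("bench-%s-%03d", variant, i),
         bbox = bb, contour = ctr, truth = tr, slide = gen$slide)
  })
}
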