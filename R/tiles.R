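#' Training configuration for tile-based segmentation
#'
#' @param tile_px tile side in pixels.
#' @param overlap_px overlap between adjacent tiles (< `tile_px`); the grid
#'   stride is `tile_px - overlap_px`.
#' @param batch_size samples per optimizer step.
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param loss `"bce"`, `"dice"` or `"bce_plus_dice"` (equal weights).
#' @param augment apply random flips / 90-degree rotations during training.
#' @param split counts of sections for train / validation / test.
#' @param seed seed driving the section shuffle, batch order and
#'   augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(tile_px = 64L, overlap_px = 32L, batch_size = 8L,
                         epochs = 6L, learning_rate = 1e-3,
                         loss = c("bce_plus_dice", "bce", "dice"),
                         augment = TRUE,
                         split = c(train = 12L, val = 3L, test = 3L),
                         seed = 7L) {
  loss <- match.arg(loss)
  if (overlap_px >= tile_px) stop("overlap_px must be smaller than tile_px")
  if (length(split) != 3L || any(split <= 0)) stop("split needs 3 positive counts")
  structure(list(tile_px = as.integer(tile_px), overlap_px = as.integer(overlap_px),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, loss = loss, augment = augment,
                 split = stats::setNames(as.integer(split), c("train", "val", "test")),
                 seed = as.integer(seed)),
            class = "train_config")
}

# tile origin grid covering 1..n: stride steps plus a flush final origin
tile_origins <- function(n, tile, stride) {
  if (n <= tile) return(1L)
  o <- seq(1L, n - tile + 1L, by = stride)
  if (o[length(o)] != n - tile + 1L) o <- c(o, n - tile + 1L)
  as.integer(o)
}

# cut one section (image + mask) into overlapping tiles; sections smaller
# than a tile are zero-padded and the padding excluded via the loss weight
tile_section <- function(image, mask, tile, stride, section_id) {
  H <- dim(image)[1]; W <- dim(image)[2]
  padH <- max(0L, tile - H); padW <- max(0L, tile - W)
  if (padH > 0L || padW > 0L) {
    img2 <- array(0, c(H + padH, W + padW, dim(image)[3]))
    img2[seq_len(H), seq_len(W), ] <- image
    msk2 <- matrix(0, H + padH, W + padW); msk2[seq_len(H), seq_len(W)] <- mask
    wgt <- matrix(0, H + padH, W + padW); wgt[seq_len(H), seq_len(W)] <- 1
    image <- img2; mask <- msk2
    H <- H + padH; W <- W + padW
  } else {
    wgt <- NULL
  }
  out <- list()
  for (r in tile_origins(H, tile, stride)) for (c in tile_origins(W, tile, stride)) {
    rr <- r:(r + tile - 1L); cc <- c:(c + tile - 1L)
    out[[length(out) + 1L]] <- list(
      image = image[rr, cc, , drop = FALSE],
      mask = (mask[rr, cc] > 0) * 1,
      weight = if (is.null(wgt)) matrix(1, tile, tile) else wgt[rr, cc],
      origin = c(r, c), section_id = section_id)
  }
  out
}

#' Build train / validation / test tile sets from annotated sections
#'
#' The split is at section level — no section contributes tiles to two
#' partitions — with a deterministic shuffle driven by `cfg$seed`.
#'
#' @param sections list of sections, each a list with `image` (HxWx3 array),
#'   `mask` (binary matrix) and optionally `id`.
#' @param cfg a [train_config()].
#' @return list of class `nm_tiles` with `train`, `val`, `test` tile lists
#'   and `section_split` (tibble of section id / partition).
#' @export
tile_dataset <- function(sections, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  n <- length(sections)
  need <- sum(cfg$split)
  if (n < need)
    stop(sprintf("split needs %d sections but only %d supplied", need, n))
  ids <- vapply(seq_len(n), function(i) sections[[i]]$id %||% sprintf("sec%03d", i), "")
  ord <- withr::with_seed(cfg$seed, sample.int(n))
  part <- rep(NA_character_, n)
  part[ord[seq_len(cfg$split["train"])]] <- "train"
  part[ord[cfg$split["train"] + seq_len(cfg$split["val"])]] <- "val"
  part[ord[cfg$split["train"] + cfg$split["val"] + seq_len(cfg$split["test"])]] <- "test"
  stride <- cfg$tile_px - cfg$overlap_px
  sets <- list(train = list(), val = list(), test = list())
  for (i in seq_len(n)) {
    if (is.na(part[i])) next
    tl <- tile_section(sections[[i]]$image, sections[[i]]$mask,
                       cfg$tile_px, stride, ids[i])
    sets[[part[i]]] <- c(sets[[part[i]]], tl)
  }
  structure(list(train = sets$train, val = sets$val, test = sets$test,
                 section_split = tibble::tibble(section_id = ids, partition = part)),
            class = "nm_tiles")
}

augment_tile <- function(tl) {
  if (runif(1) < 0.5) {  # horizontal flip
    tl$image <- tl$image[, rev(seq_len(dim(tl$image)[2])), , drop = FALSE]
    tl$mask <- tl$mask[, rev(seq_len(ncol(tl$mask)))]
    tl$weight <- tl$weight[, rev(seq_len(ncol(tl$weight)))]
  }
  if (runif(1) < 0.5) {  # vertical flip
    tl$image <- tl$image[rev(seq_len(dim(tl$image)[1])), , , drop = FALSE]
    tl$mask <- tl$mask[rev(seq_len(nrow(tl$mask))), ]
    tl$weight <- tl$weight[rev(seq_len(nrow(tl$weight))), ]
  }
  k <- sample.int(4L, 1L) - 1L
  rot1 <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  for (r in seq_len(k)) {
    tl$image <- array(apply(tl$image, 3, rot1),
                      c(dim(tl$image)[2], dim(tl$image)[1], dim(tl$image)[3]))
    tl$mask <- rot1(tl$mask)
    tl$weight <- rot1(tl$weight)
  }
  tl
}
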