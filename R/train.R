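#' Train a segmentation model on tiles
#'
#' Adam on the configured loss; per-epoch validation Dice (computed with the
#' same [dice()] operation used for concordance, at threshold 0.5) decides
#' the checkpoint that is returned. Fully reproducible for fixed model and
#' config seeds.
#'
#' @param model an `nm_model` from [build_model()].
#' @param tiles an `nm_tiles` set from [tile_dataset()] (or a list with
#'   `train` / `val` tile lists).
#' @param cfg a [train_config()].
#' @param quiet suppress per-epoch progress.
#' @return the trained `nm_model`; `$history` is a tibble with one row per
#'   epoch (`epoch`, `loss`, `val_dice`) and `$best_epoch` records the
#'   checkpoint choice.
#' @export
train <- function(model, tiles, cfg, quiet = TRUE) {
  stopifnot(inherits(model, "nm_model"))
  tr <- tiles$train
  if (!length(tr)) stop("empty training set")
  if (!any(vapply(tr, function(t) sum(t$mask) > 0, TRUE)))
    stop("degenerate task: training masks contain no positive pixel")
  withr::with_seed(cfg$seed, train_impl(model, tr, tiles$val, cfg, quiet))
}

train_impl <- function(model, tr, val, cfg, quiet) {
  params <- model$params
  st <- adam_init(params)
  history <- list()
  best <- list(dice = -Inf, params = params, epoch = 0L)
  nb <- ceiling(length(tr) / cfg$batch_size)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(tr))
    ep_loss <- 0; nseen <- 0L
    for (b in seq_len(nb)) {
      sel <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, length(tr))]
      grads <- NULL
      for (s in sel) {
        tl <- tr[[s]]
        if (isTRUE(cfg$augment)) tl <- augment_tile(tl)
        mtmp <- model; mtmp$params <- params
        fw <- model_fwd(mtmp, tl$image)
        ls <- seg_loss(fw$logits, tl$mask, tl$weight, cfg$loss)
        ep_loss <- ep_loss + ls$loss; nseen <- nseen + 1L
        g <- model_bwd(mtmp, ls$dz, fw$caches)
        if (is.null(grads)) grads <- g
        else for (nm in names(g)) {
          grads[[nm]]$W <- grads[[nm]]$W + g[[nm]]$W
          grads[[nm]]$b <- grads[[nm]]$b + g[[nm]]$b
        }
      }
      for (nm in names(grads)) {
        grads[[nm]]$W <- grads[[nm]]$W / length(sel)
        grads[[nm]]$b <- grads[[nm]]$b / length(sel)
      }
      upd <- adam_step(params, grads, st, cfg$learning_rate)
      params <- upd$params; st <- upd$state
    }
    mtmp <- model; mtmp$params <- params
    vd <- validation_dice(mtmp, val)
    history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / max(1L, nseen),
                                    val_dice = vd)
    if (!quiet)
      message(sprintf("epoch %d/%d  loss %.4f  val dice %.3f",
                      ep, cfg$epochs, ep_loss / max(1L, nseen), vd))
    if (!is.na(vd) && vd > best$dice) best <- list(dice = vd, params = params, epoch = ep)
  }
  model$params <- if (best$epoch > 0L) best$params else params
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- best$epoch
  model
}

validation_dice <- function(model, val) {
  if (!length(val)) return(NA_real_)
  ds <- vapply(val, function(tl) {
    p <- sigmoid(model_fwd(model, tl$image)$logits)
    as.numeric(dice((p >= 0.5) & (tl$weight > 0), tl$mask > 0))
  }, 1)
  mean(ds)
}

#' Evaluate mean tile Dice of a model on a tile set
#'
#' @param model an `nm_model`.
#' @param tiles list of tiles (e.g. the `test` component of `nm_tiles`).
#' @param threshold binarization threshold.
#' @return mean Dice across tiles.
#' @export
evaluate_tiles <- function(model, tiles, threshold = 0.5) {
  validation_dice_at <- vapply(tiles, function(tl) {
    p <- predict_tile(model, tl$image)
    as.numeric(dice((p >= threshold) & (tl$weight > 0), tl$mask > 0))
  }, 1)
  mean(validation_dice_at)
}

#' Save / load a model checkpoint as JSON
#'
#' The checkpoint is self-describing: it embeds the model spec so
#' [load_checkpoint()] can rebuild the architecture before restoring the
#' weights. Plain-text JSON keeps checkpoints portable and diffable.
#'
#' @param model an `nm_model`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  pr <- lapply(model$params, function(p)
    list(W = as.vector(p$W), dimW = dim(p$W), b = p$b,
         k = p$k, dil = p$dil, Cin = p$Cin, Cout = p$Cout))
  js <- list(spec = unclass(model$spec), in_channels = model$in_channels,
             channels = model$channels, params = pr,
             history = model$history, best_epoch = model$best_epoch)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(seg_model_spec, js$spec[c("variant", "structure",
                                            "input_magnification", "scales",
                                            "base_channels", "depth",
                                            "dilation_rates", "seed")])
  model <- build_model(spec, in_channels = js$in_channels)
  for (nm in names(js$params)) {
    p <- js$params[[nm]]
    model$params[[nm]]$W <- matrix(p$W, p$dimW[1], p$dimW[2])
    model$params[[nm]]$b <- as.numeric(p$b)
  }
  if (!is.null(js$history)) model$history <- tibble::as_tibble(js$history)
  model$best_epoch <- js$best_epoch
  model
}

#' Canonical training configuration for the synthetic segmentation benchmark
#'
#' 64 px tiles with 16 px overlap over 18 one-section slides split 12/3/3,
#' six epochs — sized so a benchmark model trains in about 90 seconds on one
#' CPU while clearing the mechanism thresholds comfortably.
#'
#' @param epochs training epochs.
#' @param seed seed for shuffling / augmentation.
#' @return a [train_config()].
#' @export
benchmark_train_config <- function(epochs = 6L, seed = 7L) {
  train_config(tile_px = 64L, overlap_px = 16L, epochs = epochs,
               split = c(train = 12L, val = 3L, test = 3L), seed = seed)
}

#' Model specification used by the synthetic segmentation benchmark
#'
#' Depth 3 with 8 base channels: the smallest configuration whose
#' receptive-field contrast between variants is still meaningful.
#'
#' @param variant network variant.
#' @param structure `"gc"` or `"sinus"`.
#' @param seed weight-initialization seed.
#' @return a [seg_model_spec()].
#' @export
benchmark_model_spec <- function(variant = "ms_unet", structure = "gc", seed = 11L) {
  seg_model_spec(variant = variant, structure = structure,
                 base_channels = 8L, depth = 3L,
                 dilation_rates = c(1L, 2L, 4L), seed = seed)
}
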