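#' Specification of a segmentation network
#'
#' Three fully convolutional encoder-decoder variants for binary structure
#' segmentation on tiles:
#'
#' * `unet` — standard U-Net: per level two 3x3 convolutions + ReLU,
#'   2x2 max-pooling down, nearest-neighbour upsampling and skip
#'   concatenation up, 1x1 head producing one logit per pixel.
#' * `atten_unet` — the same with additive attention gates on the skip
#'   connections, upweighting salient skip features with a mask computed
#'   from the decoder state.
#' * `ms_unet` — multiscale U-Net: the first convolution of every encoder
#'   level is replaced by parallel atrous branches at the given dilation
#'   rates, concatenated and fused by a 1x1 convolution, so each level sees
#'   receptive fields matching several magnifications (rates 1/2/4 mirror
#'   x10/x5/x2.5 fields of view) in a single forward pass.
#'
#' @param variant `"unet"`, `"atten_unet"` or `"ms_unet"`.
#' @param structure `"gc"` or `"sinus"` (label only; the network is binary).
#' @param input_magnification tag, one of `"x2_5"`, `"x5"`, `"x10"`.
#' @param scales ordered downsample factors assimilated by `ms_unet`.
#' @param base_channels channels at the first level; doubled per level.
#' @param depth number of encoder levels (5 for the full-size
#'   configuration; small benchmark models use 3).
#' @param dilation_rates atrous rates for `ms_unet`, one per scale.
#' @param seed seed for deterministic weight initialization.
#' @return object of class `seg_model_spec`.
#' @export
seg_model_spec <- function(variant = c("ms_unet", "unet", "atten_unet"),
                           structure = c("gc", "sinus"),
                           input_magnification = c("x10", "x5", "x2_5"),
                           scales = c(1L, 2L, 4L),
                           base_channels = 16L,
                           depth = 5L,
                           dilation_rates = c(1L, 2L, 4L),
                           seed = 1L) {
  variant <- match.arg(variant)
  structure_ <- match.arg(structure)
  if (depth < 2L) stop("depth must be >= 2")
  if (variant == "ms_unet") {
    if (length(scales) < 2L)
      stop("ms_unet requires at least 2 scales")
    if (length(dilation_rates) != length(scales))
      stop("dilation_rates must have one rate per scale")
  }
  structure(list(variant = variant, structure = structure_,
                 input_magnification = match.arg(input_magnification),
                 scales = as.integer(scales),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 dilation_rates = as.integer(dilation_rates),
                 seed = as.integer(seed)),
            class = "seg_model_spec")
}

#' Build a segmentation model from its specification
#'
#' Weight initialization is He-normal and fully determined by `spec$seed`.
#'
#' @param spec a [seg_model_spec()].
#' @param in_channels input channels (3 for RGB tiles).
#' @return object of class `nm_model` holding the parameter list, the spec,
#'   and (after [train()]) the training history.
#' @export
build_model <- function(spec, in_channels = 3L) {
  stopifnot(inherits(spec, "seg_model_spec"))
  withr::with_seed(spec$seed, {
    ch <- spec$base_channels * 2L ^ (seq_len(spec$depth) - 1L)
    pr <- list()
    cin <- in_channels
    for (i in seq_len(spec$depth)) {
      if (spec$variant == "ms_unet") {
        for (s in seq_along(spec$dilation_rates))
          pr[[sprintf("e%d.b%d", i, s)]] <-
            conv_param(cin, ch[i], 3L, spec$dilation_rates[s])
        pr[[sprintf("e%d.fuse", i)]] <-
          conv_param(ch[i] * length(spec$dilation_rates), ch[i], 1L)
      } else {
        pr[[sprintf("e%d.c1", i)]] <- conv_param(cin, ch[i], 3L)
      }
      pr[[sprintf("e%d.c2", i)]] <- conv_param(ch[i], ch[i], 3L)
      cin <- ch[i]
    }
    for (j in seq_len(spec$depth - 1L)) {
      pr[[sprintf("d%d.up", j)]] <- conv_param(ch[j + 1L], ch[j], 3L)
      pr[[sprintf("d%d.c", j)]] <- conv_param(2L * ch[j], ch[j], 3L)
      if (spec$variant == "atten_unet") {
        ci <- max(1L, ch[j] %/% 2L)
        pr[[sprintf("a%d.x", j)]] <- conv_param(ch[j], ci, 1L)
        pr[[sprintf("a%d.g", j)]] <- conv_param(ch[j], ci, 1L)
        pr[[sprintf("a%d.psi", j)]] <- conv_param(ci, 1L, 1L)
      }
    }
    pr[["head"]] <- conv_param(ch[1], 1L, 1L)
    structure(list(spec = spec, params = pr, in_channels = in_channels,
                   channels = ch, history = NULL),
              class = "nm_model")
  })
}

#' @export
print.nm_model <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 1))
  cat(sprintf("<nm_model %s/%s: depth %d, base %d, %s parameters>\n",
              x$spec$variant, x$spec$structure, x$spec$depth,
              x$spec$base_channels, format(npar, big.mark = ",")))
  invisible(x)
}

check_tile_dims <- function(model, x) {
  d <- dim(x)
  div <- 2L ^ (model$spec$depth - 1L)
  if (length(d) != 3L || d[3] != model$in_channels)
    stop(sprintf("tile must be H x W x %d", model$in_channels))
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("tile dimensions must be divisible by %d for depth %d",
                 div, model$spec$depth))
  invisible(TRUE)
}

# Full forward pass; returns logits plus every cache needed for backward.
model_fwd <- function(model, x) {
  sp <- model$spec; pr <- model$params
  D <- sp$depth
  caches <- list(enc = vector("list", D), pool = vector("list", D - 1L),
                 dec = vector("list", D - 1L))
  h <- x
  enc_out <- vector("list", D)
  for (i in seq_len(D)) {
    cc <- list()
    if (sp$variant == "ms_unet") {
      br <- lapply(seq_along(sp$dilation_rates), function(s)
        conv_fwd(h, pr[[sprintf("e%d.b%d", i, s)]]))
      cat_in <- Reduce(concat3, lapply(br, `[[`, "y"))
      fu <- conv_fwd(cat_in, pr[[sprintf("e%d.fuse", i)]])
      r1 <- relu_fwd(fu$y)
      cc$branches <- br; cc$fuse <- fu; cc$r1 <- r1
    } else {
      c1 <- conv_fwd(h, pr[[sprintf("e%d.c1", i)]])
      r1 <- relu_fwd(c1$y)
      cc$c1 <- c1; cc$r1 <- r1
    }
    c2 <- conv_fwd(r1$y, pr[[sprintf("e%d.c2", i)]])
    r2 <- relu_fwd(c2$y)
    cc$c2 <- c2; cc$r2 <- r2
    caches$enc[[i]] <- cc
    enc_out[[i]] <- r2$y
    if (i < D) {
      pl <- maxpool_fwd(r2$y)
      caches$pool[[i]] <- pl
      h <- pl$y
    }
  }
  d <- enc_out[[D]]
  for (j in rev(seq_len(D - 1L))) {
    cc <- list()
    up <- upsample_fwd(d)
    uc <- conv_fwd(up, pr[[sprintf("d%d.up", j)]])
    ur <- relu_fwd(uc$y)
    skip <- enc_out[[j]]
    if (sp$variant == "atten_unet") {
      ax <- conv_fwd(skip, pr[[sprintf("a%d.x", j)]])
      ag <- conv_fwd(ur$y, pr[[sprintf("a%d.g", j)]])
      aq <- relu_fwd(ax$y + ag$y)
      ap <- conv_fwd(aq$y, pr[[sprintf("a%d.psi", j)]])
      gate <- sigmoid(ap$y)
      gated <- skip * as.vector(gate)
      cc$att <- list(ax = ax, ag = ag, aq = aq, ap = ap, gate = gate, skip = skip)
      skip <- gated
    }
    cat_in <- concat3(ur$y, skip)
    dc <- conv_fwd(cat_in, pr[[sprintf("d%d.c", j)]])
    dr <- relu_fwd(dc$y)
    cc$uc <- uc; cc$ur <- ur; cc$dc <- dc; cc$dr <- dr
    caches$dec[[j]] <- cc
    d <- dr$y
  }
  hd <- conv_fwd(d, pr[["head"]])
  caches$head <- hd
  list(logits = hd$y[, , 1], caches = caches)
}

# Backward pass from d(loss)/d(logits); returns parameter gradients.
# Forward decoded j = D-1 .. 1, so backward walks j = 1 .. D-1, chaining
# the running gradient `dd` from each decoder block into the next deeper
# one, then sweeps the encoder from the bottleneck down to the input.
model_bwd <- function(model, dlogits, caches) {
  sp <- model$spec; pr <- model$params
  D <- sp$depth
  gr <- list()
  add_grad <- function(nm, g) {
    if (is.null(gr[[nm]])) gr[[nm]] <<- list(W = g$dW, b = g$db)
    else {
      gr[[nm]]$W <<- gr[[nm]]$W + g$dW
      gr[[nm]]$b <<- gr[[nm]]$b + g$db
    }
    g$dx
  }
  dz <- array(dlogits, c(dim(dlogits)[1], dim(dlogits)[2], 1L))
  dd <- add_grad("head", conv_bwd(dz, pr[["head"]], caches$head))

  dskip_acc <- vector("list", D)   # gradients flowing into encoder outputs
  for (j in seq_len(D - 1L)) {
    cc <- caches$dec[[j]]
    ddc <- relu_bwd(dd, cc$dr)
    dcat <- add_grad(sprintf("d%d.c", j),
                     conv_bwd(ddc, pr[[sprintf("d%d.c", j)]], cc$dc))
    parts <- split3(dcat, model$channels[j])
    dur <- parts[[1]]; dskip <- parts[[2]]
    if (sp$variant == "atten_unet") {
      at <- cc$att
      gate <- as.vector(at$gate)
      dskip_direct <- dskip * gate
      dgate <- array(apply(dskip * at$skip, c(1, 2), sum),
                     c(dim(at$gate)[1], dim(at$gate)[2], 1L))
      dap <- dgate * at$gate * (1 - at$gate)
      dq <- add_grad(sprintf("a%d.psi", j),
                     conv_bwd(dap, pr[[sprintf("a%d.psi", j)]], at$ap))
      dq <- relu_bwd(dq, at$aq)
      dskip_direct <- dskip_direct +
        add_grad(sprintf("a%d.x", j),
                 conv_bwd(dq, pr[[sprintf("a%d.x", j)]], at$ax))
      dur <- dur + add_grad(sprintf("a%d.g", j),
                            conv_bwd(dq, pr[[sprintf("a%d.g", j)]], at$ag))
      dskip <- dskip_direct
    }
    dskip_acc[[j]] <- dskip
    duc <- relu_bwd(dur, cc$ur)
    dup <- add_grad(sprintf("d%d.up", j),
                    conv_bwd(duc, pr[[sprintf("d%d.up", j)]], cc$uc))
    dd <- upsample_bwd(dup)  # gradient on d_{j+1} (deeper decoder/bottleneck)
  }
  dskip_acc[[D]] <- dd

  for (i in rev(seq_len(D))) {
    cc <- caches$enc[[i]]
    de <- dskip_acc[[i]]
    dc2in <- relu_bwd(de, cc$r2)
    dr1 <- add_grad(sprintf("e%d.c2", i),
                    conv_bwd(dc2in, pr[[sprintf("e%d.c2", i)]], cc$c2))
    dr1 <- relu_bwd(dr1, cc$r1)
    if (sp$variant == "ms_unet") {
      dcat <- add_grad(sprintf("e%d.fuse", i),
                       conv_bwd(dr1, pr[[sprintf("e%d.fuse", i)]], cc$fuse))
      chi <- model$channels[i]
      dh <- NULL
      for (s in seq_along(sp$dilation_rates)) {
        dbr <- dcat[, , ((s - 1L) * chi + 1L):(s * chi), drop = FALSE]
        dxs <- add_grad(sprintf("e%d.b%d", i, s),
                        conv_bwd(dbr, pr[[sprintf("e%d.b%d", i, s)]],
                                 cc$branches[[s]]))
        dh <- if (is.null(dh)) dxs else dh + dxs
      }
    } else {
      dh <- add_grad(sprintf("e%d.c1", i),
                     conv_bwd(dr1, pr[[sprintf("e%d.c1", i)]], cc$c1))
    }
    if (i > 1L) {
      dprev <- maxpool_bwd(dh, caches$pool[[i - 1L]])
      dskip_acc[[i - 1L]] <- dskip_acc[[i - 1L]] + dprev
    }
  }
  gr
}

#' Predict per-pixel structure probability for a tile
#'
#' @param model an `nm_model` (or a stub model from [stub_model()]).
#' @param tile `H x W x 3` RGB array (dimensions must satisfy the model's
#'   divisibility contract) or a grayscale matrix for single-channel stubs.
#' @return numeric matrix of probabilities in `[0, 1]`.
#' @export
predict_tile <- function(model, tile) UseMethod("predict_tile")

#' @export
predict_tile.nm_model <- function(model, tile) {
  check_tile_dims(model, tile)
  sigmoid(model_fwd(model, tile)$logits)
}

#' A stub model with a fixed prediction function
#'
#' Used for stitching-consistency checks: the stub applies `fn` to a tile
#' and must return a probability matrix of the tile's spatial dimensions.
#'
#' @param fn function(tile) -> probability matrix.
#' @return object of class `nm_stub_model`.
#' @export
stub_model <- function(fn) structure(list(fn = fn), class = "nm_stub_model")

#' @export
predict_tile.nm_stub_model <- function(model, tile) {
  p <- model$fn(tile)
  stopifnot(all(dim(p)[1:2] == dim(tile)[1:2]))
  p
}
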