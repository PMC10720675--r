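#' Minimal fully-convolutional network engine.
#'
#' Feature maps are `H x W x C` numeric arrays. Convolutions are 'same'
#' stride-1, realised as im2col gathers followed by a single matrix
#' multiply; dilation spaces the taps (atrous convolution), enlarging the
#' receptive field without downsampling. Backward passes are written out
#' explicitly; all randomness flows through the R RNG so runs are
#' bit-reproducible for a fixed seed.
#'
#' @name nn-core
#' @keywords internal
NULL

conv_param <- function(Cin, Cout, k = 3L, dil = 1L) {
  sd <- sqrt(2 / (k * k * Cin))
  list(W = matrix(rnorm(k * k * Cin * Cout, 0, sd), k * k * Cin, Cout),
       b = numeric(Cout), k = k, dil = dil, Cin = Cin, Cout = Cout)
}

# forward: compiled im2col + matmul; the input is cached for the backward
conv_fwd <- function(x, p) {
  list(y = .nm_conv_fwd(x, p$W, p$b, p$k, p$dil), x = x)
}

# backward: dW from the regathered input patches; dx is itself a
# convolution of dy with the spatially flipped weights
conv_bwd <- function(dy, p, cache) {
  .nm_conv_bwd(cache$x, p$W, dy, p$k, p$dil)
}

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, cache) dy * cache$mask

sigmoid <- function(z) 1 / (1 + exp(-z))

maxpool_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  a <- x[io, jo, , drop = FALSE]; b <- x[io + 1L, jo, , drop = FALSE]
  cc <- x[io, jo + 1L, , drop = FALSE]; d <- x[io + 1L, jo + 1L, , drop = FALSE]
  m <- pmax(a, b, cc, d)
  sel <- array(4L, dim(m))
  sel[cc == m] <- 3L; sel[b == m] <- 2L; sel[a == m] <- 1L
  list(y = m, sel = sel, H = H, W = W)
}

maxpool_bwd <- function(dy, cache) {
  H <- cache$H; W <- cache$W
  dx <- array(0, c(H, W, dim(dy)[3]))
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  sel <- cache$sel
  for (s in 1:4) {
    dr <- c(0L, 1L, 0L, 1L)[s]; dc <- c(0L, 0L, 1L, 1L)[s]
    hit <- (sel == s) * dy
    dx[io + dr, jo + dc, ] <- dx[io + dr, jo + dc, ] + hit
  }
  dx
}

upsample_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
}

upsample_bwd <- function(dy) {
  H <- dim(dy)[1]; W <- dim(dy)[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  dy[io, jo, , drop = FALSE] + dy[io + 1L, jo, , drop = FALSE] +
    dy[io, jo + 1L, , drop = FALSE] + dy[io + 1L, jo + 1L, , drop = FALSE]
}

concat3 <- function(a, b) array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))

split3 <- function(x, c1) {
  list(x[, , seq_len(c1), drop = FALSE],
       x[, , (c1 + 1L):dim(x)[3], drop = FALSE])
}

# Combined pixel-weighted binary cross-entropy + soft Dice on logits.
# Returns the scalar loss and its gradient w.r.t. the logits.
seg_loss <- function(z, y, w, kind = "bce_plus_dice") {
  sw <- sum(w)
  p <- sigmoid(z)
  bce <- sum(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z))))) / sw
  dz_bce <- w * (p - y) / sw
  if (kind == "bce") return(list(loss = bce, dz = dz_bce))
  s <- 1
  num <- 2 * sum(w * p * y) + s
  den <- sum(w * p) + sum(w * y) + s
  dloss <- 1 - num / den
  dp <- -(2 * w * y * den - num * w) / den ^ 2
  dz_dice <- dp * p * (1 - p)
  if (kind == "dice") return(list(loss = dloss, dz = dz_dice))
  list(loss = bce + dloss, dz = dz_bce + dz_dice)
}

adam_init <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(params)) {
    st$m[[nm]] <- list(W = params[[nm]]$W * 0, b = params[[nm]]$b * 0)
    st$v[[nm]] <- st$m[[nm]]
  }
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1 ^ st$t; bc2 <- 1 - beta2 ^ st$t
  for (nm in names(grads)) {
    for (f in c("W", "b")) {
      g <- grads[[nm]][[f]]
      st$m[[nm]][[f]] <- beta1 * st$m[[nm]][[f]] + (1 - beta1) * g
      st$v[[nm]][[f]] <- beta2 * st$v[[nm]][[f]] + (1 - beta2) * g ^ 2
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (st$m[[nm]][[f]] / bc1) / (sqrt(st$v[[nm]][[f]] / bc2) + eps)
    }
  }
  list(params = params, state = st)
}
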