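#' Raster helpers shared by the detection, morphometry and synthesis code.
#'
#' All functions follow the package coordinate conventions (see
#' [nodemorph-package]): matrices are `[row, col]`, polygons are `(x = col,
#' y = row)` in pixel-center coordinates.
#' @name raster-helpers
#' @keywords internal
NULL

#' Luminance grayscale of an RGB array
#'
#' Bright-field H&E convention: tissue is dark, background bright.
#'
#' @param img `H x W x 3` numeric array in `[0, 1]`, or a matrix (returned
#'   unchanged).
#' @return numeric matrix in `[0, 1]`.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Trace the outer contour of a binary mask as a sub-pixel polygon
#'
#' Marching-squares contour at level 0.5 on the zero-padded mask, followed by
#' light moving-average smoothing of the vertex chain. The smoothing removes
#' the staircase bias that would otherwise inflate perimeters of rasterized
#' shapes by several percent.
#'
#' @param mask binary/logical matrix with a single foreground component (when
#'   several loops exist the longest is returned).
#' @param smooth_iter smoothing passes over the closed vertex chain.
#' @return two-column matrix `(x = col, y = row)`, open (no repeated vertex).
#' @export
trace_contour <- function(mask, smooth_iter = 2L) {
  mask <- mask * 1
  if (sum(mask) == 0) stop("empty mask: no contour to trace")
  zm <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  zm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  cl <- grDevices::contourLines(x = seq_len(nrow(zm)) - 1L,
                                y = seq_len(ncol(zm)) - 1L,
                                z = zm, levels = 0.5)
  if (!length(cl)) stop("degenerate mask: no 0.5-level contour")
  l <- cl[[which.max(vapply(cl, function(p) length(p$x), 1L))]]
  xy <- cbind(x = l$y, y = l$x)  # contourLines x runs over rows
  n <- nrow(xy)
  if (n > 1L && all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3L) stop("degenerate mask: contour has fewer than 3 vertices")
  for (i in seq_len(smooth_iter)) {
    up <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
    dn <- rbind(xy[nrow(xy), , drop = FALSE], xy[-nrow(xy), , drop = FALSE])
    xy <- (dn + 2 * xy + up) / 4
  }
  xy
}

#' Rasterize a polygon to a binary mask (even-odd rule)
#'
#' @param poly two-column `(x, y)` matrix.
#' @param dim `c(nrow, ncol)` of the target raster.
#' @return logical matrix; a pixel is inside when its center is inside.
#' @export
rasterize_polygon <- function(poly, dim) {
  r0 <- max(1L, floor(min(poly[, 2])) - 1L); r1 <- min(dim[1], ceiling(max(poly[, 2])) + 1L)
  c0 <- max(1L, floor(min(poly[, 1])) - 1L); c1 <- min(dim[2], ceiling(max(poly[, 1])) + 1L)
  out <- matrix(FALSE, dim[1], dim[2])
  if (r1 < r0 || c1 < c0) return(out)
  rr <- r0:r1; cc <- c0:c1
  pts <- cbind(rep(cc, each = length(rr)), rep(rr, times = length(cc)))
  bnd <- rbind(poly, poly[1, ])
  inside <- mgcv::in.out(bnd, pts)
  out[r0:r1, c0:c1] <- matrix(inside, length(rr), length(cc))
  out
}

#' Point-in-polygon test
#' @keywords internal
points_in_polygon <- function(pts, poly) {
  mgcv::in.out(rbind(poly, poly[1, ]), pts)
}

#' Block-average downsampling of a matrix or RGB array
#'
#' Pads by edge replication so output dimensions are `ceiling(dim / factor)`.
#' @keywords internal
block_downsample <- function(x, factor) {
  if (factor == 1L) return(x)
  ds1 <- function(m) {
    H <- nrow(m); W <- ncol(m)
    H2 <- ceiling(H / factor); W2 <- ceiling(W / factor)
    m <- m[clamp(seq_len(H2 * factor), 1L, H), clamp(seq_len(W2 * factor), 1L, W), drop = FALSE]
    # average rows then columns within factor-blocks
    m <- rowsum(m, rep(seq_len(H2), each = factor)) / factor
    t(rowsum(t(m), rep(seq_len(W2), each = factor)) / factor)
  }
  if (is.matrix(x)) return(ds1(x))
  out <- array(0, c(ceiling(nrow(x) / factor), ceiling(dim(x)[2] / factor), dim(x)[3]))
  for (k in seq_len(dim(x)[3])) out[, , k] <- ds1(x[, , k])
  out
}

#' Stamp a thick line segment into a logical mask
#'
#' Marks pixels whose center lies within `halfwidth` of the segment
#' `p0 -> p1` (points given as `(x, y)`), restricted to `region` when given.
#' @keywords internal
stamp_segment <- function(mask, p0, p1, halfwidth, region = NULL) {
  r0 <- max(1L, floor(min(p0[2], p1[2]) - halfwidth)); r1 <- min(nrow(mask), ceiling(max(p0[2], p1[2]) + halfwidth))
  c0 <- max(1L, floor(min(p0[1], p1[1]) - halfwidth)); c1 <- min(ncol(mask), ceiling(max(p0[1], p1[1]) + halfwidth))
  if (r1 < r0 || c1 < c0) return(mask)
  rr <- r0:r1; cc <- c0:c1
  X <- matrix(rep(cc, each = length(rr)), length(rr))
  Y <- matrix(rep(rr, times = length(cc)), length(rr))
  d <- p1 - p0; len2 <- sum(d ^ 2)
  if (len2 < 1e-12) {
    dist2 <- (X - p0[1]) ^ 2 + (Y - p0[2]) ^ 2
  } else {
    t <- clamp(((X - p0[1]) * d[1] + (Y - p0[2]) * d[2]) / len2, 0, 1)
    dist2 <- (X - (p0[1] + t * d[1])) ^ 2 + (Y - (p0[2] + t * d[2])) ^ 2
  }
  hit <- dist2 <= halfwidth ^ 2
  if (!is.null(region)) hit <- hit & region[rr, cc]
  mask[rr, cc] <- mask[rr, cc] | hit
  mask
}

#' Fill an ellipse into a logical mask
#'
#' @param center `(x, y)`; `a`, `b` semi-axes in pixels; `angle` radians.
#' @keywords internal
stamp_ellipse <- function(mask, center, a, b, angle) {
  ext <- max(a, b)
  r0 <- max(1L, floor(center[2] - ext)); r1 <- min(nrow(mask), ceiling(center[2] + ext))
  c0 <- max(1L, floor(center[1] - ext)); c1 <- min(ncol(mask), ceiling(center[1] + ext))
  rr <- r0:r1; cc <- c0:c1
  X <- matrix(rep(cc, each = length(rr)), length(rr)) - center[1]
  Y <- matrix(rep(rr, times = length(cc)), length(rr)) - center[2]
  u <- X * cos(angle) + Y * sin(angle)
  v <- -X * sin(angle) + Y * cos(angle)
  mask[rr, cc] <- mask[rr, cc] | ((u / a) ^ 2 + (v / b) ^ 2 <= 1)
  mask
}

#' Analytic circumference of an ellipse (Ramanujan's approximation)
#' @keywords internal
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b)) ^ 2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}
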