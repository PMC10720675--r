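#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Shoelace area of a closed polygon
#'
#' @param poly two-column matrix (x, y); the closing edge is implicit.
#' @return area in squared input units (always non-negative).
#' @keywords internal
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) stop("polygon needs at least 3 vertices")
  i2 <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2])) / 2
}

#' Perimeter (closed polyline length) of a polygon
#' @keywords internal
polygon_perimeter <- function(poly) {
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  sum(sqrt(rowSums((poly[i2, , drop = FALSE] - poly) ^ 2)))
}

polygon_centroid <- function(poly) {
  n <- nrow(poly); i2 <- c(2:n, 1L)
  cr <- poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(poly))
  c(sum((poly[, 1] + poly[i2, 1]) * cr) / (6 * a),
    sum((poly[, 2] + poly[i2, 2]) * cr) / (6 * a))
}

#' Convert a pixel area to mm^2 at a given scale
#' @keywords internal
px_area_to_mm2 <- function(px, mpp) px * mpp ^ 2 / 1e6

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

#' Normalise a range-or-scalar parameter to c(lo, hi)
#' @keywords internal
as_range <- function(x, name) {
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(!is.finite(x)) || x[2] < x[1])
    stop(sprintf("`%s` must be a scalar or an increasing range of length 2", name),
         call. = FALSE)
  as.numeric(x)
}

runif_range <- function(n, r) if (r[1] == r[2]) rep(r[1], n) else runif(n, r[1], r[2])

#' Sample an integer uniformly from an inclusive range
#' @keywords internal
sample_int_range <- function(n, r) {
  r <- as.integer(round(r))
  if (r[1] == r[2]) rep(r[1], n) else r[1] + floor(runif(n) * (r[2] - r[1] + 1L))
}

#' md5 checksum of a file (empty string when absent)
#' @keywords internal
file_checksum <- function(path) {
  if (!file.exists(path)) return("")
  unname(tools::md5sum(path))
}
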