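#' Otsu's threshold of an 8-bit intensity raster
#'
#' Returns the integer threshold `t` in `0..255` maximizing the between-class
#' variance `w0 * w1 * (mu0 - mu1)^2` of the split `value <= t` versus
#' `value > t`. Ties are broken toward the smallest maximizing threshold.
#'
#' @param gray numeric matrix; values in `[0, 1]` are scaled to 0-255, values
#'   already on the 0-255 scale are used as is.
#' @return integer threshold on the 0-255 scale.
#' @export
otsu_threshold <- function(gray) {
  v <- as.vector(gray)
  if (!length(v)) stop("empty raster")
  if (max(v) <= 1 + 1e-9) v <- v * 255
  v <- as.integer(round(clamp(v, 0, 255)))
  if (length(unique(v)) < 2L)
    stop("Otsu threshold undefined for a constant raster")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                 # P(value <= t), t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  t_all <- 0:255
  denom <- omega * (1 - omega)
  bcv <- (mu_t * omega - mu) ^ 2 / ifelse(denom > 0, denom, NA)
  which.max(bcv) - 1L                # which.max skips NA, first max wins
}

#' Detect lymph-node sections on a slide
#'
#' The detection pipeline: luminance grayscale, Otsu foreground (tissue is
#' the dark class on bright-field H&E), morphological closing then opening
#' with a disc, hole filling, connected components, outer contour tracing,
#' rescaling of contours to the finest level, and a physical minimum-size
#' filter. A blank slide yields an empty result, not an error.
#'
#' Detection runs at a coarse pyramid level chosen so the analysed raster
#' stays at or below ~4 megapixels; Otsu and contouring are scale-stable so
#' the returned finest-level contours are insensitive to that choice.
#'
#' @param slide an `nm_slide` (finest level).
#' @param min_area_mm2 drop components below this physical area.
#' @param level pyramid factor for the analysis raster (1, 2, 4, 8, 16) or
#'   `NULL` to choose automatically.
#' @return tibble with one row per section, sorted left-to-right then
#'   top-to-bottom: `section_id`, `contour` (list of finest-level `(x, y)`
#'   matrices), `bbox` (list of `c(r0, c0, r1, c1)`), `area_mm2`,
#'   `involvement` (initialised `"unknown"`).
#' @export
detect_ln_sections <- function(slide, min_area_mm2 = 0.5, level = NULL) {
  stopifnot(inherits(slide, "nm_slide"), min_area_mm2 >= 0)
  if (is.null(level)) {
    npx <- prod(dim(slide$image)[1:2])
    level <- 1L
    while (npx / level ^ 2 > 4e6 && level < 16L) level <- level * 2L
  }
  det <- render_magnification(slide, level)
  g <- as_gray(det$image)
  t8 <- tryCatch(otsu_threshold(g), error = function(e) NA_integer_)
  if (is.na(t8)) return(empty_sections())
  fg <- round(g * 255) <= t8         # dark class (value <= t) = tissue
  if (!any(fg)) return(empty_sections())
  brush <- EBImage::makeBrush(11L, "disc")   # radius 5 disc
  fg <- EBImage::opening(EBImage::closing(fg * 1, brush), brush)
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  nlab <- max(lab)
  if (nlab == 0) return(empty_sections())

  min_area_px <- min_area_mm2 * 1e6 / det$mpp ^ 2
  rows <- list()
  for (i in seq_len(nlab)) {
    m <- lab == i
    if (sum(m) < max(min_area_px, 16)) next
    poly <- tryCatch(trace_contour(m), error = function(e) NULL)
    if (is.null(poly)) next
    poly_fine <- (poly - 0.5) * level + 0.5  # pixel-center rescale to level 1
    area <- px_area_to_mm2(polygon_area(poly_fine), slide$mpp)
    if (area < min_area_mm2) next
    bbox <- c(floor(min(poly_fine[, 2])), floor(min(poly_fine[, 1])),
              ceiling(max(poly_fine[, 2])), ceiling(max(poly_fine[, 1])))
    bbox <- as.integer(c(max(1L, bbox[1]), max(1L, bbox[2]),
                         min(dim(slide$image)[1], bbox[3]),
                         min(dim(slide$image)[2], bbox[4])))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      contour = list(poly_fine), bbox = list(bbox), area_mm2 = area,
      cx = mean(range(poly_fine[, 1])), cy = mean(range(poly_fine[, 2])))
  }
  if (!length(rows)) return(empty_sections())
  out <- dplyr::bind_rows(rows)
  out <- out[order(round(out$cx / 50), out$cy), ]    # left-to-right, then top-down
  out$section_id <- vapply(seq_len(nrow(out)), section_id, "")
  out$involvement <- "unknown"
  out[, c("section_id", "contour", "bbox", "area_mm2", "involvement")]
}

empty_sections <- function() {
  tibble::tibble(section_id = character(), contour = list(), bbox = list(),
                 area_mm2 = numeric(), involvement = character())
}

#' Physical area of a section polygon
#'
#' Shoelace pixel area scaled by `mpp^2 / 1e6`; a 1000 x 1000 px filled
#' square at 1 um/px is 1 mm^2.
#'
#' @param contour two-column `(x, y)` polygon (>= 3 vertices).
#' @param mpp microns per pixel of the contour frame.
#' @return area in mm^2.
#' @export
section_area <- function(contour, mpp) {
  if (is.list(contour) && !is.matrix(contour)) contour <- contour[[1]]
  if (nrow(contour) < 3L) stop("degenerate contour: fewer than 3 vertices")
  assert_scalar_num(mpp, "mpp", lo = 1e-9)
  px_area_to_mm2(polygon_area(contour), mpp)
}
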