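#' Extract germinal-centre instances from a binary mask
#'
#' 8-connected components with holes filled; components whose centroid lies
#' outside the LN contour and components below a physical minimum area are
#' dropped. Area, perimeter and circularity come from the traced sub-pixel
#' contour polygon of each component (pixel-count perimeters would bias
#' circularity upward substantially).
#'
#' @param gc_mask binary matrix in the section/slide frame.
#' @param ln_contour `(x, y)` polygon of the LN boundary in the same frame,
#'   or `NULL` to skip the containment filter.
#' @param mpp microns per pixel of the frame.
#' @param min_area_um2 drop instances below this area (default 2000 um^2,
#'   about a 50 um diameter follicle).
#' @return tibble with one row per instance: `instance_id`, `area_mm2`,
#'   `perimeter_mm`, `circularity`, `centroid_x`, `centroid_y`, `polygon`
#'   (list), `pixels` (list of pixel indices into the mask).
#' @export
extract_gc_instances <- function(gc_mask, ln_contour = NULL, mpp,
                                 min_area_um2 = 2000) {
  assert_scalar_num(mpp, "mpp", lo = 1e-9)
  lab <- EBImage::bwlabel(EBImage::fillHull((gc_mask > 0) * 1))
  nlab <- max(lab)
  rows <- list()
  for (i in seq_len(nlab)) {
    m <- lab == i
    idx <- which(m)
    rc <- arrayInd(idx, dim(m))
    cen <- c(mean(rc[, 2]), mean(rc[, 1]))    # (x, y)
    if (!is.null(ln_contour) && !points_in_polygon(matrix(cen, 1), ln_contour))
      next
    poly <- tryCatch(trace_contour(m), error = function(e) NULL)
    if (is.null(poly)) next
    area_um2 <- polygon_area(poly) * mpp ^ 2
    if (area_um2 < min_area_um2) next
    per_mm <- polygon_perimeter(poly) * mpp / 1e3
    area_mm2 <- area_um2 / 1e6
    rows[[length(rows) + 1L]] <- tibble::tibble(
      area_mm2 = area_mm2, perimeter_mm = per_mm,
      circularity = 4 * pi * area_mm2 / per_mm ^ 2,
      centroid_x = cen[1], centroid_y = cen[2],
      polygon = list(poly), pixels = list(idx))
  }
  if (!length(rows))
    return(tibble::tibble(instance_id = character(), area_mm2 = numeric(),
                          perimeter_mm = numeric(), circularity = numeric(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          polygon = list(), pixels = list()))
  out <- dplyr::bind_rows(rows)
  out$instance_id <- sprintf("GC%03d", seq_len(nrow(out)))
  out[, c("instance_id", "area_mm2", "perimeter_mm", "circularity",
          "centroid_x", "centroid_y", "polygon", "pixels")]
}

#' Isoperimetric circularity of a region
#'
#' `4 * pi * area / perimeter^2`; 1 for a disk, `pi/4` for a square, near 0
#' for a thin bar. Units cancel as long as area and perimeter share a scale.
#'
#' @param area region area.
#' @param perimeter region perimeter (> 0).
#' @return dimensionless circularity.
#' @export
circularity <- function(area, perimeter) {
  if (!is.finite(perimeter) || perimeter <= 0)
    stop("degenerate region: perimeter must be > 0")
  4 * pi * area / perimeter ^ 2
}

#' Per-LN morphometric feature record
#'
#' GC count and means over instances (missing, not zero, when no GC is
#' present), total sinus area clipped to the LN contour, the dimensionless
#' normalized sinus area (sinus / LN area), and the heuristic SCS width.
#'
#' @param instances tibble from [extract_gc_instances()].
#' @param sinus_mask binary matrix in the same frame (or `NULL`).
#' @param contour LN boundary polygon.
#' @param mpp microns per pixel.
#' @param section_id,involvement carried into the record.
#' @param scs logical; also run [scs_width()] (needs `sinus_mask`).
#' @return one-row tibble: `section_id`, `involvement`, `gc_count`,
#'   `mean_gc_area_mm2`, `mean_gc_circularity`, `sinus_area_mm2`,
#'   `normalized_sinus_area`, `scs_width_um`, `section_area_mm2`.
#' @export
ln_features <- function(instances, sinus_mask, contour, mpp,
                        section_id = "S01", involvement = "unknown",
                        scs = TRUE) {
  if (is.list(contour) && !is.matrix(contour)) contour <- contour[[1]]
  sec_area <- section_area(contour, mpp)
  if (sec_area <= 0) stop("zero section area")
  n_gc <- nrow(instances)
  sinus_area <- 0
  scs_um <- NA_real_
  if (!is.null(sinus_mask)) {
    inside <- rasterize_polygon(contour, dim(sinus_mask))
    sinus_area <- px_area_to_mm2(sum(sinus_mask & inside), mpp)
    if (scs) scs_um <- scs_width(contour, sinus_mask, mpp)$scs_width_um
  }
  tibble::tibble(
    section_id = section_id, involvement = involvement,
    gc_count = n_gc,
    mean_gc_area_mm2 = if (n_gc > 0) mean(instances$area_mm2) else NA_real_,
    mean_gc_circularity = if (n_gc > 0) mean(instances$circularity) else NA_real_,
    sinus_area_mm2 = sinus_area,
    normalized_sinus_area = min(1, sinus_area / sec_area),
    scs_width_um = scs_um,
    section_area_mm2 = sec_area)
}

#' Heuristic subcapsular sinus width
#'
#' Operationalizes the four-point capsule measurement: the reference axis is
#' the longest chord across the LN contour, a second axis runs orthogonal to
#' it through the contour centroid, and at each of the four axis-boundary
#' intersections the width is the longest run of sinus pixels encountered
#' while walking inward from the capsule within a band of depth `d_band_um`.
#' If the exact ray misses sinus entirely, directions within +/-5 degrees
#' are searched; a still-missing intersection contributes width 0 and is
#' flagged. The reported width is the mean of the four measurements.
#'
#' @param contour LN boundary polygon `(x, y)`.
#' @param sinus_mask binary sinus raster in the contour frame.
#' @param mpp microns per pixel.
#' @param d_band_um capsule band depth searched inward (default 200 um).
#' @return one-row tibble: `w1`..`w4` (um), `scs_width_um` (their mean),
#'   `n_missed`, plus the axis endpoints as attributes `major_axis` /
#'   `orthogonal_axis`.
#' @export
scs_width <- function(contour, sinus_mask, mpp, d_band_um = 200) {
  if (is.list(contour) && !is.matrix(contour)) contour <- contour[[1]]
  if (nrow(contour) < 3L) stop("degenerate contour")
  assert_scalar_num(mpp, "mpp", lo = 1e-9)

  hull <- contour[grDevices::chull(contour), , drop = FALSE]
  d2 <- as.matrix(stats::dist(hull))
  far <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  p1 <- hull[far[1], ]; p2 <- hull[far[2], ]
  u <- (p2 - p1) / sqrt(sum((p2 - p1) ^ 2))     # major-axis direction
  v <- c(-u[2], u[1])                            # orthogonal direction
  cen <- polygon_centroid(contour)

  # boundary hit along direction dir from the centroid: last inside sample
  boundary_hit <- function(dir) {
    span <- max(d2)
    ts <- seq(0, span, by = 0.5)
    pts <- cbind(cen[1] + ts * dir[1], cen[2] + ts * dir[2])
    ins <- points_in_polygon(pts, contour)
    k <- which(!ins)[1]
    if (is.na(k)) k <- length(ts) + 1L
    ts[max(1L, k - 1L)]
  }

  probe <- function(dir) {
    t_b <- boundary_hit(dir)
    step <- 0.25
    best <- 0
    for (ddeg in c(0, -5, 5)) {
      a <- ddeg * pi / 180
      dr <- c(dir[1] * cos(a) - dir[2] * sin(a), dir[1] * sin(a) + dir[2] * cos(a))
      depth <- min(d_band_um / mpp, t_b)
      ts <- seq(0, depth, by = step)
      pts <- cbind(cen[1] + (t_b - ts) * dr[1], cen[2] + (t_b - ts) * dr[2])
      r <- round(pts[, 2]); c <- round(pts[, 1])
      ok <- r >= 1 & r <= nrow(sinus_mask) & c >= 1 & c <= ncol(sinus_mask)
      hit <- rep(FALSE, length(ts))
      hit[ok] <- sinus_mask[cbind(r[ok], c[ok])]
      if (!any(hit)) next
      runs <- rle(hit)
      best <- max(best, max(runs$lengths[runs$values]) * step)
      if (ddeg == 0) break
    }
    best
  }

  dirs <- list(u, -u, v, -v)
  w_px <- vapply(dirs, probe, 1)
  w_um <- w_px * mpp
  out <- tibble::tibble(w1 = w_um[1], w2 = w_um[2], w3 = w_um[3], w4 = w_um[4],
                        scs_width_um = mean(w_um), n_missed = sum(w_um == 0))
  attr(out, "major_axis") <- rbind(p1, p2)
  attr(out, "orthogonal_axis") <- rbind(cen - v * 10, cen + v * 10)
  out
}

#' Mean SCS width from four point measurements
#'
#' The four capsule-width measurements are averaged into the per-node score.
#'
#' @param w numeric vector of four non-negative widths (um).
#' @return one-row tibble `w1..w4`, `scs_width_um`.
#' @export
scs_measurement <- function(w) {
  stopifnot(length(w) == 4L, all(w >= 0))
  tibble::tibble(w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4],
                 scs_width_um = mean(w), n_missed = sum(w == 0))
}

#' Precision / recall / F1 of predicted GC instances
#'
#' Greedy one-to-one matching by descending pairwise IoU; pairs with IoU at
#' or above the threshold are true positives. Empty prediction or truth
#' sets follow the 0-convention (F1 = 0 unless both are empty).
#'
#' @param pred,truth instance tibbles (from [extract_gc_instances()]) with a
#'   `pixels` list column, in the same frame.
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
gc_count_f1 <- function(pred, truth, iou_threshold = 0.5) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 && nt == 0)
    return(tibble::tibble(tp = 0L, fp = 0L, fn = 0L,
                          precision = 1, recall = 1, f1 = 1))
  if (np == 0 || nt == 0)
    return(tibble::tibble(tp = 0L, fp = np, fn = nt,
                          precision = 0, recall = 0, f1 = 0))
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    a <- pred$pixels[[i]]; b <- truth$pixels[[j]]
    inter <- length(intersect(a, b))
    if (inter > 0) iou[i, j] <- inter / (length(a) + length(b) - inter)
  }
  tp <- 0L
  repeat {
    m <- max(iou)
    if (m < iou_threshold) break
    k <- which(iou == m, arr.ind = TRUE)[1, ]
    tp <- tp + 1L
    iou[k[1], ] <- -1; iou[, k[2]] <- -1
  }
  prec <- tp / np; rec <- tp / nt
  f1 <- if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
  tibble::tibble(tp = tp, fp = np - tp, fn = nt - tp,
                 precision = prec, recall = rec, f1 = f1)
}

#' Quantify all sections of a slide from structure masks
#'
#' Convenience wrapper running [extract_gc_instances()] and [ln_features()]
#' per detected section.
#'
#' @param sections tibble from [detect_ln_sections()] (or ground-truth
#'   contours wrapped in the same shape).
#' @param gc_mask,sinus_mask binary matrices in the slide frame.
#' @param mpp microns per pixel of the masks.
#' @param min_area_um2 instance filter passed through.
#' @return tibble with one [ln_features()] row per section.
#' @export
quantify_sections <- function(sections, gc_mask, sinus_mask, mpp,
                              min_area_um2 = 2000) {
  rows <- lapply(seq_len(nrow(sections)), function(i) {
    ctr <- sections$contour[[i]]
    inst <- extract_gc_instances(gc_mask, ctr, mpp, min_area_um2)
    ln_features(inst, sinus_mask, ctr, mpp,
                section_id = sections$section_id[i],
                involvement = sections$involvement[i])
  })
  dplyr::bind_rows(rows)
}
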