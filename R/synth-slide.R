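#' Specification for a synthetic lymph-node slide
#'
#' Describes a white-background slide carrying one or more irregular
#' elliptical tissue sections, each with a pale subcapsular sinus (SCS) rim,
#' a branching intranodal sinus tree, and basophilic elliptical germinal
#' centre (GC) blobs. Colours are flat class colours plus Gaussian pixel
#' noise and a mild low-frequency intensity field; the generator is a
#' mechanism benchmark with analytically known ground truth, not a stain
#' simulator.
#'
#' Default physical scale is 4 microns per pixel, chosen so the planted
#' structures land in clinically familiar ranges: GC areas of roughly
#' 0.02-0.1 mm^2, SCS widths of 16-36 um straddling the 20 um prognostic
#' cut-off, and normalized sinus areas around 0.12.
#'
#' @param width_px,height_px slide canvas in pixels.
#' @param n_sections number of tissue sections to place.
#' @param section_radius_px range of mean section radii (pixels).
#' @param gc_count_per_section integer range (or fixed count) of GCs per
#'   section.
#' @param gc_radius_px range of GC semi-major axes (pixels).
#' @param gc_eccentricity range in `[0, 1)`; semi-minor `b = a*sqrt(1-e^2)`.
#' @param sinus_fraction target fraction of each section's area occupied by
#'   sinus pixels, in `[0, 0.5]`. The generator guarantees the achieved
#'   fraction within +/-20 percent relative.
#' @param scs_width_px range of SCS rim widths (pixels); capped per section
#'   so the rim alone cannot overshoot `sinus_fraction`.
#' @param capsule_px width of the fibrous capsule line drawn just outside
#'   the SCS rim (pixels); stains darker than the pale sinus lumen, as on
#'   H&E, which keeps the section boundary detectable.
#' @param mpp microns per pixel (> 0).
#' @param background_rgb,tissue_rgb,gc_rgb,sinus_rgb colour triplets, 0-255.
#' @param noise_sd Gaussian pixel noise standard deviation on the 0-255
#'   scale.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   spec.
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(width_px = 900L, height_px = 900L,
                       n_sections = 3L,
                       section_radius_px = c(110, 155),
                       gc_count_per_section = c(2L, 8L),
                       gc_radius_px = c(18, 40),
                       gc_eccentricity = c(0, 0.6),
                       sinus_fraction = 0.12,
                       scs_width_px = c(4, 8),
                       capsule_px = 3,
                       mpp = 4.0,
                       background_rgb = c(247, 247, 247),
                       tissue_rgb = c(199, 140, 170),
                       gc_rgb = c(120, 78, 155),
                       sinus_rgb = c(238, 226, 238),
                       capsule_rgb = c(158, 112, 140),
                       noise_sd = 12,
                       seed = 1L) {
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    n_sections = as.integer(n_sections),
    section_radius_px = as_range(section_radius_px, "section_radius_px"),
    gc_count_per_section = as_range(gc_count_per_section, "gc_count_per_section"),
    gc_radius_px = as_range(gc_radius_px, "gc_radius_px"),
    gc_eccentricity = as_range(gc_eccentricity, "gc_eccentricity"),
    sinus_fraction = sinus_fraction,
    scs_width_px = as_range(scs_width_px, "scs_width_px"),
    capsule_px = capsule_px,
    mpp = mpp,
    background_rgb = background_rgb, tissue_rgb = tissue_rgb,
    gc_rgb = gc_rgb, sinus_rgb = sinus_rgb, capsule_rgb = capsule_rgb,
    noise_sd = noise_sd, seed = as.integer(seed))
  validate_slide_spec(spec)
  structure(spec, class = "slide_spec")
}

validate_slide_spec <- function(s) {
  assert_scalar_num(s$mpp, "mpp", lo = 1e-6)
  assert_scalar_num(s$sinus_fraction, "sinus_fraction", 0, 0.5)
  assert_scalar_num(s$noise_sd, "noise_sd", 0)
  if (s$n_sections < 1L) stop("n_sections must be >= 1")
  if (any(s$section_radius_px <= 0) || any(s$gc_radius_px <= 0) ||
      any(s$scs_width_px <= 0))
    stop("all pixel ranges must be positive")
  if (s$gc_eccentricity[1] < 0 || s$gc_eccentricity[2] >= 1)
    stop("gc_eccentricity must lie in [0, 1)")
  # GC blobs occupy well under half the section by construction; combined
  # with the sinus target the structures must leave room for plain tissue
  if (s$sinus_fraction + 0.45 >= 1) stop("sinus_fraction too large")
  invisible(s)
}

# radial profile of an irregular blob: R(theta) = R0 * (1 + sum perturbation)
blob_radius_fun <- function(R0) {
  amp <- runif(3, 0.02, 0.06)
  phase <- runif(3, 0, 2 * pi)
  k <- 2:4
  function(theta) {
    pert <- amp[1] * cos(k[1] * theta + phase[1]) +
      amp[2] * cos(k[2] * theta + phase[2]) +
      amp[3] * cos(k[3] * theta + phase[3])
    R0 * (1 + pert)
  }
}

#' Generate a synthetic lymph-node slide with ground truth
#'
#' Renders the slide described by a [slide_spec()] and returns both the RGB
#' image and its construction-level ground truth: section contours, binary
#' GC and sinus masks (disjoint by construction), per-GC ellipse parameters,
#' and per-section planted morphometric features computed analytically from
#' the construction.
#'
#' @param spec a [slide_spec()].
#' @return list with elements `slide` (class `nm_slide`: `image` HxWx3 in
#'   `[0,1]`, `mpp`, `id`) and `truth` (class `nm_truth`: `section_contours`,
#'   `gc_mask`, `sinus_mask`, `section_label` integer raster, `gc_params`
#'   tibble, `planted` tibble of per-section features).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  withr::with_seed(spec$seed, generate_slide_impl(spec))
}

generate_slide_impl <- function(spec) {
  H <- spec$height_px; W <- spec$width_px
  n <- spec$n_sections

  # --- place section centers without overlap (bounded retries) ------------
  centers <- matrix(NA_real_, n, 2)  # (x, y)
  radii <- runif_range(n, spec$section_radius_px)
  maxR <- radii * 1.07  # irregularity headroom
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(300L)) {
      cx <- runif(1, maxR[i] + 3, W - maxR[i] - 3)
      cy <- runif(1, maxR[i] + 3, H - maxR[i] - 3)
      ok <- TRUE
      if (i > 1L) {
        d <- sqrt((centers[seq_len(i - 1L), 1] - cx) ^ 2 +
                  (centers[seq_len(i - 1L), 2] - cy) ^ 2)
        ok <- all(d > maxR[i] + maxR[seq_len(i - 1L)] + 8)
      }
      if (ok) { centers[i, ] <- c(cx, cy); placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(paste0("unable to place %d non-overlapping sections of radius ",
                          "%.0f-%.0f px on a %dx%d canvas after bounded retries"),
                   n, spec$section_radius_px[1], spec$section_radius_px[2], W, H))
  }

  section_label <- matrix(0L, H, W)
  gc_mask <- matrix(FALSE, H, W)
  sinus_mask <- matrix(FALSE, H, W)
  capsule_mask <- matrix(FALSE, H, W)
  contours <- vector("list", n)
  gc_params <- list()
  planted <- list()

  theta_grid <- seq(0, 2 * pi, length.out = 257L)[-257L]

  for (i in seq_len(n)) {
    radf <- blob_radius_fun(radii[i])
    cx <- centers[i, 1]; cy <- centers[i, 2]
    Rmin <- min(radf(seq(0, 2 * pi, length.out = 720)))

    # rasterize the blob analytically in polar form
    ext <- ceiling(maxR[i]) + 2L
    rr <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
    cc <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
    X <- matrix(rep(cc, each = length(rr)), length(rr)) - cx
    Y <- matrix(rep(rr, times = length(cc)), length(rr)) - cy
    r_pix <- sqrt(X ^ 2 + Y ^ 2)
    th_pix <- atan2(Y, X)
    inside <- r_pix <= radf(th_pix)
    sec <- matrix(FALSE, H, W); sec[rr, cc] <- inside
    section_label[sec] <- i
    sec_area_px <- sum(sec)
    contours[[i]] <- cbind(x = cx + radf(theta_grid) * cos(theta_grid),
                           y = cy + radf(theta_grid) * sin(theta_grid))

    # --- capsule line and SCS rim just beneath it -------------------------
    # cap the rim width so the rim alone stays below the sinus target
    cap <- spec$capsule_px
    capsule <- matrix(FALSE, H, W)
    capsule[rr, cc] <- inside & (r_pix >= radf(th_pix) - cap)
    w <- runif_range(1, spec$scs_width_px)
    repeat {
      band <- matrix(FALSE, H, W)
      band[rr, cc] <- inside & (r_pix >= radf(th_pix) - cap - w) &
        (r_pix < radf(th_pix) - cap)
      band_frac <- sum(band) / sec_area_px
      if (band_frac <= 0.8 * spec$sinus_fraction || w <= 2) break
      w <- w - 0.5
    }
    sec_sinus <- band
    capsule_mask <- capsule_mask | capsule

    # --- germinal centres: disjoint ellipses, well inside the rim --------
    k_gc <- sample_int_range(1, spec$gc_count_per_section)
    placed_gc <- list()
    for (g in seq_len(k_gc)) {
      for (try in seq_len(600L)) {
        # bias radii toward the range minimum once the section gets crowded
        rad_hi <- if (try <= 150L) spec$gc_radius_px[2] else
          max(spec$gc_radius_px[1],
              spec$gc_radius_px[2] - (spec$gc_radius_px[2] - spec$gc_radius_px[1]) *
                (try - 150L) / 300L)
        a <- runif_range(1, c(spec$gc_radius_px[1], rad_hi))
        e <- runif_range(1, spec$gc_eccentricity)
        b <- a * sqrt(1 - e ^ 2)
        ang <- runif(1, 0, pi)
        rmaxc <- Rmin - cap - w - a - 6
        if (rmaxc <= 1) next
        rc <- sqrt(runif(1)) * rmaxc
        thc <- runif(1, 0, 2 * pi)
        gx <- cx + rc * cos(thc); gy <- cy + rc * sin(thc)
        ok <- TRUE
        for (p in placed_gc) {
          if (sqrt((p$cx - gx) ^ 2 + (p$cy - gy) ^ 2) < p$a + a + 6) { ok <- FALSE; break }
        }
        if (ok) {
          placed_gc[[length(placed_gc) + 1L]] <-
            list(section_id = section_id(i), cx = gx, cy = gy, a = a, b = b, angle = ang)
          break
        }
      }
    }
    sec_gc <- matrix(FALSE, H, W)
    for (p in placed_gc)
      sec_gc <- stamp_ellipse(sec_gc, c(p$cx, p$cy), p$a, p$b, p$angle)
    # keep-out zone so GC and sinus stay disjoint with a visible gap
    gc_keepout <- EBImage::dilate(sec_gc * 1, EBImage::makeBrush(7L, "disc")) > 0
    sec_sinus <- sec_sinus & !gc_keepout

    # --- intranodal sinus tree until the target fraction is met ----------
    allowed <- sec & !gc_keepout
    frac <- sum(sec_sinus) / sec_area_px
    hw <- max(1.2, w / 2)
    n_branch <- 0L
    while (frac < spec$sinus_fraction && n_branch < 80L) {
      th0 <- runif(1, 0, 2 * pi)
      r0b <- radf(th0) - cap - w - 1
      p0 <- c(cx + r0b * cos(th0), cy + r0b * sin(th0))
      dir <- atan2(cy - p0[2], cx - p0[1]) + runif(1, -0.5, 0.5)
      len <- runif(1, 0.35, 0.8) * radii[i]
      nseg <- 3L
      pt <- p0
      for (s in seq_len(nseg)) {
        dir <- dir + runif(1, -0.45, 0.45)
        p1 <- pt + (len / nseg) * c(cos(dir), sin(dir))
        sec_sinus <- stamp_segment(sec_sinus, pt, p1, hw, region = allowed)
        pt <- p1
      }
      n_branch <- n_branch + 1L
      frac <- sum(sec_sinus) / sec_area_px
    }
    sinus_mask <- sinus_mask | sec_sinus
    gc_mask <- gc_mask | sec_gc
    gc_params <- c(gc_params, placed_gc)

    areas <- vapply(placed_gc, function(p) pi * p$a * p$b, 1)
    circs <- vapply(placed_gc, function(p)
      4 * pi * (pi * p$a * p$b) / ellipse_perimeter(p$a, p$b) ^ 2, 1)
    planted[[i]] <- tibble::tibble(
      section_id = section_id(i),
      gc_count = length(placed_gc),
      mean_gc_area_mm2 = if (length(areas)) px_area_to_mm2(mean(areas), spec$mpp) else NA_real_,
      mean_gc_circularity = if (length(circs)) mean(circs) else NA_real_,
      sinus_fraction = frac,
      scs_width_um = w * spec$mpp,
      section_area_mm2 = px_area_to_mm2(sec_area_px, spec$mpp))
  }

  # --- render ------------------------------------------------------------
  img <- array(0, c(H, W, 3))
  tissue <- section_label > 0L
  lf_period <- runif(1, 220, 420)
  lf_phase <- runif(2, 0, 2 * pi)
  lf <- (spec$noise_sd / 3) *
    outer(sin(2 * pi * seq_len(H) / lf_period + lf_phase[1]),
          cos(2 * pi * seq_len(W) / lf_period + lf_phase[2]))
  for (k in 1:3) {
    ch <- matrix(spec$background_rgb[k], H, W)
    ch[tissue] <- spec$tissue_rgb[k]
    ch[capsule_mask] <- spec$capsule_rgb[k]
    ch[sinus_mask] <- spec$sinus_rgb[k]
    ch[gc_mask] <- spec$gc_rgb[k]
    ch <- ch + lf + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    img[, , k] <- clamp(ch / 255, 0, 1)
  }

  names(contours) <- vapply(seq_len(n), section_id, "")
  slide <- new_slide(img, mpp = spec$mpp,
                     id = sprintf("synthetic-slide-%d", spec$seed))
  truth <- structure(list(
    section_contours = contours,
    gc_mask = gc_mask,
    sinus_mask = sinus_mask,
    section_label = section_label,
    gc_params = dplyr::bind_rows(gc_params),
    planted = dplyr::bind_rows(planted),
    mpp = spec$mpp,
    spec = spec), class = "nm_truth")
  list(slide = slide, truth = truth)
}

section_id <- function(i) sprintf("S%02d", i)

#' Construct a slide object
#'
#' @param image HxWx3 numeric array in `[0,1]` (or a grayscale matrix).
#' @param mpp microns per pixel at this level.
#' @param id slide identifier.
#' @param level downsample factor relative to the finest level.
#' @return object of class `nm_slide`.
#' @export
new_slide <- function(image, mpp, id = "slide", level = 1L) {
  assert_scalar_num(mpp, "mpp", lo = 1e-9)
  structure(list(image = image, mpp = mpp, id = id, level = as.integer(level)),
            class = "nm_slide")
}

#' @export
print.nm_slide <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<nm_slide %s: %d x %d px, %.3g um/px, level %d>\n",
              x$id, d[1], d[2], x$mpp, x$level))
  invisible(x)
}

#' Render a slide at a coarser magnification
#'
#' Block-average downsampling by an integral pyramid factor, mirroring the
#' magnification levels used for tile extraction (for instance x10 / x5 /
#' x2.5 relative to the scan). Output dimensions are `ceiling(dim / factor)`
#' and `mpp` scales by the factor.
#'
#' @param slide an `nm_slide`.
#' @param factor one of 1, 2, 4, 8, 16.
#' @return an `nm_slide` at the coarser level.
#' @export
render_magnification <- function(slide, factor) {
  stopifnot(inherits(slide, "nm_slide"))
  if (!factor %in% c(1L, 2L, 4L, 8L, 16L))
    stop("factor must be one of 1, 2, 4, 8, 16")
  factor <- as.integer(factor)
  if (factor == 1L) return(slide)
  new_slide(block_downsample(slide$image, factor), mpp = slide$mpp * factor,
            id = slide$id, level = slide$level * factor)
}

#' Downsample a binary mask by majority vote within blocks
#' @param mask logical/binary matrix.
#' @param factor integral downsample factor.
#' @return logical matrix of dimension `ceiling(dim / factor)`.
#' @export
downsample_mask <- function(mask, factor) {
  if (factor == 1L) return(mask > 0)
  block_downsample(mask * 1, factor) >= 0.5
}

#' Slide specification used by the segmentation benchmark
#'
#' One-section slides sized for fast tile training. Noise is set above the
#' generator default (sd 30 on the 0-255 scale) so that per-pixel colour
#' alone is an imperfect classifier and spatial context carries signal; the
#' `multiscale_gc` variant draws GC radii across a wide range (8-60 px) so
#' that structures span several receptive-field scales.
#'
#' @param variant `"standard"` or `"multiscale_gc"`.
#' @param seed integer seed.
#' @return a [slide_spec()].
#' @export
benchmark_slide_spec <- function(variant = c("standard", "multiscale_gc"), seed = 1L) {
  variant <- match.arg(variant)
  gc_r <- if (variant == "multiscale_gc") c(8, 55) else c(16, 34)
  gc_n <- if (variant == "multiscale_gc") c(1L, 4L) else c(2L, 6L)
  slide_spec(width_px = 280L, height_px = 280L, n_sections = 1L,
             section_radius_px = c(95, 120),
             gc_count_per_section = gc_n,
             gc_radius_px = gc_r,
             gc_eccentricity = c(0, 0.5),
             sinus_fraction = 0.12,
             scs_width_px = c(4, 7),
             noise_sd = 30,
             seed = seed)
}
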