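#' Read a slide raster from PNG or TIFF
#'
#' @param path image file (`.png`, `.tif`, `.tiff`). For multi-page TIFFs
#'   the first (finest) page is used.
#' @param mpp microns per pixel of the raster (scanner metadata is not
#'   parsed; supply the value from the acquisition record).
#' @param id slide identifier; defaults to the file name.
#' @return an `nm_slide`.
#' @export
read_slide <- function(path, mpp, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the `tiff` package is required to read TIFF slides")
      x <- tiff::readTIFF(path, all = TRUE)
      if (is.list(x)) x[[1]] else x
    },
    stop(sprintf("unsupported slide format `.%s` (PNG/TIFF supported)", ext)))
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  new_slide(img, mpp = mpp, id = id %||% basename(path))
}

#' Write a slide raster to PNG or TIFF
#' @param slide an `nm_slide`.
#' @param path output path; format by extension.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(slide$image, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the `tiff` package is required to write TIFF slides")
      tiff::writeTIFF(slide$image, path)
    },
    stop(sprintf("unsupported slide format `.%s`", ext)))
  invisible(path)
}

#' Write a binary mask as single-channel PNG (0/255)
#' @param mask logical/binary matrix.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask_png()]
#' @param path `.png` path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m >= 0.5
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' The dialect matches digital-pathology annotation exports: one `Feature`
#' per polygon with a `Polygon` geometry (single exterior ring, closed) and
#' free-form `properties`.
#'
#' @param polys named list of two-column `(x, y)` matrices.
#' @param path output path.
#' @param properties optional data frame / tibble with one row per polygon
#'   (e.g. `section_id`, `area_mm2`, `involvement`, `classification`).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])
    props <- if (is.null(properties)) {
      list(name = names(polys)[i] %||% sprintf("poly-%d", i))
    } else {
      as.list(properties[i, , drop = FALSE])
    }
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(lapply(seq_len(nrow(ring)),
                                                          function(j) unname(ring[j, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file with `Polygon` features.
#' @return tibble with columns `polygon` (list of `(x, y)` matrices) and one
#'   column per property found in the file.
#' @export
read_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  if (!identical(js$type, "FeatureCollection")) stop("not a FeatureCollection")
  rows <- lapply(js$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon geometries are supported")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    colnames(m) <- c("x", "y")
    n <- nrow(m)
    if (n > 1L && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
    props <- lapply(f$properties, function(p) if (is.null(p)) NA else p)
    tibble::tibble(polygon = list(m), !!!props)
  })
  dplyr::bind_rows(rows)
}

#' Write detected sections as GeoJSON
#' @param sections tibble from [detect_ln_sections()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sections_geojson <- function(sections, path) {
  write_geojson(stats::setNames(sections$contour, sections$section_id), path,
                properties = data.frame(section_id = sections$section_id,
                                        area_mm2 = sections$area_mm2,
                                        involvement = sections$involvement,
                                        stringsAsFactors = FALSE))
}
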