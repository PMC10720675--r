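#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]; any element can be overridden
#' via `...` (lists are merged recursively). The global `seed` propagates
#' to every stochastic stage (synthesis, model initialization, shuffling).
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @param ... overrides, e.g. `training = list(epochs = 2)`.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("nodemorph-run-"), seed = 1L, ...) {
  base <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    slide = list(n_sections = 3L, width_px = 900L, height_px = 900L),
    cohort = list(n_patients = 300L),
    detection = list(min_area_mm2 = 0.1),
    training = list(variant = "ms_unet", base_channels = 6L, depth = 3L,
                    epochs = 3L, tile_px = 64L, overlap_px = 32L,
                    n_sections = 8L, split = c(5L, 2L, 1L)),
    inference = list(threshold = 0.5),
    quantification = list(min_area_um2 = 2000),
    survival = list(preset = "tnbc", feature = "mean_gc_count"))
  ov <- list(...)
  merge_rec <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_rec(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  structure(merge_rec(base, ov), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

pipeline_stages <- c("synth", "detect", "train", "infer", "quantify", "survive")

stage_requires <- list(
  synth = character(),
  detect = c("slide.png", "slide_meta.json"),
  train = character(),
  infer = c("slide.png", "slide_meta.json", "sections.geojson",
            "checkpoint_gc.json", "checkpoint_sinus.json"),
  quantify = c("sections.geojson", "mask_gc.png", "mask_sinus.png",
               "slide_meta.json"),
  survive = c("cohort.csv"))

#' Run the lymph-node analysis pipeline
#'
#' Executes the requested stages in order — synthesis, section detection,
#' model training, whole-section inference, feature quantification, outcome
#' analysis — exchanging artifacts through `out_dir`, and writes a run
#' manifest (seed, config hash, package version, per-stage artifact
#' checksums). Re-running with an identical config reproduces identical
#' checksums for the deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("synth", "detect", "train", "infer", "quantify", "survive")`.
#' @return the manifest as a tibble (also written to `manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (st in stages) {
    missing <- stage_requires[[st]][!file.exists(file.path(out, stage_requires[[st]]))]
    if (length(missing)) {
      prior <- switch(st, detect = "synth", infer = "train (and synth/detect)",
                      quantify = "infer", survive = "synth", "an earlier stage")
      stop(sprintf("stage `%s` is missing artifact(s) %s; run %s first",
                   st, paste(missing, collapse = ", "), prior))
    }
    t0 <- Sys.time()
    arts <- switch(st,
      synth = stage_synth(config, out),
      detect = stage_detect(config, out),
      train = stage_train(config, out),
      infer = stage_infer(config, out),
      quantify = stage_quantify(config, out),
      survive = stage_survive(config, out))
    manifest[[st]] <- tibble::tibble(
      stage = st, status = "complete",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
      artifact = arts,
      checksum = vapply(file.path(out, arts), file_checksum, "",
                        USE.NAMES = FALSE))
  }
  man <- dplyr::bind_rows(manifest)
  cfg_file <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  meta <- list(seed = config$seed,
               config_checksum = file_checksum(cfg_file),
               package_version = as.character(utils::packageVersion("nodemorph")),
               stages = unique(man$stage))
  jsonlite::write_json(list(meta = meta, artifacts = man),
                       file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(man)
}

stage_synth <- function(config, out) {
  sspec <- do.call(slide_spec, c(config$slide, list(seed = config$seed)))
  gen <- generate_slide(sspec)
  write_slide(gen$slide, file.path(out, "slide.png"))
  jsonlite::write_json(list(mpp = gen$slide$mpp, id = gen$slide$id),
                       file.path(out, "slide_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_mask_png(gen$truth$gc_mask, file.path(out, "truth_gc_mask.png"))
  write_mask_png(gen$truth$sinus_mask, file.path(out, "truth_sinus_mask.png"))
  write_geojson(gen$truth$section_contours, file.path(out, "truth_sections.geojson"))
  utils::write.csv(gen$truth$planted, file.path(out, "planted_features.csv"),
                   row.names = FALSE)
  cohort <- generate_cohort(do.call(cohort_spec,
                                    c(config$cohort, list(seed = config$seed))))
  utils::write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)
  c("slide.png", "slide_meta.json", "truth_gc_mask.png", "truth_sinus_mask.png",
    "truth_sections.geojson", "planted_features.csv", "cohort.csv")
}

read_stage_slide <- function(out) {
  meta <- jsonlite::read_json(file.path(out, "slide_meta.json"))
  read_slide(file.path(out, "slide.png"), mpp = meta$mpp, id = meta$id)
}

stage_detect <- function(config, out) {
  slide <- read_stage_slide(out)
  sections <- detect_ln_sections(slide, min_area_mm2 = config$detection$min_area_mm2)
  write_sections_geojson(sections, file.path(out, "sections.geojson"))
  "sections.geojson"
}

stage_train <- function(config, out) {
  tc <- config$training
  cfg <- train_config(tile_px = tc$tile_px, overlap_px = tc$overlap_px,
                      epochs = tc$epochs, split = tc$split,
                      seed = config$seed)
  log <- list()
  for (struct in c("gc", "sinus")) {
    secs <- make_benchmark_sections(tc$n_sections, struct,
                                    seed_base = config$seed * 1000L)
    tiles <- tile_dataset(secs, cfg)
    spec <- seg_model_spec(variant = tc$variant, structure = struct,
                           base_channels = tc$base_channels, depth = tc$depth,
                           seed = config$seed)
    mod <- train(build_model(spec), tiles, cfg)
    save_checkpoint(mod, file.path(out, sprintf("checkpoint_%s.json", struct)))
    log[[struct]] <- dplyr::mutate(mod$history, structure = struct)
  }
  utils::write.csv(dplyr::bind_rows(log), file.path(out, "training_log.csv"),
                   row.names = FALSE)
  c("checkpoint_gc.json", "checkpoint_sinus.json", "training_log.csv")
}

read_sections_geojson <- function(path) {
  tbl <- read_geojson(path)
  tibble::tibble(
    section_id = tbl$section_id,
    contour = tbl$polygon,
    bbox = lapply(tbl$polygon, function(p)
      as.integer(c(floor(min(p[, 2])), floor(min(p[, 1])),
                   ceiling(max(p[, 2])), ceiling(max(p[, 1]))))),
    area_mm2 = tbl$area_mm2,
    involvement = tbl$involvement %||% "unknown")
}

stage_infer <- function(config, out) {
  slide <- read_stage_slide(out)
  sections <- read_sections_geojson(file.path(out, "sections.geojson"))
  sections$bbox <- lapply(sections$bbox, function(b)
    as.integer(c(max(1L, b[1]), max(1L, b[2]),
                 min(dim(slide$image)[1], b[3]), min(dim(slide$image)[2], b[4]))))
  tc <- config$training
  cfg <- train_config(tile_px = tc$tile_px, overlap_px = tc$overlap_px,
                      split = tc$split, seed = config$seed)
  arts <- character()
  for (struct in c("gc", "sinus")) {
    model <- load_checkpoint(file.path(out, sprintf("checkpoint_%s.json", struct)))
    full <- matrix(FALSE, dim(slide$image)[1], dim(slide$image)[2])
    for (i in seq_len(nrow(sections))) {
      m <- segment_section(model, slide, sections[i, ], cfg,
                           threshold = config$inference$threshold)
      bb <- m$bbox
      full[bb[1]:bb[3], bb[2]:bb[4]] <- full[bb[1]:bb[3], bb[2]:bb[4]] | m$binary
    }
    f <- sprintf("mask_%s.png", struct)
    write_mask_png(full, file.path(out, f))
    arts <- c(arts, f)
  }
  arts
}

stage_quantify <- function(config, out) {
  meta <- jsonlite::read_json(file.path(out, "slide_meta.json"))
  sections <- read_sections_geojson(file.path(out, "sections.geojson"))
  gc_mask <- read_mask_png(file.path(out, "mask_gc.png"))
  sinus_mask <- read_mask_png(file.path(out, "mask_sinus.png"))
  feats <- quantify_sections(sections, gc_mask, sinus_mask, mpp = meta$mpp,
                             min_area_um2 = config$quantification$min_area_um2)
  utils::write.csv(feats, file.path(out, "features.csv"), row.names = FALSE)
  "features.csv"
}

stage_survive <- function(config, out) {
  cohort <- tibble::as_tibble(utils::read.csv(file.path(out, "cohort.csv")))
  pat <- aggregate_patient(cohort, mode = "mean", subset = "all")
  feature <- config$survival$feature
  preset <- cutoff_preset(config$survival$preset)
  cut <- preset[preset$feature == feature, ]
  if (nrow(cut) == 0) stop(sprintf("feature `%s` has no preset cut-off", feature))
  pat$group <- suppressWarnings(dichotomize(pat[[feature]], cut$cutoff, cut$orientation))
  keep <- !is.na(pat$group)
  km <- km_logrank(pat$time[keep], pat$event[keep], pat$group[keep])
  cox <- cox_ph(pat[keep, ], ~ group)
  res <- list(feature = feature, cutoff = cut$cutoff,
              orientation = cut$orientation,
              group_sizes = as.list(table(pat$group[keep])),
              logrank_p = km$p,
              hr = cox$tidy$hr[1], ci95 = c(cox$tidy$conf_low[1], cox$tidy$conf_high[1]),
              p_likelihood = cox$p_likelihood)
  jsonlite::write_json(res, file.path(out, "survival.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(km$curves, file.path(out, "km_curves.csv"), row.names = FALSE)
  c("survival.json", "km_curves.csv")
}
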