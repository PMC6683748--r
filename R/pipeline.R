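#' Default pipeline configuration
#'
#' A nested list of every tunable of the pipeline stages, suitable for
#' YAML serialization. [load_config()] merges a user YAML file over these
#' defaults; command-line flags override both. Every run writes the fully
#' resolved configuration into its manifest.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    channels = c("blue", "green", "orange", "farred"),
    patterns = NULL,                 # NULL = all 2^n - 1
    n_per_pattern = 8,
    seed = 1,
    noise = list(brightness_mean = 100, brightness_sdlog = 0.3,
                 channel_cv = 0.10, background = 20, pixel_sd = 0.10),
    geometry = list(lm_size = 800, lm_pixel_size_um = 0.1,
                    cell_diameter_um = 4, cell_diameter_cv = 0.08,
                    ring_px = 2, min_gap_px = 4, em_scale = 8,
                    em_rotation_deg = 7, n_holes = 5, n_debris = 5,
                    max_place_tries = 2000),
    segmentation = list(smoothing_radius_px = 3, min_area_um2 = 3,
                        max_area_um2 = 80, min_circularity = 0.6,
                        marker_separation_um = 1.5),
    dilation_um = 0.2,
    clustering = list(restarts = 50, low_conf_quantile = 0.95,
                      min_prob = 0),
    morphometry = list(include_constant = TRUE),
    nav = list(y_flip = TRUE, map_label = "overview",
               stage_um_per_px = 0.0125)
  )
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], extra[[nm]])
    } else {
      base[[nm]] <- extra[[nm]]
    }
  }
  base
}

#' @rdname default_config
#' @param path YAML file with (a subset of) the configuration keys, or
#'   `NULL` for pure defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

cfg_noise <- function(cfg) do.call(noise_config, cfg$noise)
cfg_geometry <- function(cfg) do.call(sample_geometry, cfg$geometry)
cfg_segparams <- function(cfg) {
  g <- cfg$geometry
  do.call(segmentation_params,
          c(cfg$segmentation,
            list(pixel_size_nm = g$lm_pixel_size_um * 1000 / g$em_scale)))
}

need_file <- function(path, what) {
  if (!file.exists(path)) {
    stop("missing ", what, ": ", path, call. = FALSE)
  }
  path
}

#' Run one pipeline stage against a working directory
#'
#' The working directory convention is: `sim/` holds the synthetic
#' microscope output (`lm.tif`, `em.tif`, `class_map.tif`, `truth.csv`,
#' `control_points.csv`), and stage outputs are written next to it
#' (`cells.csv`, `transform.txt`, `intensities.csv`, `calls.csv`, `qc/`,
#' `points.nav`). Stages communicate only through these files, so each
#' can be re-run in isolation.
#'
#' @param stage One of `"simulate"`, `"detect"`, `"correlate"`,
#'   `"classify"`, `"qc-report"`, `"nav-export"`.
#' @param dir Working directory.
#' @param cfg Configuration list ([default_config()] / [load_config()]).
#' @param overrides Optional override CSV path for `qc-report`.
#' @return Invisibly, the stage's main result object.
#' @export
run_stage <- function(stage, dir, cfg = default_config(),
                      overrides = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- file.path(dir, "sim")
  panel_path <- file.path(sim, "channels.txt")
  result <- switch(
    stage,
    "simulate" = {
      sample <- render_sample(channel_panel(cfg$channels),
                              patterns = cfg$patterns,
                              n_per_pattern = cfg$n_per_pattern,
                              noise = cfg_noise(cfg),
                              geometry = cfg_geometry(cfg),
                              seed = cfg$seed)
      write_sample(sample, sim)
      sample
    },
    "detect" = {
      cm <- read_class_map(need_file(file.path(sim, "class_map.tif"),
                                     "class map"))
      cells <- detect_cells(cm, cfg_segparams(cfg))
      write_cells(cells, file.path(dir, "cells"))
      cells
    },
    "correlate" = {
      cp <- read_control_points(need_file(
        file.path(sim, "control_points.csv"), "control points"))
      fit <- fit_affine(cp[c("em_x", "em_y")], cp[c("lm_x", "lm_y")],
                        direction = "em_to_lm")
      write_affine(fit$transform, file.path(dir, "transform.txt"))
      need_file(file.path(dir, "cells.csv"), "cell table")
      cells <- read_cells(file.path(dir, "cells"))
      cm <- read_class_map(file.path(sim, "class_map.tif"))
      holes <- holes_mask(cm, cfg_segparams(cfg))
      lm <- read_lm_stack(need_file(file.path(sim, "lm.tif"), "LM stack"))
      masks <- build_masks(cells, holes, fit$transform, dim(lm)[1:2],
                           dilation_um = cfg$dilation_um,
                           lm_pixel_size_um = cfg$geometry$lm_pixel_size_um)
      channels <- readLines(panel_path)
      tab <- measure_intensities(lm, masks, channels)
      write_intensities(tab, file.path(dir, "intensities.csv"))
      list(transform = fit$transform, masks = masks, intensities = tab)
    },
    "classify" = {
      tab <- read_intensities(need_file(file.path(dir, "intensities.csv"),
                                        "intensity table"))
      panel <- channel_panel(readLines(need_file(panel_path,
                                                 "channel list")))
      calls <- classify_cells(tab, panel, patterns = cfg$patterns,
                              seed = cfg$seed,
                              restarts = cfg$clustering$restarts,
                              low_conf_quantile =
                                cfg$clustering$low_conf_quantile,
                              min_prob = cfg$clustering$min_prob)
      utils::write.csv(calls, file.path(dir, "calls.csv"),
                       row.names = FALSE, quote = FALSE)
      calls
    },
    "qc-report" = {
      calls <- read_calls(need_file(file.path(dir, "calls.csv"),
                                    "barcode calls"))
      need_file(file.path(dir, "cells.csv"), "cell table")
      cells <- read_cells(file.path(dir, "cells"))
      lm <- read_lm_stack(need_file(file.path(sim, "lm.tif"), "LM stack"))
      em <- tiff::readTIFF(need_file(file.path(sim, "em.tif"),
                                     "EM overview"))
      cp <- read_control_points(file.path(sim, "control_points.csv"))
      fit <- fit_affine(cp[c("em_x", "em_y")], cp[c("lm_x", "lm_y")],
                        direction = "em_to_lm")
      cm <- read_class_map(file.path(sim, "class_map.tif"))
      masks <- build_masks(cells, holes_mask(cm, cfg_segparams(cfg)),
                           fit$transform, dim(lm)[1:2],
                           dilation_um = cfg$dilation_um,
                           lm_pixel_size_um = cfg$geometry$lm_pixel_size_um)
      qc_report(calls, cells, lm, masks, em, file.path(dir, "qc"),
                overrides = overrides)
    },
    "nav-export" = {
      calls_path <- file.path(dir, "qc", "calls.csv")
      if (!file.exists(calls_path)) calls_path <- file.path(dir, "calls.csv")
      calls <- read_calls(need_file(calls_path, "barcode calls"))
      need_file(file.path(dir, "cells.csv"), "cell table")
      cells <- read_cells(file.path(dir, "cells"))
      em <- tiff::readTIFF(need_file(file.path(sim, "em.tif"),
                                     "EM overview"))
      doc <- nav_skeleton(cfg$nav$map_label, width = ncol(em),
                          height = nrow(em),
                          scale = cfg$nav$stage_um_per_px)
      doc <- add_acquisition_points(doc, cfg$nav$map_label, cells, calls,
                                    y_flip = cfg$nav$y_flip)
      write_navigator(doc, file.path(dir, "points.nav"))
      doc
    },
    stop("unknown stage '", stage, "'", call. = FALSE)
  )
  invisible(result)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Chains simulate, detect, correlate, classify, qc-report and nav-export
#' in a working directory, then writes `manifest.json` with the resolved
#' configuration, the seed and an MD5 checksum of every artifact. With a
#' fixed seed the whole artifact set is bit-reproducible.
#'
#' @param dir Working directory (created).
#' @param cfg Configuration ([default_config()]); `seed` overrides the
#'   config's seed if given.
#' @param seed Optional integer overriding `cfg$seed`.
#' @return Invisibly, a list with the calls table and the manifest.
#' @export
run_pipeline <- function(dir, cfg = default_config(), seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  for (stage in c("simulate", "detect", "correlate", "classify",
                  "qc-report", "nav-export")) {
    run_stage(stage, dir, cfg)
  }
  files <- sort(setdiff(
    list.files(dir, recursive = TRUE),
    "manifest.json"))
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(config = cfg, seed = cfg$seed,
                   artifacts = as.list(stats::setNames(unname(sums),
                                                       files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  calls <- read_calls(file.path(dir, "calls.csv"))
  invisible(list(calls = calls, manifest = manifest))
}
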