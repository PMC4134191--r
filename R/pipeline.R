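#' Configuration for an end-to-end multi-channel (FMT-style) analysis
#'
#' Describes a batch of co-registered hypoxia + glucose tumor scenes to be
#' analyzed by [run_fmt_analysis()]: hotspot detection on the hypoxia
#' channel inside the whole-tumor ROI, ROI transfer to the glucose channel,
#' per-hotspot fold enrichment, per-tumor glucose CV, and (when both groups
#' have >= 2 tumors) a hotspot-positive vs hotspot-negative CV comparison.
#'
#' @param specs List of [phantom_spec()] objects, one per tumor; or `NULL`
#'   if `channel_sets` is given.
#' @param channel_sets Optional list of pre-built [channel_set()]s with a
#'   parallel list `tumor_masks` of whole-tumor `roi_mask`s (for real data).
#' @param tumor_masks See `channel_sets`.
#' @param hotspot [hotspot_params()] used on the hypoxia channel.
#' @param hypoxia_channel,glucose_channel Channel names.
#' @param seed Integer master seed; phantom `i` runs at `seed + i`.
#' @return A `fmt_config` object.
#' @export
fmt_config <- function(specs = NULL, channel_sets = NULL, tumor_masks = NULL,
                       hotspot = hotspot_params(),
                       hypoxia_channel = "hypoxia",
                       glucose_channel = "glucose", seed = 1L) {
  if (is.null(specs) == is.null(channel_sets)) {
    abort("Provide exactly one of `specs` or `channel_sets`.")
  }
  if (!is.null(channel_sets) && is.null(tumor_masks)) {
    abort("`channel_sets` requires matching `tumor_masks`.")
  }
  structure(list(specs = specs, channel_sets = channel_sets,
                 tumor_masks = tumor_masks, hotspot = hotspot,
                 hypoxia_channel = hypoxia_channel,
                 glucose_channel = glucose_channel, seed = as.integer(seed)),
            class = "fmt_config")
}

#' Run the multi-channel hotspot/enrichment/CV analysis
#'
#' For each tumor: detect hypoxia hotspots inside the whole-tumor ROI,
#' transfer every ROI to the glucose channel, compute whole-tumor and
#' per-hotspot statistics, per-hotspot fold enrichment over the whole tumor,
#' and the whole-tumor glucose CV. Tumors are then grouped by whether any
#' hotspot was detected and, when both groups have at least two members,
#' the group CVs are compared with a pooled t-test.
#'
#' @param config An [fmt_config()].
#' @return A `run_report` list: `tumor_stats`, `hotspot_stats`,
#'   `enrichment`, `cv_table`, `comparison` (tibble or `NULL`), `warnings`,
#'   `provenance`.
#' @export
run_fmt_analysis <- function(config) {
  stopifnot(inherits(config, "fmt_config"))
  n_tumors <- length(config$specs %||% config$channel_sets)
  tumor_stats <- list(); hotspot_stats <- list(); enrich <- list()
  cv_rows <- list(); warnings <- character(0)

  for (i in seq_len(n_tumors)) {
    if (!is.null(config$specs)) {
      spec <- config$specs[[i]]
      spec$seed <- config$seed + i
      ph <- generate_phantom(spec)
      channels <- ph$channels
      tumor_mask <- ph$truth$tumor_mask
    } else {
      channels <- config$channel_sets[[i]]
      tumor_mask <- config$tumor_masks[[i]]
    }
    validate_coregistered(channels)
    glu <- channels[[config$glucose_channel]]
    if (is.null(glu)) abort(sprintf("Tumor %d has no '%s' channel.", i,
                                    config$glucose_channel))
    tumor_mask$role <- "whole_tumor"
    glu_mask <- transfer_roi(tumor_mask, glu, config$glucose_channel)
    ts <- region_stats(glu, glu_mask)
    tumor_stats[[i]] <- dplyr::mutate(ts, tumor = i, .before = 1)

    hyp <- channels[[config$hypoxia_channel]]
    hotspots <- if (!is.null(hyp)) {
      detect_hotspots(hyp, tumor_mask, config$hotspot)
    } else list()
    for (k in seq_along(hotspots)) {
      hs_glu <- transfer_roi(hotspots[[k]], glu, config$glucose_channel)
      hs <- region_stats(glu, hs_glu)
      hotspot_stats[[length(hotspot_stats) + 1L]] <-
        dplyr::mutate(hs, tumor = i, hotspot = k, .before = 1)
      fe <- fold_enrichment(glu, hs_glu, glu_mask)
      enrich[[length(enrich) + 1L]] <-
        dplyr::mutate(fe, tumor = i, hotspot = k, .before = 1)
    }
    cv_rows[[i]] <- tibble(tumor = i, cv = ts$cv,
                           hotspot_positive = length(hotspots) > 0,
                           n_hotspots = length(hotspots))
  }

  cv_table <- dplyr::bind_rows(cv_rows)
  comparison <- NULL
  if (sum(cv_table$hotspot_positive) >= 2 &&
      sum(!cv_table$hotspot_positive) >= 2) {
    comparison <- tidy(compare_cv_groups(
      cv_table$cv[cv_table$hotspot_positive],
      cv_table$cv[!cv_table$hotspot_positive]))
  } else if (n_tumors > 1) {
    warnings <- c(warnings,
                  "Too few tumors in a group for a CV comparison; skipped.")
  }
  new_run_report(
    kind = "fmt",
    tables = list(tumor_stats = dplyr::bind_rows(tumor_stats),
                  hotspot_stats = dplyr::bind_rows(hotspot_stats),
                  enrichment = dplyr::bind_rows(enrich),
                  cv_table = cv_table, comparison = comparison),
    warnings = warnings, config = config
  )
}

#' Configuration for a single-channel (PET-style) ROI-contraction analysis
#'
#' Describes a batch of tumor volumes analyzed by [run_pet_analysis()]:
#' edge delineation (or a supplied/ground-truth ROI-E), circumferential
#' contraction by the scanner resolution, descriptive statistics of both
#' ROIs, and intensity histograms.
#'
#' @param specs List of [phantom_spec()]s; or `NULL` with `volumes` given.
#' @param volumes Optional list of `image_volume`s (real data) with either
#'   `roi_e_masks` or `segmentation` supplied.
#' @param roi_e_masks Optional list of precomputed ROI-E `roi_mask`s.
#' @param segmentation Optional [segmentation_params()]; when given, ROI-E
#'   is delineated with [segment_gradient_edge()] instead of taken from
#'   ground truth.
#' @param contraction_mm Contraction distance ROI-E -> ROI-C, in mm
#'   (default 5, a PET-resolution-matched choice).
#' @param bin_width Histogram bin width in intensity units.
#' @param seed Integer master seed for phantom generation.
#' @return A `pet_config` object.
#' @export
pet_config <- function(specs = NULL, volumes = NULL, roi_e_masks = NULL,
                       segmentation = NULL, contraction_mm = 5,
                       bin_width = 0.05, seed = 1L) {
  if (is.null(specs) == is.null(volumes)) {
    abort("Provide exactly one of `specs` or `volumes`.")
  }
  if (!is.null(volumes) && is.null(roi_e_masks) && is.null(segmentation)) {
    abort("`volumes` requires `roi_e_masks` or `segmentation`.")
  }
  if (contraction_mm < 0) abort("`contraction_mm` must be >= 0.")
  structure(list(specs = specs, volumes = volumes,
                 roi_e_masks = roi_e_masks, segmentation = segmentation,
                 contraction_mm = contraction_mm, bin_width = bin_width,
                 seed = as.integer(seed)),
            class = "pet_config")
}

#' Run the ROI-contraction heterogeneity analysis
#'
#' For each tumor volume: obtain ROI-E (ground truth, supplied, or
#' gradient-delineated), contract it by `contraction_mm` into ROI-C,
#' compute descriptive statistics for both ROIs (reported in the
#' conventional column order `volume_mL, max, min, mean, median, sd, cv`),
#' histogram both ROIs, and tabulate tumor volume against ROI-C CV. An
#' empty ROI-C is recorded as a warning and its statistics omitted.
#'
#' @param config A [pet_config()].
#' @return A `run_report` list: `stats` (one row per tumor x ROI),
#'   `histograms`, `volume_cv`, `warnings`, `provenance`.
#' @export
run_pet_analysis <- function(config) {
  stopifnot(inherits(config, "pet_config"))
  n_tumors <- length(config$specs %||% config$volumes)
  stats_rows <- list(); hist_rows <- list(); vol_cv <- list()
  warnings <- character(0)

  for (i in seq_len(n_tumors)) {
    if (!is.null(config$specs)) {
      spec <- config$specs[[i]]
      spec$seed <- config$seed + i
      ph <- generate_phantom(spec)
      vol <- ph$channels$glucose
      roi_e <- if (is.null(config$segmentation)) {
        m <- ph$truth$tumor_mask; m$role <- "ROI_E"; m
      } else {
        p <- config$segmentation
        p$seed_point_mm <- spec$tumor_center_mm
        segment_gradient_edge(vol, p)
      }
    } else {
      vol <- config$volumes[[i]]
      roi_e <- if (!is.null(config$roi_e_masks)) {
        config$roi_e_masks[[i]]
      } else {
        segment_gradient_edge(vol, config$segmentation)
      }
    }
    roi_c <- withCallingHandlers(
      contract_roi(roi_e, config$contraction_mm),
      warning = function(w) {
        warnings <<- c(warnings, sprintf("tumor %d: %s", i,
                                         conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    for (m in list(roi_e, roi_c)) {
      if (!any(m$values)) next
      st <- region_stats(vol, m)
      stats_rows[[length(stats_rows) + 1L]] <-
        dplyr::mutate(st, tumor = i, .before = 1)
      h <- roi_histogram(vol, m, config$bin_width)
      hist_rows[[length(hist_rows) + 1L]] <-
        tibble(tumor = i, roi = m$role, bin_left = h$bin_left,
               bin_right = h$bin_right, count = h$count)
      if (m$role == "ROI_C") {
        vol_cv[[length(vol_cv) + 1L]] <-
          tibble(tumor = i, volume_mL = st$volume_mL, cv = st$cv)
      }
    }
  }
  stats <- dplyr::bind_rows(stats_rows) |>
    dplyr::select("tumor", "roi", "volume_mL", "max", "min", "mean",
                  "median", "sd", "cv", "n_voxels", "units")
  new_run_report(
    kind = "pet",
    tables = list(stats = stats, histograms = dplyr::bind_rows(hist_rows),
                  volume_cv = dplyr::bind_rows(vol_cv)),
    warnings = warnings, config = config
  )
}

new_run_report <- function(kind, tables, warnings, config) {
  structure(
    c(tables,
      list(warnings = warnings,
           provenance = list(kind = kind, seed = config$seed,
                             config_hash = rlang::hash(config),
                             package_version =
                               as.character(utils::packageVersion("tumorhet"))))),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report:%s> seed %d, %d warning(s)\n",
              x$provenance$kind, x$provenance$seed, length(x$warnings)))
  for (nm in setdiff(names(x), c("warnings", "provenance"))) {
    if (is.data.frame(x[[nm]])) {
      cat(sprintf("  $%s: %d row(s)\n", nm, nrow(x[[nm]])))
    }
  }
  invisible(x)
}

#' Write a run report to a directory
#'
#' Every table goes to `<name>.csv`; warnings and provenance go to
#' `provenance.json`. Bodies contain no timestamps, so identical
#' config + seed produces byte-identical files.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in setdiff(names(report), c("warnings", "provenance"))) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    if (is.data.frame(tab) && nrow(tab) == 0 && ncol(tab) == 0) next
    write.csv(tab, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(list(warnings = report$warnings,
                            provenance = report$provenance),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Build a phantom spec from a YAML/JSON config file
#'
#' Reads a config whose keys mirror [phantom_spec()] fields (`grid_shape`,
#' `spacing_mm`, `background_level`, `tumor_center_mm`, `tumor_radii_mm`,
#' `tumor_level`, `hotspots` (list of `center_mm`/`radius_mm`/`multiplier`),
#' `psf_fwhm_mm`, `noise` (`type` plus `sigma` or `fraction`), `units`,
#' `seed`).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_file <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  noise <- noise_none()
  if (!is.null(cfg$noise)) {
    noise <- switch(cfg$noise$type %||% "none",
      none = noise_none(),
      gaussian_constant = noise_gaussian(cfg$noise$sigma),
      gaussian_proportional = noise_proportional(cfg$noise$fraction),
      abort(sprintf("Unknown noise type '%s'.", cfg$noise$type)))
  }
  hotspots <- lapply(cfg$hotspots %||% list(), function(h) {
    list(center_mm = as.numeric(unlist(h$center_mm)),
         radius_mm = h$radius_mm, multiplier = h$multiplier)
  })
  phantom_spec(
    grid_shape = as.integer(unlist(cfg$grid_shape)),
    spacing_mm = as.numeric(unlist(cfg$spacing_mm)),
    background_level = cfg$background_level %||% 0,
    tumor_center_mm = as.numeric(unlist(cfg$tumor_center_mm)),
    tumor_radii_mm = as.numeric(unlist(cfg$tumor_radii_mm)),
    tumor_level = cfg$tumor_level %||% 1,
    hotspots = hotspots,
    psf_fwhm_mm = cfg$psf_fwhm_mm %||% 0,
    noise_model = noise,
    units = cfg$units %||% "arbitrary",
    seed = cfg$seed %||% 1L
  )
}
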