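#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline, with defaults equal to
#' the method's published calibration (pixel-unit constants assume the
#' 0.15625 um/px scale: 25 px = 3.91 um, 8 px = 1.25 um).
#'
#' @param pixel_size_um physical pixel size (um/px).
#' @param bleed_ratio DAPI/(Nppa or Hcn4) ratio above which a DAPI pixel is
#'   zeroed.
#' @param nppa_threshold perinuclear 90th-percentile intensity threshold.
#' @param nppa_ring_px radial extent of the perinuclear ring (px).
#' @param binucleate_px joining distance for same-class nuclei (px).
#' @param organization_threshold minimum sarcomere organization for
#'   length/direction reporting.
#' @param gaussian_radius_px smoothing radius for all channel binarizations.
#' @param closing_radius_px DAPI morphological-closing disc radius.
#' @param min_nucleus_area smallest retained nucleus (px).
#' @param gray_levels co-occurrence gray-level bins.
#' @param angles,offsets Haralick surface grids.
#' @param interp_factor sub-pixel interpolation factor.
#' @param gabor_wavelengths,gabor_orientations Gabor bank grids.
#' @param run_baselines compute Gabor/Fourier scores per cell.
#' @param seed integer seed echoed into outputs (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_size_um = SARCOTEX_PIXEL_SIZE_UM,
                            bleed_ratio = 1.5,
                            nppa_threshold = 0.1,
                            nppa_ring_px = 8,
                            binucleate_px = 25,
                            organization_threshold = 0.1,
                            gaussian_radius_px = 4,
                            closing_radius_px = 3,
                            min_nucleus_area = 60,
                            gray_levels = 8,
                            angles = seq(0, 176, by = 4),
                            offsets = 1:40,
                            interp_factor = 8,
                            gabor_wavelengths = exp(seq(log(4), log(32), length.out = 10)),
                            gabor_orientations = seq(0, 180 - 11.25, by = 11.25),
                            run_baselines = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  num <- c("pixel_size_um", "bleed_ratio", "nppa_threshold", "nppa_ring_px",
           "binucleate_px", "organization_threshold", "gaussian_radius_px",
           "min_nucleus_area", "gray_levels")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      abort(sprintf("config value `%s` must be positive.", nm),
            class = "sarcotex_config_error")
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full per-cell analysis pipeline
#'
#' Wires all stages together: DAPI bleed-through correction, nucleus
#' detection, marker and Nppa classification, binucleate joining,
#' sequential-masking watershed cell segmentation, per-cell morphology, SOTA
#' sarcomere metrics on the alpha-actinin channel, cell-sarcomere
#' misalignment, and (optionally) the Gabor and Fourier comparator scores.
#' The run is deterministic for a given stack and configuration.
#'
#' @param stack a [channel_stack()] (channels `dapi` and `actinin` required;
#'   `hcn4`, `nppa` optional — the corresponding classifications are skipped
#'   and logged when absent), or a named character vector of image paths
#'   accepted by [read_channel_stack()].
#' @param config a [pipeline_config()].
#' @param output_dir if given, per-cell CSV, nucleus/cell label TIFFs, and a
#'   JSON run-metadata file are written there.
#' @return List of class `sarcotex_run`: `cells` (per-cell tibble including
#'   subtype, morphology, sarcomere and misalignment columns), `nuclei`
#'   (per-nucleus tibble), `cell_labels`, `nucleus_labels`, `config`, `log`
#'   (character vector of stage messages).
#' @export
run_pipeline <- function(stack, config = pipeline_config(), output_dir = NULL) {
  if (is.character(stack)) {
    stack <- read_channel_stack(stack, pixel_size_um = config$pixel_size_um)
  }
  stopifnot(inherits(stack, "channel_stack"), inherits(config, "pipeline_config"))
  ch <- stack$channels
  if (is.null(ch$dapi) || is.null(ch$actinin)) {
    abort("pipeline requires 'dapi' and 'actinin' channels.",
          class = "sarcotex_config_error")
  }
  log <- character()
  note <- function(...) { log <<- c(log, sprintf(...)); invisible(NULL) }
  note("channels present: %s", paste(names(ch), collapse = ", "))
  if (is.null(ch$hcn4)) note("hcn4 channel absent: hcn4 classification disabled")
  if (is.null(ch$nppa)) note("nppa channel absent: nppa classification disabled")

  dapi <- withCallingHandlers(
    correct_dapi_bleedthrough(ch$dapi, ch$nppa, ch$hcn4, config$bleed_ratio),
    message = function(m) { note("%s", conditionMessage(m)); invokeRestart("muffleMessage") })
  nuclei <- detect_nuclei(dapi, config$min_nucleus_area,
                          config$closing_radius_px, config$gaussian_radius_px)
  note("nuclei detected: %d", max(nuclei))

  records <- classify_nucleus_markers(nuclei, ch$actinin, ch$hcn4,
                                      config$gaussian_radius_px)
  nppa_pos <- if (!is.null(ch$nppa) && nrow(records)) {
    classify_nppa(nuclei, ch$nppa, config$nppa_ring_px,
                  config$nppa_threshold)
  } else NULL
  records <- join_binucleates(nuclei, records, config$binucleate_px)
  if (nrow(records)) {
    records$nppa_positive <- if (is.null(nppa_pos)) FALSE
                             else unname(nppa_pos[as.character(records$label)])
  }
  note("nucleus classes: %s",
       paste(names(table(records$marker_class)),
             table(records$marker_class), sep = "=", collapse = ", "))

  seg <- segment_cells(stack, nuclei, records, nppa_pos,
                       config$gaussian_radius_px)
  cells <- seg$cells
  note("cells segmented: %d", nrow(cells))

  if (nrow(cells)) {
    extra <- purrr::map(cells$cell_id, function(id) {
      mask <- seg$labels == id
      morph <- tryCatch(compute_morphology(mask, config$pixel_size_um),
                        sarcotex_invalid_input = function(e) NULL)
      # texture metrics only need the cell's bounding box (pairs are
      # mask-restricted); pad so Gabor kernels keep local context
      rc <- which(mask, arr.ind = TRUE)
      pad <- 16L
      rr <- max(1L, min(rc[, 1]) - pad):min(nrow(mask), max(rc[, 1]) + pad)
      cc <- max(1L, min(rc[, 2]) - pad):min(ncol(mask), max(rc[, 2]) + pad)
      act_crop <- ch$actinin[rr, cc]
      mask_crop <- mask[rr, cc]
      sarc <- tryCatch(
        sota_metrics(act_crop, mask_crop, config$pixel_size_um,
                     config$angles, config$offsets, config$gray_levels,
                     config$interp_factor, config$organization_threshold),
        error = function(e) NULL)
      row <- tibble::tibble(.rows = 1)
      if (!is.null(morph)) {
        row <- dplyr::bind_cols(row, dplyr::select(morph, -"area_px"))
      }
      if (!is.null(sarc)) {
        row <- dplyr::bind_cols(
          row,
          dplyr::rename(sarc, sarcomere_organization = "organization",
                        sarcomere_length_um = "length_um",
                        sarcomere_direction_deg = "direction_deg",
                        sarcomere_length_px = "length_px"))
      }
      row$gabor_score <- if (config$run_baselines)
        gabor_score(act_crop, mask_crop, config$gabor_wavelengths,
                    config$gabor_orientations) else NA_real_
      row$fourier_score <- if (config$run_baselines)
        tryCatch(fourier_score(act_crop, mask_crop),
                 sarcotex_invalid_input = function(e) NA_real_) else NA_real_
      row
    })
    cells <- dplyr::bind_cols(cells, dplyr::bind_rows(extra))
    cells$misalignment_deg <- cell_sarcomere_misalignment(
      cells$major_axis_deg, cells$sarcomere_direction_deg)
  }

  run <- structure(list(cells = cells, nuclei = records,
                        cell_labels = seg$labels, nucleus_labels = nuclei,
                        config = config, log = log),
                   class = "sarcotex_run")
  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

write_run_outputs <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cells_out <- dplyr::select(run$cells, -dplyr::any_of("length_is_first_peak"))
  write.csv(cells_out, file.path(output_dir, "cells.csv"), row.names = FALSE)
  write.csv(run$nuclei, file.path(output_dir, "nuclei.csv"), row.names = FALSE)
  write_label_tiff(run$cell_labels, file.path(output_dir, "cell_labels.tif"))
  write_label_tiff(run$nucleus_labels, file.path(output_dir, "nucleus_labels.tif"))
  jsonlite::write_json(
    list(config = unclass(run$config), log = run$log,
         n_nuclei = nrow(run$nuclei), n_cells = nrow(run$cells)),
    file.path(output_dir, "run_metadata.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.sarcotex_run <- function(x, ...) {
  cat(sprintf("<sarcotex_run> %d nuclei, %d cells\n",
              nrow(x$nuclei), nrow(x$cells)))
  if (nrow(x$cells)) print(dplyr::count(x$cells, .data$subtype))
  invisible(x)
}

#' Subtype tally of a pipeline run
#'
#' Groups segmented cells by their marker-combination subtype, the
#' distribution view of cardiac marker expression over a field.
#'
#' @param run a [run_pipeline()] result (or its `cells` tibble).
#' @return Tibble with `subtype` and `n`.
#' @export
subtype_tally <- function(run) {
  cells <- if (inherits(run, "sarcotex_run")) run$cells else run
  dplyr::count(cells, .data$subtype, name = "n")
}
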