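#' Multi-channel image stack
#'
#' The raw input unit of the pipeline: a set of co-registered grayscale
#' channels (named matrices with intensities in [0, 1]) plus the physical
#' pixel size. The full pipeline requires `dapi` and `actinin`; `hcn4` and
#' `nppa` are optional and the corresponding classifications are skipped when
#' absent.
#'
#' @param channels named list of numeric matrices, all the same shape,
#'   values in [0, 1].
#' @param pixel_size_um physical pixel size in micrometers per pixel.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = SARCOTEX_PIXEL_SIZE_UM) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("`channels` must be a named list of matrices.")
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) {
    abort("all channels must be co-registered (identical dimensions).")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) abort(sprintf("channel '%s' is not a numeric matrix.", nm))
    if (anyNA(ch) || min(ch) < 0 || max(ch) > 1) {
      abort(sprintf("channel '%s' must have intensities in [0, 1] with no NAs.", nm))
    }
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a positive number.")
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> %d x %d px | %.5g um/px | channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

read_gray_image <- function(path) {
  img <- switch(tolower(tools::file_ext(path)),
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    abort(sprintf("unsupported image format: '%s' (use TIFF or PNG).", path),
          class = "sarcotex_io_error")
  )
  if (length(dim(img)) == 3) img <- img[, , 1]   # take first plane of RGB/gray-alpha
  img
}

#' Read a channel stack from image files
#'
#' Accepts either a named character vector mapping channel names to
#' single-page TIFF/PNG files, or the path of a multi-page TIFF written by
#' [write_channel_stack()] (channel names are taken from its JSON sidecar, or
#' from `channel_names`).
#'
#' @param paths named character vector (`c(dapi = "...", actinin = "...")`)
#'   or a single multi-page TIFF path.
#' @param pixel_size_um physical pixel size.
#' @param channel_names channel names for a multi-page TIFF without a sidecar.
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(paths, pixel_size_um = SARCOTEX_PIXEL_SIZE_UM,
                               channel_names = NULL) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("image file(s) not found: %s", paste(missing, collapse = ", ")),
          class = "sarcotex_io_error")
  }
  if (length(paths) == 1 && is.null(names(paths))) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    sidecar <- paste0(tools::file_path_sans_ext(paths), ".channels.json")
    meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nms <- channel_names %||% meta$channels
    if (is.null(nms) || length(nms) != length(pages)) {
      abort("multi-page TIFF needs `channel_names` or a .channels.json sidecar.",
            class = "sarcotex_io_error")
    }
    if (!is.null(meta$pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    chans <- setNames(lapply(pages, function(p) {
      if (length(dim(p)) == 3) p[, , 1] else p
    }), nms)
  } else {
    if (is.null(names(paths))) abort("`paths` must be named by channel.")
    chans <- lapply(paths, read_gray_image)
  }
  channel_stack(chans, pixel_size_um)
}

#' Write a channel stack as a multi-page TIFF
#'
#' One 16-bit page per channel; channel names and pixel size go to a
#' `.channels.json` sidecar next to the TIFF so [read_channel_stack()] can
#' restore them.
#'
#' @param stack a [channel_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  tiff::writeTIFF(unname(stack$channels), path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channels = names(stack$channels), pixel_size_um = stack$pixel_size_um),
    paste0(tools::file_path_sans_ext(path), ".channels.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write an integer label map as a 16-bit TIFF
#'
#' @param labels integer matrix of object labels (0 = background).
#' @param path output path.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) abort("more than 65535 labels cannot be stored in 16 bits.")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_label_tiff()]
#' @param path TIFF path.
#' @return integer matrix.
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Materialize the stripe-panel phantoms on disk
#'
#' Writes the six [make_stripe_panels()] images as single-page TIFFs plus a
#' CSV of their generating parameters; used by the command-line `fixtures`
#' subcommand.
#'
#' @param dir output directory (created if needed).
#' @param shape,seed passed to [make_stripe_panels()].
#' @return Tibble of the written files and parameters, invisibly.
#' @export
write_stripe_fixtures <- function(dir, shape = c(128, 128), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panels <- make_stripe_panels(shape, seed)
  info <- purrr::map2(panels, names(panels), function(ph, nm) {
    f <- file.path(dir, paste0("stripes_", nm, ".tif"))
    tiff::writeTIFF(ph$image, f, bits.per.sample = 16L)
    tibble::tibble(name = nm, file = f, period_px = ph$period_px,
                   orientation_deg = ph$orientation_deg, duty = ph$duty,
                   noise_sd = ph$noise_sd, coverage = ph$coverage,
                   jitter_sd = ph$jitter_sd)
  })
  out <- dplyr::bind_rows(info)
  write.csv(out, file.path(dir, "stripes_truth.csv"), row.names = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
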