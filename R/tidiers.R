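#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line facet_wrap
#'   scale_y_reverse coord_fixed labs theme_minimal scale_fill_viridis_c
#'   scale_fill_gradient
#' @export
ggplot2::autoplot

#' Tidy a Haralick surface into a long tibble
#'
#' @param x a [haralick_surface()].
#' @param interpolated use the sub-pixel interpolated traces (default) or the
#'   raw grid values.
#' @param ... unused.
#' @return Tibble with `angle_deg`, `offset_px`, `value`, `feature`.
#' @export
tidy.haralick_surface <- function(x, interpolated = TRUE, ...) {
  if (interpolated) {
    vals <- x$interp; offs <- x$interp_offsets
  } else {
    vals <- x$values; offs <- x$offsets
  }
  tibble::tibble(
    angle_deg = rep(x$angles, times = length(offs)),
    offset_px = rep(offs, each = length(x$angles)),
    value = as.vector(vals),
    feature = x$feature
  )
}

#' One-row summary of a Haralick surface
#'
#' @param x a [haralick_surface()].
#' @param pixel_size_um,organization_threshold passed to
#'   [extract_sarcomere_metrics()].
#' @param ... unused.
#' @return One-row tibble: feature, grid sizes, and the extracted sarcomere
#'   metrics.
#' @export
glance.haralick_surface <- function(x, pixel_size_um = SARCOTEX_PIXEL_SIZE_UM,
                                    organization_threshold = 0.1, ...) {
  met <- extract_sarcomere_metrics(x, pixel_size_um, organization_threshold)
  dplyr::bind_cols(
    tibble::tibble(feature = x$feature, n_angles = length(x$angles),
                   n_offsets = length(x$offsets), levels = x$levels),
    met
  )
}

#' @export
tidy.periodic_fit <- function(x, ...) {
  g <- tibble::tibble(term = paste0("gaussian_", names(x$gaussian)),
                      estimate = unname(x$gaussian))
  if (!is.null(x$aperiodic)) {
    g <- dplyr::bind_rows(
      g, tibble::tibble(term = names(x$aperiodic),
                        estimate = unname(x$aperiodic)))
  }
  g
}

#' @export
glance.periodic_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged,
                 amplitude = unname(x$gaussian["amplitude"]),
                 se_amplitude = x$se_amplitude,
                 resid_norm = x$resid_norm)
}

#' Heatmap of a Haralick surface
#'
#' Angle-by-offset raster of the feature values; striated texture appears as
#' periodic vertical banding concentrated at the striation direction.
#'
#' @param object a [haralick_surface()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.haralick_surface <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(.data$offset_px, .data$angle_deg, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(x = "offset distance (px)", y = "angle (deg)",
         fill = object$feature,
         title = sprintf("Haralick %s surface", object$feature)) +
    theme_minimal()
}

#' Per-angle traces of a Haralick surface
#'
#' @param surface a [haralick_surface()].
#' @param angles which angles (degrees) to draw; defaults to the trace
#'   holding the global maximum-prominence peak plus its perpendicular.
#' @return A ggplot.
#' @export
plot_surface_traces <- function(surface, angles = NULL) {
  if (is.null(angles)) {
    met <- extract_sarcomere_metrics(surface, organization_threshold = -Inf)
    a1 <- if (is.na(met$direction_deg)) surface$angles[1] else met$direction_deg
    a2 <- surface$angles[which.min(abs(((surface$angles - a1 - 90 + 90) %% 180) - 90))]
    angles <- unique(c(a1, a2))
  }
  df <- dplyr::filter(tidy(surface), .data$angle_deg %in% angles)
  ggplot(df, aes(.data$offset_px, .data$value,
                 colour = factor(.data$angle_deg))) +
    geom_line(na.rm = TRUE) +
    labs(x = "offset distance (px)", y = surface$feature,
         colour = "angle (deg)") +
    theme_minimal()
}

image_raster_df <- function(img, name) {
  tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    intensity = as.vector(img),
    channel = name
  )
}

#' Plot a stripe phantom
#' @param object a [make_stripes()] phantom.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.stripe_phantom <- function(object, ...) {
  ggplot(image_raster_df(object$image, "phantom"),
         aes(.data$col, .data$row, fill = .data$intensity)) +
    geom_raster() + scale_y_reverse() + coord_fixed() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    labs(title = sprintf("stripes: period %.3g px @ %.0f deg",
                         object$period_px, object$orientation_deg),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot the channels of a stack side by side
#' @param object a [channel_stack()].
#' @param ... unused.
#' @return A ggplot faceted by channel.
#' @export
autoplot.channel_stack <- function(object, ...) {
  df <- dplyr::bind_rows(purrr::map2(object$channels, names(object$channels),
                                     image_raster_df))
  ggplot(df, aes(.data$col, .data$row, fill = .data$intensity)) +
    geom_raster() + scale_y_reverse() + coord_fixed() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    facet_wrap(~channel) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
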