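#' Shape-metric formulas
#'
#' The definitional formulas behind the per-cell shape metrics, exposed so
#' they can be evaluated on analytic shapes as well as rasters:
#' `circularity_index()` is `4 * pi * area / perimeter^2` (1 for a perfect
#' circle); `ellipse_eccentricity()` is the focal distance over the major
#' axis length, `sqrt(major^2 - minor^2) / major` (0 for a circle).
#'
#' @param area,perimeter region area and boundary length (any consistent
#'   units).
#' @param major,minor full axis lengths of the ellipse, `major >= minor > 0`.
#' @return Numeric scalar.
#' @examples
#' circularity_index(pi * 5^2, 2 * pi * 5)   # exactly 1
#' ellipse_eccentricity(10, 10)              # exactly 0
#' @export
circularity_index <- function(area, perimeter) 4 * pi * area / perimeter^2

#' @rdname circularity_index
#' @export
ellipse_eccentricity <- function(major, minor) {
  stopifnot(all(major >= minor), all(minor > 0))
  sqrt(major^2 - minor^2) / major
}

# Boundary length of a binary mask from its 8-connected outer contour,
# with Kulpa's step weights (0.948 axial, 1.340 diagonal) to correct the
# digitization bias of raw chain length.
mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask), ncol(mask)))[[1]]
  if (nrow(oc) < 2) return(4)   # single pixel
  steps <- diff(rbind(oc, oc[1, , drop = FALSE]))
  diag_step <- rowSums(abs(steps)) == 2
  0.948 * sum(!diag_step) + 1.340 * sum(diag_step)
}

#' Per-cell morphology metrics
#'
#' Size and shape descriptors of a segmented region: area in square
#' micrometers; elongation (major/minor axis length ratio); circularity
#' (`4 * pi * area / perimeter^2`); eccentricity of the ellipse with the same
#' second moments as the region; and the major-axis orientation. Axis lengths
#' come from the eigenvalues of the pixel-coordinate covariance (pixel
#' centers, each pixel spread by the 1/12 variance of its unit square), the
#' same-second-moments-ellipse convention of standard region-props
#' implementations. The perimeter uses a bias-corrected 8-connected chain
#' length, recorded in the `perimeter_estimator` column.
#'
#' @param mask logical matrix containing a single connected component of at
#'   least 16 pixels.
#' @param pixel_size_um physical pixel size.
#' @return One-row tibble: `area_um2`, `elongation`, `circularity`,
#'   `eccentricity`, `major_axis_deg` (degrees in [0, 180), ccw from the +x
#'   image axis with y up), `area_px`, `perimeter_px`, `perimeter_estimator`.
#' @examples
#' disc <- outer(1:81, 1:81, function(r, c) (r - 41)^2 + (c - 41)^2 <= 30^2)
#' compute_morphology(disc, 1)
#' @export
compute_morphology <- function(mask, pixel_size_um = SARCOTEX_PIXEL_SIZE_UM) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.",
                              class = "sarcotex_invalid_input")
  mask <- mask > 0
  n <- sum(mask)
  if (n < 16) abort("mask must contain at least 16 pixels.",
                    class = "sarcotex_invalid_input")
  lab <- EBImage::bwlabel(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  if (max(lab) != 1) abort("mask must be a single connected component.",
                           class = "sarcotex_invalid_input")

  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2]; y <- -idx[, 1]           # math convention, y up
  mx <- mean(x); my <- mean(y)
  cxx <- mean((x - mx)^2) + 1 / 12
  cyy <- mean((y - my)^2) + 1 / 12
  cxy <- mean((x - mx) * (y - my))
  tr <- cxx + cyy
  disc <- sqrt(pmax((cxx - cyy)^2 + 4 * cxy^2, 0))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  theta <- (atan2(2 * cxy, cxx - cyy) / 2 * 180 / pi) %% 180

  per <- mask_perimeter(mask)
  tibble::tibble(
    area_um2 = n * pixel_size_um^2,
    elongation = major / minor,
    circularity = circularity_index(n, per),
    eccentricity = ellipse_eccentricity(major, minor),
    major_axis_deg = theta,
    area_px = n,
    perimeter_px = per,
    perimeter_estimator = "kulpa_chain8"
  )
}
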