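#' Marker-controlled watershed on a gradient image
#'
#' Floods catchment basins outward from labeled marker pixels in order of
#' increasing `gradient` value (seeded priority-flood / Meyer algorithm,
#' 4-connected). Every pixel ends up in the basin of some marker, so a
#' background marker should normally be included alongside the object
#' markers.
#'
#' @param gradient numeric matrix, typically a Sobel gradient magnitude.
#' @param markers integer matrix of the same shape; positive labels are
#'   seeds, 0 is unassigned.
#' @return Integer label matrix: each pixel carries the label of the basin
#'   that claimed it.
#' @export
watershed_markers <- function(gradient, markers) {
  stopifnot(is.matrix(gradient), is.matrix(markers),
            identical(dim(gradient), dim(markers)))
  if (!any(markers > 0)) abort("`markers` contains no seeds.")
  storage.mode(markers) <- "integer"
  watershed_flood(gradient, markers)
}

#' Sobel gradient magnitude
#'
#' Applies horizontal and vertical Sobel edge-emphasizing kernels and returns
#' the hypotenuse of the two responses.
#'
#' @param image numeric matrix.
#' @return Numeric matrix of gradient magnitudes.
#' @export
sobel_gradient <- function(image) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gy <- as.matrix(EBImage::filter2(image, kx))
  gx <- as.matrix(EBImage::filter2(image, t(kx)))
  sqrt(gx^2 + gy^2)
}
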