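#' Gray-level co-occurrence matrix inside an arbitrary mask
#'
#' Counts how often a pixel of binned intensity i is paired with a pixel of
#' binned intensity j at a fixed integer displacement. Both pixels of a pair
#' must lie inside the mask, which is what lets texture be measured for
#' pixels of the cellular region alone, with no bounding-box artifacts.
#'
#' Intensities are binned into `levels` equal-width bins spanning the in-mask
#' min-max range (a constant region collapses to a single bin). With
#' `symmetric = TRUE` (default) each pair is accumulated in both directions,
#' so the matrix is symmetric and features are invariant to flipping the
#' offset sign.
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same shape, or `NULL` for the whole
#'   image.
#' @param offset integer displacement `c(drow, dcol)` between the pixels of a
#'   pair.
#' @param levels number of gray-level bins (8 is the conventional default for
#'   grayscale, 2 for binary images).
#' @param symmetric accumulate pairs in both directions.
#' @return An object of class `glcm`: list with `p` (levels x levels
#'   probability matrix summing to 1), `counts`, `offset`, `levels`,
#'   `symmetric`, `n_pairs`.
#' @examples
#' g <- compute_glcm(matrix(c(0, 1, 0, 1), 2, 2), offset = c(0, 1), levels = 2)
#' g$p
#' @export
compute_glcm <- function(image, mask = NULL, offset, levels = 8,
                         symmetric = TRUE) {
  stopifnot(is.matrix(image), length(offset) == 2)
  offset <- as.integer(round(offset))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(mask), dim(image)))

  b <- bin_intensities(image, mask, levels)
  nr <- nrow(image); nc <- ncol(image)
  dr <- offset[1]; dc <- offset[2]

  if (max(1, 1 - dr) > min(nr, nr - dr) || max(1, 1 - dc) > min(nc, nc - dc)) {
    abort("offset larger than the image; no pixel pairs exist.",
          class = "sarcotex_degenerate_glcm")
  }
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a  <- b[r1, c1, drop = FALSE]
  bb <- b[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(bb)
  n_pairs <- sum(ok)
  if (n_pairs < 2) {
    abort("fewer than 2 valid in-mask pixel pairs at this offset.",
          class = "sarcotex_degenerate_glcm")
  }
  code <- (a[ok] - 1L) * levels + bb[ok]
  counts <- matrix(tabulate(code, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), counts = counts, offset = offset,
                 levels = levels, symmetric = symmetric, n_pairs = n_pairs),
            class = "glcm")
}

# bin in-mask intensities into `levels` equal-width bins over min-max;
# out-of-mask pixels are NA
bin_intensities <- function(image, mask, levels) {
  v <- image[mask]
  if (!length(v)) abort("mask is empty.", class = "sarcotex_degenerate_glcm")
  lo <- min(v); hi <- max(v)
  b <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi == lo) {
    b[mask] <- 1L
  } else {
    idx <- pmin(as.integer(floor((image[mask] - lo) / (hi - lo) * levels)) + 1L,
                levels)
    b[mask] <- idx
  }
  b
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels | offset (%d, %d) | %s | %d pairs\n",
              x$levels, x$offset[1], x$offset[2],
              if (x$symmetric) "symmetric" else "asymmetric", x$n_pairs))
  print(round(x$p, 4))
  invisible(x)
}

as_glcm_p <- function(glcm) {
  if (inherits(glcm, "glcm")) return(glcm$p)
  if (is.matrix(glcm)) {
    s <- sum(glcm)
    if (abs(s - 1) > 1e-8) return(glcm / s)
    return(glcm)
  }
  abort("expected a `glcm` object or a co-occurrence probability matrix.")
}

#' Haralick texture features of a co-occurrence matrix
#'
#' `haralick_correlation()` measures the likelihood of finding two pixels of
#' similar intensity separated by the matrix's offset:
#' \deqn{\sum_{i,j} \frac{(i-\mu_i)(j-\mu_j)\,p(i,j)}{\sigma_i \sigma_j}}
#' with \eqn{\mu_i, \sigma_i} the mean and standard deviation of the row
#' marginal \eqn{p_i} (and likewise for columns). It lies in [-1, 1] and is
#' undefined for a constant region (\eqn{\sigma = 0}), in which case a
#' condition of class `sarcotex_undefined_correlation` is signalled.
#'
#' `haralick_contrast()` is \eqn{\sum |i-j|^2 p(i,j)};
#' `haralick_uniformity()` (energy / angular second moment) is
#' \eqn{\sum p(i,j)^2}; `haralick_homogeneity()` is
#' \eqn{\sum p(i,j) / (1 + |i-j|)}.
#'
#' @param glcm a [compute_glcm()] result or a probability matrix.
#' @return A single numeric value.
#' @export
haralick_correlation <- function(glcm) {
  p <- as_glcm_p(glcm)
  g <- nrow(p)
  i <- seq_len(g)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(i * pi_); mu_j <- sum(i * pj_)
  sd_i <- sqrt(sum((i - mu_i)^2 * pi_)); sd_j <- sqrt(sum((i - mu_j)^2 * pj_))
  if (sd_i == 0 || sd_j == 0) {
    abort("correlation undefined: a marginal has zero variance (constant region).",
          class = "sarcotex_undefined_correlation")
  }
  sum(outer(i - mu_i, i - mu_j) * p) / (sd_i * sd_j)
}

#' @rdname haralick_correlation
#' @export
haralick_contrast <- function(glcm) {
  p <- as_glcm_p(glcm)
  i <- seq_len(nrow(p))
  sum(outer(i, i, function(a, b) abs(a - b)^2) * p)
}

#' @rdname haralick_correlation
#' @export
haralick_uniformity <- function(glcm) {
  p <- as_glcm_p(glcm)
  sum(p^2)
}

#' @rdname haralick_correlation
#' @export
haralick_homogeneity <- function(glcm) {
  p <- as_glcm_p(glcm)
  i <- seq_len(nrow(p))
  sum(p / (1 + outer(i, i, function(a, b) abs(a - b))))
}

haralick_feature_fun <- function(feature) {
  switch(feature,
         correlation = haralick_correlation,
         contrast = haralick_contrast,
         uniformity = haralick_uniformity,
         homogeneity = haralick_homogeneity,
         abort(sprintf("unknown Haralick feature '%s'.", feature)))
}

#' Texture variance value at unit offset
#'
#' Sum of the Haralick contrast values over the angle grid at an offset
#' distance of one pixel. Close to zero for homogeneous regions and large for
#' strongly patterned ones, so it serves as a cheap patternedness screen.
#'
#' @param image,mask as in [compute_glcm()].
#' @param angles angle grid in degrees, [0, 180).
#' @param levels gray-level bins.
#' @return Numeric scalar (sum over angles; degenerate angles are skipped
#'   with a warning).
#' @export
variance_metric <- function(image, mask = NULL, angles = seq(0, 176, by = 4),
                            levels = 8) {
  offs <- unique(lapply(angles, function(a) offset_for(a, 1)))
  vals <- vapply(offs, function(o) {
    tryCatch(haralick_contrast(compute_glcm(image, mask, o, levels)),
             sarcotex_degenerate_glcm = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(vals)) warn("degenerate co-occurrence matrix at some angles; skipped.")
  sum(vals, na.rm = TRUE)
}

# integer pixel displacement for angle (deg, ccw from +x with y up) and
# offset distance d (px)
offset_for <- function(angle_deg, d) {
  th <- angle_deg * pi / 180
  as.integer(round(c(-d * sin(th), d * cos(th))))
}
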