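#' Haralick feature surface over an angle-by-offset grid
#'
#' The core of SarcOmere Texture Analysis: a gray-level co-occurrence matrix
#' is computed for every combination of orientation angle and pixel offset
#' distance (both pixels of each pair restricted to the mask), a Haralick
#' feature is evaluated on each, and every per-angle trace is interpolated to
#' sub-pixel offset resolution (piecewise-linear, so interpolation never
#' overshoots the computed values). Striated texture shows up as repeated
#' peaks along the trace of the periodicity direction.
#'
#' For each angle and distance the real-valued displacement
#' `d * (-sin(theta), cos(theta))` is rounded to the nearest integer pixel
#' displacement (GLCM semantics require integer offsets); duplicate integer
#' displacements within an angle are computed once, and each is placed on the
#' offset axis at the Euclidean length of its rounded displacement before
#' interpolation.
#'
#' @param image numeric matrix.
#' @param mask logical matrix or `NULL` (whole frame).
#' @param feature one or more of `"correlation"`, `"contrast"`,
#'   `"uniformity"`, `"homogeneity"`. All requested features share the same
#'   co-occurrence matrices, so asking for several costs little extra.
#' @param angles angle grid in degrees within [0, 180) (the surface is
#'   180-degree periodic).
#' @param offsets integer offset distances in pixels.
#' @param levels gray-level bins for the co-occurrence matrices.
#' @param interp_factor sub-pixel resolution: each trace is resampled at
#'   `1 / interp_factor` px spacing.
#' @param symmetric symmetric co-occurrence accumulation.
#' @param min_pairs minimum number of in-mask pixel pairs for a surface entry
#'   to be considered valid; below it the entry is `NA`. The correlation
#'   estimate has standard error of roughly `1/sqrt(n_pairs)`, so small
#'   masks at large oblique offsets would otherwise contribute wild values.
#' @return For a single feature, an object of class `haralick_surface`:
#'   `values` (angles x offsets matrix on the requested grid), `interp`
#'   (angles x fine-offset matrix), `interp_offsets`, `angles`, `offsets`,
#'   `feature`, plus binning metadata. Entries whose co-occurrence matrix is
#'   degenerate are `NA` and do not poison neighbouring entries. For several
#'   features, a named list of such objects.
#' @export
haralick_surface <- function(image, mask = NULL, feature = "correlation",
                             angles = seq(0, 176, by = 4), offsets = 1:40,
                             levels = 8, interp_factor = 8, symmetric = TRUE,
                             min_pairs = 300) {
  features <- match.arg(feature,
                        c("correlation", "contrast", "uniformity", "homogeneity"),
                        several.ok = TRUE)
  stopifnot(all(angles >= 0 & angles < 180), all(offsets >= 1))
  m <- length(angles); n <- length(offsets)
  xout <- seq(min(offsets), max(offsets), by = 1 / interp_factor)

  vals <- lapply(features, function(f) matrix(NA_real_, m, n))
  names(vals) <- features
  interp <- lapply(features, function(f) matrix(NA_real_, m, length(xout)))
  names(interp) <- features

  for (ai in seq_len(m)) {
    offs <- lapply(offsets, function(d) offset_for(angles[ai], d))
    key <- vapply(offs, paste, character(1), collapse = ",")
    uniq <- !duplicated(key)
    feats_at <- new.env(parent = emptyenv())
    for (k in which(uniq)) {
      g <- tryCatch(compute_glcm(image, mask, offs[[k]], levels, symmetric),
                    sarcotex_degenerate_glcm = function(e) NULL)
      if (!is.null(g) && g$n_pairs < min_pairs) g <- NULL
      fv <- if (is.null(g)) {
        rep(NA_real_, length(features))
      } else {
        vapply(features, function(f) {
          tryCatch(haralick_feature_fun(f)(g),
                   sarcotex_undefined_correlation = function(e) NA_real_)
        }, numeric(1))
      }
      assign(key[k], fv, envir = feats_at)
    }
    for (fi in seq_along(features)) {
      v <- vapply(key, function(k) get(k, envir = feats_at)[fi], numeric(1))
      vals[[fi]][ai, ] <- v
      # spline over unique displacements at their true Euclidean lengths
      ku <- which(uniq)
      x <- vapply(offs[ku], function(o) sqrt(sum(o^2)), numeric(1))
      y <- v[ku]
      keep <- !is.na(y) & x > 0
      x <- x[keep]; y <- y[keep]
      if (length(x) >= 4) {
        o <- order(x); x <- x[o]; y <- y[o]
        inside <- xout >= min(x) & xout <= max(x)
        interp[[fi]][ai, inside] <- approx(x, y, xout = xout[inside],
                                           ties = mean)$y
      }
    }
  }

  out <- lapply(features, function(f) {
    structure(list(feature = f, values = vals[[f]], interp = interp[[f]],
                   interp_offsets = xout, angles = angles, offsets = offsets,
                   levels = levels, symmetric = symmetric,
                   image_dim = dim(image)),
              class = "haralick_surface")
  })
  names(out) <- features
  if (length(out) == 1) out[[1]] else out
}

#' @export
print.haralick_surface <- function(x, ...) {
  cat(sprintf("<haralick_surface> %s | %d angles x %d offsets (interp %d) | %d levels\n",
              x$feature, length(x$angles), length(x$offsets),
              length(x$interp_offsets), x$levels))
  invisible(x)
}

#' Local maxima and their topographic prominences
#'
#' Finds strict local maxima of a 1-D trace and computes each peak's
#' topographic prominence: its height above the higher of the two lowest
#' points separating it from higher terrain (or from the trace ends). On a
#' decaying oscillatory trace prominence is baseline-free, unlike raw peak
#' height.
#'
#' @param y numeric trace (NAs allowed at the ends; internal NAs split the
#'   trace is not supported and such traces are trimmed to the first
#'   contiguous run).
#' @param x positions of the samples (defaults to indices).
#' @return Tibble with `x`, `height`, `prominence`, one row per peak,
#'   ordered by position.
#' @export
find_peaks <- function(y, x = seq_along(y)) {
  ok <- !is.na(y)
  if (!any(ok)) return(tibble::tibble(x = numeric(), height = numeric(),
                                      prominence = numeric()))
  first <- which(ok)[1]
  last <- first + which(!ok[first:length(y)])[1] - 2
  if (is.na(last)) last <- length(y)
  y <- y[first:last]; x <- x[first:last]
  n <- length(y)
  if (n < 3) return(tibble::tibble(x = numeric(), height = numeric(),
                                   prominence = numeric()))
  pk <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  prom <- vapply(pk, function(i) {
    j <- i - 1L; lmin <- y[i]
    while (j >= 1L && y[j] <= y[i]) { if (y[j] < lmin) lmin <- y[j]; j <- j - 1L }
    k <- i + 1L; rmin <- y[i]
    while (k <= n && y[k] <= y[i]) { if (y[k] < rmin) rmin <- y[k]; k <- k + 1L }
    y[i] - max(lmin, rmin)
  }, numeric(1))
  tibble::tibble(x = x[pk], height = y[pk], prominence = prom)
}

#' Sarcomere metrics from a Haralick correlation surface
#'
#' Scans every interpolated per-angle trace of the surface for local maxima
#' and their topographic prominences. Sarcomere organization is the maximum
#' prominence over all traces; the angle at which it occurs is the primary
#' sarcomere direction (the axis along which intensity is periodic, i.e.
#' perpendicular to the Z-line bands); sarcomere length is the offset
#' distance of that peak converted to micrometers. Direction and length are
#' reported only when organization exceeds `organization_threshold` — below
#' it, the peak position reflects arbitrary intensity features rather than
#' striation.
#'
#' @param surface a [haralick_surface()] (conventionally of the correlation
#'   feature).
#' @param pixel_size_um physical pixel size.
#' @param organization_threshold minimum organization for length/direction to
#'   be meaningful (0.1 by convention).
#' @param tie_tol relative prominence tolerance within which peaks count as
#'   tied with the global maximum; among tied peaks the smallest offset wins
#'   (protects direction and length against lattice aliasing and harmonics
#'   on highly coherent texture; see Details in the source).
#' @return One-row tibble: `organization`, `length_um`, `direction_deg`,
#'   `length_px`, `length_is_first_peak` (whether the chosen peak is also the
#'   first peak of its trace — they coincide for clean striation and diverge
#'   on harmonics), `n_peaks`.
#' @export
extract_sarcomere_metrics <- function(surface,
                                      pixel_size_um = SARCOTEX_PIXEL_SIZE_UM,
                                      organization_threshold = 0.1,
                                      tie_tol = 0.02) {
  stopifnot(inherits(surface, "haralick_surface"))
  # Organization is the global maximum prominence. For direction and length,
  # all peaks within `tie_tol` (relative) of that maximum count as tied and
  # the one at the smallest offset wins. Near-ties arise for highly coherent
  # periodic texture: any angle whose rounded offsets hit the stripe lattice
  # swings almost as hard as the true direction, but always with a stretched
  # apparent period, and harmonics of the true period likewise tie at larger
  # offsets — so the shortest-offset rule recovers the true direction and
  # period. On decaying real-cell traces the maximum is isolated and the
  # rule is inert.
  all_pks <- list(); total_peaks <- 0L
  for (ai in seq_along(surface$angles)) {
    pks <- find_peaks(surface$interp[ai, ], surface$interp_offsets)
    total_peaks <- total_peaks + nrow(pks)
    if (!nrow(pks)) next
    pks$angle <- surface$angles[ai]
    pks$is_first <- seq_len(nrow(pks)) == 1L
    all_pks[[length(all_pks) + 1L]] <- pks
  }
  if (!length(all_pks)) {
    return(tibble::tibble(organization = 0, length_um = NA_real_,
                          direction_deg = NA_real_, length_px = NA_real_,
                          length_is_first_peak = NA, n_peaks = 0L))
  }
  pks <- dplyr::bind_rows(all_pks)
  gmax <- max(pks$prominence)
  near <- which(pks$prominence >= gmax * (1 - tie_tol))
  top <- near[which.min(pks$x[near])]
  best <- list(prom = gmax, x = pks$x[top], angle = pks$angle[top],
               is_first = pks$is_first[top])
  qualified <- best$prom > organization_threshold
  tibble::tibble(
    organization = best$prom,
    length_um = if (qualified) best$x * pixel_size_um else NA_real_,
    direction_deg = if (qualified) best$angle else NA_real_,
    length_px = if (qualified) best$x else NA_real_,
    length_is_first_peak = if (qualified) best$is_first else NA,
    n_peaks = total_peaks
  )
}

#' Angle between cell elongation and sarcomere direction
#'
#' Both the cell's major axis and the sarcomere direction are axial (defined
#' modulo 180 degrees), so their difference is folded into [0, 90].
#'
#' @param major_axis_deg cell major-axis orientation, degrees in [0, 180).
#' @param direction_deg primary sarcomere direction, degrees in [0, 180);
#'   `NA` (organization below threshold) propagates.
#' @return Misalignment in degrees, in [0, 90].
#' @export
cell_sarcomere_misalignment <- function(major_axis_deg, direction_deg) {
  d <- abs((major_axis_deg %% 180) - (direction_deg %% 180))
  pmin(d, 180 - d)
}

#' One-call SOTA for a masked cell image
#'
#' Convenience wrapper: correlation surface + metric extraction.
#'
#' @inheritParams haralick_surface
#' @inheritParams extract_sarcomere_metrics
#' @return One-row tibble as from [extract_sarcomere_metrics()].
#' @export
sota_metrics <- function(image, mask = NULL,
                         pixel_size_um = SARCOTEX_PIXEL_SIZE_UM,
                         angles = seq(0, 176, by = 4), offsets = 1:40,
                         levels = 8, interp_factor = 8,
                         organization_threshold = 0.1) {
  surf <- haralick_surface(image, mask, "correlation", angles, offsets,
                           levels, interp_factor)
  extract_sarcomere_metrics(surf, pixel_size_um, organization_threshold)
}
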