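#' Synthetic stripe phantoms with known period and orientation
#'
#' Generates an idealized striated-texture image: parallel bands whose
#' intensity is periodic along `orientation_deg`, emulating the Z-line
#' striations of sarcomeric alpha-actinin stains. Every geometric property of
#' the texture (period, direction, band duty cycle, noise level, spatial
#' coverage, per-band phase jitter) is a known input, so phantoms serve as
#' ground truth for texture metrics.
#'
#' The angle convention matches the analysis functions: 0 degrees is the +x
#' (column) axis, measured counterclockwise with y pointing up (i.e. against
#' image rows). `orientation_deg` is the axis *along which intensity is
#' periodic*; the visible bands run perpendicular to it. A phantom with
#' `orientation_deg = 90` therefore shows horizontal bands.
#'
#' @param shape integer vector (rows, cols); each dimension must be at least
#'   4 periods so the texture is resolvable.
#' @param period_px band-center spacing in pixels (>= 2; smaller periods are
#'   below the Nyquist limit of the pixel grid).
#' @param orientation_deg periodicity direction in degrees, folded to [0, 180).
#' @param duty fraction of each period occupied by the bright band, in (0, 1).
#' @param noise_sd standard deviation of additive Gaussian noise (intensities
#'   are clipped to [0, 1] after adding noise).
#' @param coverage fraction (0, 1] of the image, contiguous along the periodic
#'   axis, that contains stripes; the remainder is flat background.
#' @param jitter_sd standard deviation (px) of a random phase offset applied
#'   independently to each transverse band of width `band_width_px`,
#'   emulating laterally mis-registered myofibrils.
#' @param band_width_px width (px) of the transverse bands used for jitter.
#' @param profile `"rect"` for hard-edged bands (smoothed by
#'   `smooth_sigma`), or `"sine"` for a sinusoidal profile (ignores `duty`).
#' @param hi,lo intensities of bright bands and dark gaps/background.
#' @param smooth_sigma Gaussian smoothing (px) applied to the noiseless
#'   pattern; 0 disables smoothing.
#' @param seed integer seed; the phantom is a pure function of its arguments.
#' @return An object of class `stripe_phantom`: a list with `image` (matrix in
#'   [0,1]) and all generating parameters.
#' @examples
#' ph <- make_stripes(c(128, 128), period_px = 8, orientation_deg = 90)
#' range(ph$image)
#' @export
make_stripes <- function(shape, period_px, orientation_deg = 90,
                         duty = 0.5, noise_sd = 0, coverage = 1,
                         jitter_sd = 0, band_width_px = 8,
                         profile = c("rect", "sine"),
                         hi = 0.85, lo = 0.15, smooth_sigma = 1,
                         seed = NULL) {
  profile <- match.arg(profile)
  if (period_px < 2) {
    abort("`period_px` must be >= 2 (sub-Nyquist stripes are not resolvable).",
          class = "sarcotex_invalid_parameter")
  }
  if (length(shape) != 2 || any(shape < 4 * period_px)) {
    abort("each dimension of `shape` must be at least 4 * period_px.",
          class = "sarcotex_invalid_parameter")
  }
  if (duty <= 0 || duty >= 1) abort("`duty` must be in (0, 1).",
                                    class = "sarcotex_invalid_parameter")
  if (coverage <= 0 || coverage > 1) abort("`coverage` must be in (0, 1].",
                                           class = "sarcotex_invalid_parameter")
  orientation_deg <- orientation_deg %% 180

  nr <- shape[1]; nc <- shape[2]
  th <- orientation_deg * pi / 180
  R <- matrix(rep(0:(nr - 1), nc), nr, nc)
  C <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  # periodic coordinate (y up): s increases along the periodicity axis
  s <- C * cos(th) - R * sin(th)
  # transverse coordinate, along the visible bands
  q <- R * cos(th) + C * sin(th)

  gen <- function() {
    if (jitter_sd > 0) {
      band <- floor(q / band_width_px)
      bidx <- band - min(band) + 1L
      offs <- rnorm(max(bidx), sd = jitter_sd)
      s <- s + offs[bidx]
    }
    frac <- s %% period_px
    img <- if (profile == "rect") {
      ifelse(frac < duty * period_px, hi, lo)
    } else {
      lo + (hi - lo) * 0.5 * (1 + cos(2 * pi * s / period_px))
    }
    if (coverage < 1) {
      s0 <- C * cos(th) - R * sin(th)   # coverage is in unjittered coordinates
      covered <- (s0 - min(s0)) <= coverage * (max(s0) - min(s0))
      img[!covered] <- lo
    }
    if (smooth_sigma > 0) {
      img <- as.matrix(EBImage::gblur(img, sigma = smooth_sigma))
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
    pmin(pmax(img, 0), 1)
  }
  img <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  structure(
    list(image = img, period_px = period_px, orientation_deg = orientation_deg,
         duty = duty, noise_sd = noise_sd, coverage = coverage,
         jitter_sd = jitter_sd, band_width_px = band_width_px,
         profile = profile, hi = hi, lo = lo, smooth_sigma = smooth_sigma,
         seed = seed),
    class = "stripe_phantom"
  )
}

#' @export
print.stripe_phantom <- function(x, ...) {
  cat(sprintf(
    "<stripe_phantom> %d x %d | period %.3g px @ %.1f deg | duty %.2f | noise %.2g | coverage %.2g | jitter %.2g\n",
    nrow(x$image), ncol(x$image), x$period_px, x$orientation_deg, x$duty,
    x$noise_sd, x$coverage, x$jitter_sd))
  invisible(x)
}

#' The six canonical stripe-phantom panels
#'
#' A fixed panel of idealized striation images used throughout the tests and
#' vignette: plain horizontal bands, the same bands rotated 45 degrees, bands
#' of a longer period, bands with additive noise, bands covering only one
#' third of the image, and bands with random per-column phase offsets.
#'
#' @param shape image size (rows, cols).
#' @param seed seed for the stochastic panels.
#' @return Named list of [make_stripes()] phantoms:
#'   `plain`, `rotated`, `long_period`, `noisy`, `partial`, `jittered`.
#' @export
make_stripe_panels <- function(shape = c(128, 128), seed = 1L) {
  list(
    plain       = make_stripes(shape, 8,  90),
    rotated     = make_stripes(shape, 8,  45),
    long_period = make_stripes(shape, 16, 90),
    noisy       = make_stripes(shape, 8,  90, noise_sd = 0.2, seed = seed),
    partial     = make_stripes(shape, 8,  90, coverage = 1 / 3),
    jittered    = make_stripes(shape, 8,  90, jitter_sd = 2, seed = seed + 1L)
  )
}

#' Labeled phantom set for metric discrimination benchmarks
#'
#' Builds two groups of single-cell-like textures: "organized" phantoms with
#' coherent striations (sarcomere-like periods of 10-16 px, random
#' orientation, mild noise) and "disorganized" phantoms of spatially smoothed
#' noise with matched intensity statistics. Staining variability is emulated
#' by a random per-image gain and offset applied to both groups, so metrics
#' that are not normalized to image contrast are penalized exactly as they
#' would be on real stains.
#'
#' @param n_per_group phantoms per group.
#' @param shape image size.
#' @param seed seed controlling the whole set.
#' @return Tibble with columns `id`, `group` ("organized"/"disorganized"),
#'   `image` (list of matrices), `period_px`, `orientation_deg` (NA for
#'   disorganized), and `mask` (list of logical matrices; here the full frame).
#' @export
make_discrimination_set <- function(n_per_group = 20, shape = c(128, 128),
                                    seed = 1L) {
  withr::with_seed(seed, {
    n <- n_per_group
    rescale_stain <- function(img, gain, offs) pmin(pmax(img * gain + offs, 0), 1)
    org <- purrr::map(seq_len(n), function(i) {
      per <- runif(1, 10, 16)
      ang <- runif(1, 0, 180)
      ph <- make_stripes(shape, per, ang, noise_sd = runif(1, 0.02, 0.08),
                         jitter_sd = runif(1, 0, 0.6),
                         seed = sample.int(1e6, 1))
      list(image = rescale_stain(ph$image, runif(1, 0.55, 1), runif(1, 0, 0.12)),
           period = per, ang = ang)
    })
    dis <- purrr::map(seq_len(n), function(i) {
      raw <- matrix(runif(prod(shape)), shape[1], shape[2])
      img <- as.matrix(EBImage::gblur(raw, sigma = runif(1, 1.5, 3)))
      img <- (img - min(img)) / diff(range(img)) * 0.7 + 0.15
      list(image = rescale_stain(img, runif(1, 0.55, 1), runif(1, 0, 0.12)),
           period = NA_real_, ang = NA_real_)
    })
    full_mask <- matrix(TRUE, shape[1], shape[2])
    tibble::tibble(
      id = seq_len(2 * n),
      group = rep(c("organized", "disorganized"), each = n),
      image = c(purrr::map(org, "image"), purrr::map(dis, "image")),
      period_px = c(purrr::map_dbl(org, "period"), purrr::map_dbl(dis, "period")),
      orientation_deg = c(purrr::map_dbl(org, "ang"), purrr::map_dbl(dis, "ang")),
      mask = rep(list(full_mask), 2 * n)
    )
  })
}

# ---- multi-channel cell fields -----------------------------------------------

default_subtype_table <- function() {
  tibble::tibble(
    actinin    = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    hcn4       = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    nppa       = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    binucleate = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

# raster of a perturbed ellipse: radial harmonics on top of the ellipse radius
rasterize_cell <- function(shape, cr, cc, a, b, phi_deg, wob_amp, wob_ph) {
  nr <- shape[1]; nc <- shape[2]
  phi <- phi_deg * pi / 180
  R <- matrix(rep(seq_len(nr) - 1, nc), nr, nc) - cr
  C <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) - cc
  # rotate into the ellipse frame (y up convention)
  x <-  C * cos(phi) - R * sin(phi)
  y <- -R * cos(phi) - C * sin(phi)
  ang <- atan2(y, x)
  r_ell <- (a * b) / sqrt((b * cos(ang))^2 + (a * sin(ang))^2)
  r_ell <- r_ell * (1 + wob_amp[1] * sin(3 * ang + wob_ph[1]) +
                        wob_amp[2] * sin(5 * ang + wob_ph[2]))
  sqrt(x^2 + y^2) <= r_ell
}

gaussian_blob <- function(shape, cr, cc, sigma, peak = 0.9) {
  nr <- shape[1]; nc <- shape[2]
  R <- matrix(rep(seq_len(nr) - 1, nc), nr, nc) - cr
  C <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) - cc
  peak * exp(-(R^2 + C^2) / (2 * sigma^2))
}

#' Synthetic multi-channel cell field with exhaustive ground truth
#'
#' Lays out non-overlapping cells (randomized perturbed ellipses) on a dark
#' background and renders the four pipeline channels from a per-cell marker
#' table: DAPI nucleus blobs (one or two per cell), striated alpha-actinin
#' texture of known period and orientation, diffuse Hcn4-GFP fill, and a
#' perinuclear Nppa annulus. The returned truth table is the complete
#' generating record, so segmentation and classification can be scored
#' exactly.
#'
#' @param n_cells number of cells; ignored if `subtype_table` is given.
#' @param subtype_table tibble with logical columns `actinin`, `hcn4`, `nppa`
#'   and optionally `binucleate`; one row per cell. Defaults to a fixed
#'   10-cell mix covering the subtype combinations.
#' @param shape image size (rows, cols).
#' @param pixel_size_um physical pixel size.
#' @param period_px sarcomere-stripe period for actinin-positive cells.
#' @param noise_sd background noise added to every channel.
#' @param dapi_bleed fraction of the Nppa and Hcn4 channels added into DAPI,
#'   emulating spectral bleed-through (0 disables).
#' @param seed integer seed; the field is reproducible bit-for-bit.
#' @return List with `stack` (a [channel_stack()]) and `truth`, a tibble with
#'   one row per cell: centroid, ellipse axes and orientation, subtype flags,
#'   nucleus centers (list-col), stripe period/orientation, and the exact
#'   cell mask (list-col of logical matrices).
#' @export
make_cell_field <- function(n_cells = 10, subtype_table = NULL,
                            shape = c(512, 512),
                            pixel_size_um = SARCOTEX_PIXEL_SIZE_UM,
                            period_px = 12.8, noise_sd = 0.005,
                            dapi_bleed = 0, seed = 1L) {
  if (is.null(subtype_table)) {
    subtype_table <- default_subtype_table()
    if (n_cells != nrow(subtype_table)) {
      subtype_table <- subtype_table[rep_len(seq_len(nrow(subtype_table)), n_cells), ]
    }
  }
  n_cells <- nrow(subtype_table)
  if (!all(c("actinin", "hcn4", "nppa") %in% names(subtype_table))) {
    abort("`subtype_table` needs logical columns actinin, hcn4, nppa.")
  }
  if (is.null(subtype_table$binucleate)) subtype_table$binucleate <- FALSE

  withr::with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    # rejection-sample non-overlapping cell centers
    cells <- list(); tries <- 0L
    while (length(cells) < n_cells) {
      tries <- tries + 1L
      if (tries > 400L * n_cells) {
        abort("could not place all cells without overlap; enlarge `shape` or reduce `n_cells`.",
              class = "sarcotex_placement_error")
      }
      a <- runif(1, 30, 42); b <- runif(1, 16, 26)
      margin <- a * 1.12 + 6
      cr <- runif(1, margin, nr - 1 - margin)
      cc <- runif(1, margin, nc - 1 - margin)
      ok <- all(vapply(cells, function(cl) {
        sqrt((cl$cr - cr)^2 + (cl$cc - cc)^2) > (cl$a + a) * 1.12 + 8
      }, logical(1)))
      if (ok) cells[[length(cells) + 1L]] <-
          list(cr = cr, cc = cc, a = a, b = b, phi = runif(1, 0, 180))
    }

    dapi <- matrix(0, nr, nc); actinin <- matrix(0, nr, nc)
    hcn4 <- matrix(0, nr, nc); nppa <- matrix(0, nr, nc)
    truth <- vector("list", n_cells)

    for (i in seq_len(n_cells)) {
      cl <- cells[[i]]; fl <- subtype_table[i, ]
      mask <- rasterize_cell(shape, cl$cr, cl$cc, cl$a, cl$b, cl$phi,
                             wob_amp = c(runif(1, 0.02, 0.06), runif(1, 0.01, 0.04)),
                             wob_ph = runif(2, 0, 2 * pi))
      stripe_ang <- runif(1, 0, 180)

      # nuclei: centers along the major axis; binucleates < 25 px apart
      phi <- cl$phi * pi / 180
      axis_rc <- c(-sin(phi), cos(phi))     # (drow, dcol) of the major axis
      offs <- if (fl$binucleate) c(-11, 11) else 0   # 22 px apart: joined, not merged
      ncenters <- lapply(offs, function(o) c(cl$cr + o * axis_rc[1],
                                             cl$cc + o * axis_rc[2]))
      nuc_mask <- matrix(FALSE, nr, nc)
      for (cn in ncenters) {
        dapi <- pmax(dapi, gaussian_blob(shape, cn[1], cn[2], sigma = 4.5))
        nuc_mask <- nuc_mask | (gaussian_blob(shape, cn[1], cn[2], sigma = 4.5) > 0.3)
      }

      if (fl$actinin) {
        th <- stripe_ang * pi / 180
        Rm <- matrix(rep(0:(nr - 1), nc), nr, nc)
        Cm <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
        sline <- Cm * cos(th) - Rm * sin(th)
        tex <- ifelse((sline %% period_px) < 0.5 * period_px, 0.85, 0.35)
        actinin[mask] <- pmax(actinin[mask], tex[mask])
      }
      if (fl$hcn4) hcn4[mask] <- pmax(hcn4[mask], 0.7)
      if (fl$nppa) {
        ring <- EBImage::dilate(nuc_mask, EBImage::makeBrush(17, "disc")) & !nuc_mask
        nppa[ring & mask] <- 0.5
      }

      truth[[i]] <- tibble::tibble(
        cell_id = i, centroid_r = cl$cr, centroid_c = cl$cc,
        semi_major_px = cl$a, semi_minor_px = cl$b, major_axis_deg = cl$phi,
        actinin = fl$actinin, hcn4 = fl$hcn4, nppa = fl$nppa,
        n_nuclei = length(offs),
        nucleus_centers = list(do.call(rbind, ncenters)),
        stripe_period_px = if (fl$actinin) period_px else NA_real_,
        stripe_orientation_deg = if (fl$actinin) stripe_ang else NA_real_,
        mask = list(mask)
      )
    }

    if (dapi_bleed > 0) dapi <- dapi + dapi_bleed * pmax(nppa, hcn4)
    addnoise <- function(x) pmin(pmax(x + 0.02 + rnorm(length(x), sd = noise_sd), 0), 1)
    stack <- channel_stack(
      list(dapi = addnoise(dapi), actinin = addnoise(actinin),
           hcn4 = addnoise(hcn4), nppa = addnoise(nppa)),
      pixel_size_um = pixel_size_um
    )
    list(stack = stack, truth = dplyr::bind_rows(truth))
  })
}
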