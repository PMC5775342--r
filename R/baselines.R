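#' Fit a periodic + aperiodic decomposition to a 1-D profile
#'
#' Used by the Gabor and Fourier comparator scores: a response profile is
#' modelled as an aperiodic background (quadratic, or the sum of two
#' exponentials) plus one Gaussian bump representing the periodic component.
#' Fitted by trust-region least squares with three starts over the Gaussian
#' center; the best-residual convergent fit wins.
#'
#' @param x,y profile support (strictly positive) and values.
#' @param aperiodic `"quadratic"` (`a x^2 + b x + c`) or `"biexponential"`
#'   (`a1 exp(-x/t1) + a2 exp(-x/t2)`).
#' @return List of class `periodic_fit`: `gaussian` (amplitude, center,
#'   width), `aperiodic` (named coefficients), `se_amplitude`, `resid_norm`,
#'   `converged`.
#' @export
fit_periodic_profile <- function(x, y, aperiodic = c("quadratic", "biexponential")) {
  aperiodic <- match.arg(aperiodic)
  stopifnot(length(x) == length(y), all(x > 0))
  rng <- range(x); span <- diff(rng)
  base <- list(converged = FALSE, gaussian = c(amplitude = 0, center = NA, width = NA),
               aperiodic = NULL, se_amplitude = NA_real_, resid_norm = sqrt(sum(y^2)))
  if (sd(y) < 1e-12) return(structure(base, class = "periodic_fit"))

  # fit on a unit-normalized profile for numerical stability; the Gaussian
  # amplitude is rescaled afterwards
  yscale <- max(abs(y))
  dat <- data.frame(x = x, y = y / yscale)
  y <- y / yscale
  mid <- x >= rng[1] + 0.15 * span
  centers <- unique(c(rng[1] + c(0.25, 0.5, 0.75) * span, x[which.max(y)],
                      x[mid][which.max(y[mid])]))
  fits <- list()
  for (ctr in centers) {
    fml <- if (aperiodic == "quadratic") {
      y ~ a * x^2 + b * x + c0 + A * exp(-((x - m)^2) / (2 * s^2))
    } else {
      y ~ a1 * exp(-x / t1) + a2 * exp(-x / t2) + A * exp(-((x - m)^2) / (2 * s^2))
    }
    start <- if (aperiodic == "quadratic") {
      list(a = 0, b = 0, c0 = mean(y), A = max(max(y) - mean(y), 1e-6),
           m = ctr, s = span / 8)
    } else {
      list(a1 = max(mean(y), 1e-6), t1 = span / 5, a2 = max(mean(y) / 4, 1e-6),
           t2 = span, A = max(max(y) - mean(y), 1e-6), m = ctr, s = span / 8)
    }
    # unbounded Levenberg-Marquardt (box constraints make nlsLM's initial
    # Jacobian singular on these profiles); a negative fitted amplitude is
    # reported as zero periodic component instead
    ft <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(ft) && !is.finite(sum(coef(ft)))) ft <- NULL
    if (!is.null(ft)) fits[[length(fits) + 1L]] <- ft
  }
  if (!length(fits)) return(structure(base, class = "periodic_fit"))
  rn <- vapply(fits, function(f) sqrt(sum(residuals(f)^2)), numeric(1))
  ft <- fits[[which.min(rn)]]
  cf <- coef(ft)
  se <- tryCatch(summary(ft)$coefficients["A", "Std. Error"],
                 error = function(e) NA_real_)
  ap <- cf[setdiff(names(cf), c("A", "m", "s"))]
  ap[!grepl("^t", names(ap)) & names(ap) != "m"] <- ap[!grepl("^t", names(ap)) & names(ap) != "m"] * yscale
  # identifiability guard: a "bump" wider than half the support or centered
  # outside it is part of the aperiodic background, not a periodic component
  amp <- max(unname(cf["A"]), 0)
  if (abs(cf[["s"]]) > span / 2 || cf[["m"]] < rng[1] - abs(cf[["s"]]) ||
      cf[["m"]] > rng[2] + abs(cf[["s"]])) amp <- 0
  structure(list(
    converged = TRUE,
    gaussian = c(amplitude = amp * yscale,
                 center = unname(cf["m"]), width = abs(unname(cf["s"]))),
    aperiodic = ap, se_amplitude = se * yscale, resid_norm = min(rn) * yscale
  ), class = "periodic_fit")
}

#' @export
print.periodic_fit <- function(x, ...) {
  cat(sprintf("<periodic_fit> converged=%s | gaussian A=%.4g at %.4g (width %.4g) | resid %.4g\n",
              x$converged, x$gaussian["amplitude"], x$gaussian["center"],
              x$gaussian["width"], x$resid_norm))
  invisible(x)
}

# complex Gabor kernel; sigma tied to wavelength at one-octave bandwidth
gabor_kernel <- function(wavelength, orientation_deg, max_radius = Inf) {
  sigma <- 0.5622 * wavelength
  rad <- min(ceiling(3 * sigma), max_radius)
  g <- seq(-rad, rad)
  X <- outer(rep(1, length(g)), g)     # column offsets
  Y <- outer(-g, rep(1, length(g)))    # y up
  th <- orientation_deg * pi / 180
  xp <- X * cos(th) + Y * sin(th)
  yp <- -X * sin(th) + Y * cos(th)
  env <- exp(-(xp^2 + yp^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * xp / wavelength)
  re <- re - env * sum(re) / sum(env)   # zero-DC even kernel
  # unit-energy normalization keeps responses comparable across wavelengths
  im <- env * sin(2 * pi * xp / wavelength)
  nrm <- sqrt(sum(re^2) + sum(im^2))
  list(re = re / nrm, im = im / nrm)
}

#' Gabor-filter periodic-component score
#'
#' A bank of Gabor filters is applied over a grid of wavelengths and
#' orientations; per orientation, the in-mask mean response magnitude
#' (response normalized to cell area) is plotted against wavelength and fit
#' to a quadratic plus a Gaussian, separating the aperiodic background from
#' the periodic component. The score is the maximum fitted Gaussian
#' amplitude over orientations.
#'
#' @param image numeric matrix.
#' @param mask logical matrix or `NULL` for the full frame.
#' @param wavelengths wavelength grid in pixels (>= 6 values spanning the
#'   plausible striation periods).
#' @param orientations orientation grid in degrees.
#' @param details return the per-orientation fits alongside the score.
#' @return The score (numeric), or with `details = TRUE` a list
#'   `(score, best_orientation, fits)`.
#' @export
gabor_score <- function(image, mask = NULL,
                        wavelengths = exp(seq(log(4), log(32), length.out = 10)),
                        orientations = seq(0, 180 - 11.25, by = 11.25),
                        details = FALSE) {
  stopifnot(length(wavelengths) >= 6, length(orientations) >= 8)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  area <- sum(mask)
  max_rad <- floor((min(dim(image)) - 2) / 2)

  fits <- purrr::map(orientations, function(ori) {
    prof <- vapply(wavelengths, function(wl) {
      k <- gabor_kernel(wl, ori, max_radius = max_rad)
      re <- as.matrix(EBImage::filter2(image, k$re))
      im <- as.matrix(EBImage::filter2(image, k$im))
      sum(sqrt(re^2 + im^2)[mask]) / area
    }, numeric(1))
    fit_periodic_profile(wavelengths, prof, "quadratic")
  })
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) {
    warn("no Gabor profile fit converged; score 0.")
    score <- 0; best <- NA_real_
  } else {
    amps <- vapply(fits, function(f) if (f$converged) f$gaussian["amplitude"] else -Inf,
                   numeric(1))
    score <- max(amps); best <- orientations[which.max(amps)]
  }
  if (details) list(score = score, best_orientation = best, fits = fits)
  else score
}

#' Fourier radial-profile score
#'
#' The 2-D FFT of the cell's bounding-box image (raw intensities; this is
#' the method's known weakness — the box carries cell-shape artifacts) is
#' radially integrated over 360 one-degree angular sectors into a frequency
#' profile, which is fit to two exponentials plus a Gaussian. The score is
#' the area under the fitted Gaussian.
#'
#' @param image numeric matrix (e.g. the alpha-actinin channel).
#' @param mask logical matrix whose bounding box is analyzed; `NULL` uses
#'   the whole image.
#' @param spectrum `"magnitude"` (default) or `"power"`.
#' @param details return the fit object alongside the score.
#' @return The score, or with `details = TRUE` a list
#'   `(score, fit, profile)`.
#' @export
fourier_score <- function(image, mask = NULL,
                          spectrum = c("magnitude", "power"),
                          details = FALSE) {
  spectrum <- match.arg(spectrum)
  if (!is.null(mask)) {
    rc <- which(mask, arr.ind = TRUE)
    image <- image[min(rc[, 1]):max(rc[, 1]), min(rc[, 2]):max(rc[, 2])]
  }
  if (any(dim(image) < 32)) {
    abort("bounding box must be at least 32 x 32 pixels.",
          class = "sarcotex_invalid_input")
  }
  nr <- nrow(image); nc <- ncol(image)
  F <- fft(image - mean(image))
  mag <- Mod(F)
  if (spectrum == "power") mag <- mag^2

  # frequency (cycles/px) of every FFT sample
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  fmat <- sqrt(outer(fr^2, fc^2, "+"))
  sector <- atan2(outer(fr, rep(1, nc)), outer(rep(1, nr), fc))  # kept for sector semantics

  step <- 1 / max(nr, nc)                 # one frequency sample
  bins <- pmin(floor(fmat / step) + 1L, ceiling(0.5 * sqrt(2) / step))
  keep <- fmat > 0 & fmat <= 0.5          # up to the axis Nyquist
  # annulus totals normalized by the number of samples per annulus, so the
  # aperiodic background is not dominated by the multiplicity growth ~ f
  prof <- tapply(mag[keep], bins[keep], mean)
  nsamp <- tapply(mag[keep], bins[keep], length)
  prof <- prof[nsamp >= 8]          # drop annuli too small to average
  x <- (as.integer(names(prof)) - 0.5) * step
  y <- as.numeric(prof)

  fit <- fit_periodic_profile(x, y, "biexponential")
  score <- if (fit$converged) {
    unname(fit$gaussian["amplitude"] * abs(fit$gaussian["width"]) * sqrt(2 * pi))
  } else {
    warn("Fourier profile fit did not converge; score 0.")
    0
  }
  if (details) list(score = score, fit = fit,
                    profile = tibble::tibble(frequency = x, value = y))
  else score
}

#' Head-to-head benchmark of sarcomere-organization metrics
#'
#' Computes, for every image of a labeled fixture set (see
#' [make_discrimination_set()]), the organization score of the four
#' Haralick-surface variants (correlation, contrast, uniformity,
#' homogeneity), the Gabor score, and the Fourier score, then summarizes each
#' metric's ability to separate the groups with a two-sample t-test.
#'
#' @param fixture tibble with `image`, `mask`, `group` columns.
#' @param angles,offsets,levels surface parameters.
#' @return List with `scores` (per-image tibble) and `summary` (per-metric
#'   tibble: group means, SDs, `p_value`, `neglog10_p`).
#' @export
compare_organization_metrics <- function(fixture,
                                         angles = seq(0, 176, by = 4),
                                         offsets = 1:40, levels = 8) {
  feats <- c("correlation", "contrast", "uniformity", "homogeneity")
  rows <- purrr::map(seq_len(nrow(fixture)), function(i) {
    img <- fixture$image[[i]]; msk <- fixture$mask[[i]]
    surfs <- haralick_surface(img, msk, feats, angles, offsets, levels)
    orgs <- vapply(surfs, function(s)
      extract_sarcomere_metrics(s, organization_threshold = -Inf)$organization,
      numeric(1))
    tibble::tibble(
      id = fixture$id[i], group = fixture$group[i],
      sota_correlation = orgs[["correlation"]],
      sota_contrast = orgs[["contrast"]],
      sota_uniformity = orgs[["uniformity"]],
      sota_homogeneity = orgs[["homogeneity"]],
      gabor = gabor_score(img, msk),
      fourier = fourier_score(img, msk)
    )
  })
  scores <- dplyr::bind_rows(rows)
  metrics <- setdiff(names(scores), c("id", "group"))
  summary <- dplyr::bind_rows(purrr::map(metrics, function(mn) {
    a <- scores[[mn]][scores$group == "organized"]
    b <- scores[[mn]][scores$group == "disorganized"]
    tt <- t.test(a, b)
    tibble::tibble(metric = mn, mean_organized = mean(a), sd_organized = sd(a),
                   mean_disorganized = mean(b), sd_disorganized = sd(b),
                   p_value = tt$p.value, neglog10_p = -log10(tt$p.value))
  }))
  list(scores = scores, summary = summary)
}
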