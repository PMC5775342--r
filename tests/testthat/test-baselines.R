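test_that("periodic+aperiodic fit recovers a planted Gaussian", {
  x <- seq(1, 40, by = 0.5)
  y <- 0.002 * x^2 - 0.1 * x + 3 + 1.6 * exp(-((x - 14)^2) / (2 * 2.5^2))
  ft <- fit_periodic_profile(x, y, "quadratic")
  expect_true(ft$converged)
  expect_lt(abs(ft$gaussian["amplitude"] - 1.6), 0.05)
  expect_lt(abs(ft$gaussian["center"] - 14), 0.2)
  td <- tidy(ft)
  expect_true(all(c("gaussian_amplitude", "gaussian_center") %in% td$term))
  expect_equal(glance(ft)$converged, TRUE)

  y2 <- 5 * exp(-x / 3) + 2 * exp(-x / 20) + 0.9 * exp(-((x - 22)^2) / (2 * 3^2))
  ft2 <- fit_periodic_profile(x, y2, "biexponential")
  expect_true(ft2$converged)
  expect_lt(abs(ft2$gaussian["amplitude"] - 0.9), 0.1)
  expect_lt(abs(ft2$gaussian["center"] - 22), 0.5)
  # flat profile: no periodic component
  expect_equal(unname(fit_periodic_profile(x, rep(1, length(x)))$gaussian["amplitude"]), 0)
})

test_that("Gabor score finds the stripe wavelength and vanishes on flat images", {
  ph <- make_stripes(c(128, 128), 12.8, 30, noise_sd = 0.05, seed = 3)
  gs <- gabor_score(ph$image, details = TRUE)
  expect_gt(gs$score, 0)
  amps <- vapply(gs$fits, function(f) unname(f$gaussian["amplitude"]), numeric(1))
  best <- gs$fits[[which.max(amps)]]
  expect_lt(abs(best$gaussian["center"] - 12.8) / 12.8, 0.2)
  # best orientation within one grid step of the stripe direction
  expect_lte(min(abs(gs$best_orientation - 30), 180 - abs(gs$best_orientation - 30)),
             11.25)
  expect_equal(suppressWarnings(gabor_score(matrix(0.5, 128, 128))), 0)
})

test_that("Fourier score centers on the stripe frequency; white noise is statistically zero", {
  ph <- make_stripes(c(128, 128), 12.8, 30, noise_sd = 0.05, seed = 3)
  fs <- fourier_score(ph$image, details = TRUE)
  expect_gt(fs$score, 0)
  expect_lt(abs(fs$fit$gaussian["center"] - 1 / 12.8) / (1 / 12.8), 0.15)

  set.seed(1)
  fn <- fourier_score(matrix(runif(128 * 128), 128, 128), details = TRUE)
  expect_lt(abs(fn$score), 3 * fn$fit$se_amplitude)

  expect_error(fourier_score(matrix(0.5, 20, 20)),
               class = "sarcotex_invalid_input")
})

test_that("both comparator scores rise monotonically with stripe contrast", {
  contrasts <- c(0.55, 0.7, 0.85)
  g <- f <- numeric(3)
  for (k in seq_along(contrasts)) {
    hi <- contrasts[k]
    ph <- make_stripes(c(128, 128), 12.8, 30, hi = hi, lo = 1 - hi,
                       noise_sd = 0.03, seed = 4)
    g[k] <- gabor_score(ph$image)
    f[k] <- fourier_score(ph$image)
  }
  expect_true(all(diff(g) > 0))
  expect_true(all(diff(f) > 0))
  expect_true(all(g >= 0) && all(f >= 0))
})

test_that("bounding-box Fourier is sensitive to mask shape while masked SOTA is not", {
  ph <- make_stripes(c(128, 128), 12.8, 30, noise_sd = 0.05, seed = 3)
  mask_rect <- matrix(FALSE, 128, 128); mask_rect[10:119, 10:119] <- TRUE
  mask_irr <- mask_rect
  mask_irr[outer(1:128, 1:128, function(r, c) (r - 10)^2 + (c - 119)^2 < 55^2)] <- FALSE
  mask_irr[outer(1:128, 1:128, function(r, c) (r - 119)^2 + (c - 10)^2 < 45^2)] <- FALSE

  f1 <- fourier_score(ph$image, mask_rect)
  # same bounding box, but the irregular mask zeroes part of the image content
  img_irr <- ph$image; img_irr[!mask_irr] <- 0
  f2 <- fourier_score(img_irr, mask_rect)
  s1 <- sota_metrics(ph$image, mask_rect, pixel_size_um = 1)$organization
  s2 <- sota_metrics(ph$image, mask_irr, pixel_size_um = 1)$organization

  rel_f <- abs(f1 - f2) / max(f1, f2)
  rel_s <- abs(s1 - s2) / max(s1, s2)
  expect_gt(rel_f, rel_s)     # box metric moves more than the masked metric
  expect_lt(rel_s, 0.1)
})

test_that("organized phantoms outscore disorganized ones on the comparator metrics", {
  fx <- make_discrimination_set(n_per_group = 4, shape = c(96, 96), seed = 2)
  g <- vapply(seq_len(nrow(fx)), function(i)
    gabor_score(fx$image[[i]], fx$mask[[i]]), numeric(1))
  expect_gt(mean(g[fx$group == "organized"]), mean(g[fx$group == "disorganized"]))
})
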