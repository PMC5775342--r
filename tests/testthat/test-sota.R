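test_that("peak prominences match hand-computed values", {
  # peaks at 3 and 5; the trace end truncates the right base of the global
  # max (standard topographic convention), so both prominences are 1
  y <- c(1, 3, 2, 5, 4)
  pk <- find_peaks(y)
  expect_equal(pk$x, c(2, 4))
  expect_equal(pk$prominence, c(1, 1))
  # with the right base extended to a deep valley the global max gets its
  # full height above the higher base
  y1 <- c(1, 3, 2, 5, 0, 0.5)
  expect_equal(find_peaks(y1)$prominence, c(1, 4))
  # decaying sinusoid: every interior peak's prominence is its swing
  x <- seq(0, 6 * pi, length.out = 400)
  y2 <- exp(-x / 10) * cos(x)
  pk2 <- find_peaks(y2, x)
  expect_equal(nrow(pk2), 3)
  expect_true(all(diff(pk2$prominence) < 0))   # decaying swings
  # no local maxima on a monotone trace
  expect_equal(nrow(find_peaks(seq(1, 0, length.out = 50))), 0)
})

test_that("correlation trace of striped texture peaks at multiples of the period", {
  ph <- make_stripes(c(128, 128), 8, 90)
  s <- haralick_surface(ph$image)
  tr <- s$values[which(s$angles == 88), ]   # nearest grid angle to the axis
  pk <- find_peaks(tr, s$offsets)
  expect_true(all(abs(pk$x[1:3] - c(8, 16, 24)) <= 1))
})

test_that("period is recovered as sarcomere length within half a pixel", {
  for (p in c(6, 8, 12.8, 16)) {
    ph <- make_stripes(c(128, 128), p, 90)
    m <- sota_metrics(ph$image, pixel_size_um = 1)
    expect_lt(abs(m$length_px - p), 0.5)
    expect_true(m$length_is_first_peak)
  }
})

test_that("direction tracks the generator orientation within one grid step", {
  angs <- c(0, 30, 45, 60, 90, 135)
  orgs <- numeric(length(angs))
  for (i in seq_along(angs)) {
    ph <- make_stripes(c(128, 128), 8, angs[i], jitter_sd = 1.5, seed = 7)
    m <- sota_metrics(ph$image, pixel_size_um = 1)
    delta <- abs(m$direction_deg - angs[i])
    expect_lte(min(delta, 180 - delta), 4, label = sprintf("angle %d", angs[i]))
    orgs[i] <- m$organization
  }
  expect_lt(diff(range(orgs)) / max(orgs), 0.15)  # organization stable under rotation
})

test_that("organization degrades monotonically with noise and with reduced coverage", {
  noise_orgs <- vapply(c(0, 0.1, 0.2, 0.4), function(ns) {
    ph <- make_stripes(c(128, 128), 8, 90, noise_sd = ns, seed = 5)
    sota_metrics(ph$image, pixel_size_um = 1)$organization
  }, numeric(1))
  expect_true(all(diff(noise_orgs) < 0))

  cov_orgs <- vapply(c(1, 2 / 3, 1 / 3), function(cv) {
    ph <- make_stripes(c(128, 128), 8, 90, coverage = cv)
    sota_metrics(ph$image, pixel_size_um = 1)$organization
  }, numeric(1))
  expect_true(all(diff(cov_orgs) < 0))
})

test_that("pure noise stays under the organization threshold with outputs suppressed", {
  set.seed(2)
  noise <- matrix(runif(128 * 128), 128, 128)
  m <- sota_metrics(noise, pixel_size_um = 1)
  expect_lte(m$organization, 0.1)
  expect_true(is.na(m$length_um))
  expect_true(is.na(m$direction_deg))
  # monotone gradient image: no qualifying oscillation
  grad <- matrix(rep(seq(0, 1, length.out = 128), each = 128), 128, 128)
  mg <- sota_metrics(grad, pixel_size_um = 1)
  expect_lte(mg$organization, 0.1)
})

test_that("metrics are invariant to translating image and mask together", {
  ph <- make_stripes(c(160, 160), 12.8, 30, noise_sd = 0.05, seed = 9)
  mask <- matrix(FALSE, 160, 160); mask[20:110, 20:110] <- TRUE
  m1 <- sota_metrics(ph$image, mask, pixel_size_um = 1)
  sh <- 24
  img2 <- matrix(0, 160, 160); msk2 <- matrix(FALSE, 160, 160)
  img2[(20:110) + sh, (20:110) + sh] <- ph$image[20:110, 20:110]
  msk2[(20:110) + sh, (20:110) + sh] <- TRUE
  m2 <- sota_metrics(img2, msk2, pixel_size_um = 1)
  expect_equal(m1$organization, m2$organization)
  expect_equal(m1$length_px, m2$length_px)
  expect_equal(m1$direction_deg, m2$direction_deg)
})

test_that("length scales with pixel size and the threshold gates reporting", {
  ph <- make_stripes(c(128, 128), 12.8, 90)
  m <- sota_metrics(ph$image, pixel_size_um = 0.15625)
  expect_lt(abs(m$length_um - 2.0), 0.1)    # 12.8 px at 0.15625 um/px
  # raising the threshold above the score suppresses length/direction
  s <- haralick_surface(ph$image)
  m2 <- extract_sarcomere_metrics(s, organization_threshold = 10)
  expect_true(is.na(m2$length_um) && is.na(m2$direction_deg))
  expect_gt(m2$organization, 0)
})

test_that("misalignment folds axial angles into [0, 90]", {
  expect_equal(cell_sarcomere_misalignment(30, 30), 0)
  expect_equal(cell_sarcomere_misalignment(0, 90), 90)
  expect_equal(cell_sarcomere_misalignment(170, 10), 20)
  expect_equal(cell_sarcomere_misalignment(179, 1), 2)
  set.seed(1)
  a <- runif(50, 0, 180); b <- runif(50, 0, 180)
  mis <- cell_sarcomere_misalignment(a, b)
  expect_true(all(mis >= 0 & mis <= 90))
  expect_equal(cell_sarcomere_misalignment(a, b),
               cell_sarcomere_misalignment(b, a))
})

test_that("degenerate surface entries stay missing without poisoning the trace", {
  # mask so small that large offsets have too few pairs
  img <- matrix(runif(40 * 40), 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[5:35, 5:35] <- TRUE
  s <- haralick_surface(img, mask, offsets = 1:40)
  expect_true(anyNA(s$values))
  expect_false(all(is.na(s$values)))
  m <- extract_sarcomere_metrics(s, pixel_size_um = 1)
  expect_true(is.finite(m$organization))
})

test_that("tidy/glance/autoplot work on surfaces", {
  ph <- make_stripes(c(64, 64), 8, 90)
  s <- haralick_surface(ph$image, offsets = 1:20)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("angle_deg", "offset_px", "value", "feature"))
  gl <- glance(s, pixel_size_um = 1)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$organization, 0.1)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(plot_surface_traces(s), "ggplot")
})
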