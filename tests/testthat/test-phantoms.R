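test_that("horizontal stripe phantom is periodic in blocks of duty * period", {
  ph <- make_stripes(c(128, 128), 8, 90, smooth_sigma = 0)
  img <- ph$image
  # exactly two intensity levels, constant along every row
  expect_setequal(unique(as.vector(img)), c(ph$lo, ph$hi))
  expect_true(all(apply(img, 1, function(r) length(unique(r)) == 1)))
  col <- img[, 1]
  # vertical period of exactly 8 and bright runs of length 4
  expect_equal(col[1:120], col[9:128])
  runs <- rle(col > mean(col))
  expect_true(all(runs$lengths[2:(length(runs$lengths) - 1)] == 4))
  expect_gt(mean(img), 0); expect_lt(mean(img), 1)
})

test_that("generation is deterministic given a seed and rejects bad parameters", {
  a <- make_stripes(c(64, 64), 8, 45, noise_sd = 0.1, seed = 11)
  b <- make_stripes(c(64, 64), 8, 45, noise_sd = 0.1, seed = 11)
  expect_identical(a$image, b$image)
  expect_error(make_stripes(c(64, 64), 1.5, 0),
               class = "sarcotex_invalid_parameter")
  expect_error(make_stripes(c(16, 16), 8, 0),
               class = "sarcotex_invalid_parameter")
})

test_that("45-degree phantom equals the rotated 90-degree phantom away from borders", {
  ph90 <- make_stripes(c(128, 128), 8, 90)
  ph45 <- make_stripes(c(128, 128), 8, 45)
  rot <- as.matrix(EBImage::rotate(EBImage::Image(ph90$image), -45,
                                   output.dim = c(128, 128),
                                   bg.col = "white"))
  ctr <- 39:90   # central window, away from rotation borders
  d <- abs(rot[ctr, ctr] - ph45$image[ctr, ctr])
  # identical up to raster/interpolation error and an arbitrary phase shift:
  # compare against the best phase among small shifts
  best <- min(vapply(-4:4, function(s) {
    mean(abs(rot[ctr + s, ctr] - ph45$image[ctr, ctr]))
  }, numeric(1)))
  expect_lt(best, 0.05)
})

test_that("noise has the stated standard deviation after accounting for clipping", {
  ph0 <- make_stripes(c(128, 128), 8, 90)
  ph <- make_stripes(c(128, 128), 8, 90, noise_sd = 0.2, seed = 5)
  observed_sd <- sd(ph$image - ph0$image)
  # oracle: clip the same noiseless image with fresh noise draws
  set.seed(99)
  sims <- replicate(20, {
    noisy <- pmin(pmax(ph0$image + rnorm(length(ph0$image), sd = 0.2), 0), 1)
    sd(noisy - ph0$image)
  })
  expect_lt(abs(observed_sd - mean(sims)) / mean(sims), 0.1)
})

test_that("coverage restricts stripes to a contiguous fraction of the frame", {
  ph <- make_stripes(c(128, 128), 8, 90, coverage = 1 / 3, smooth_sigma = 0)
  col <- ph$image[, 1]
  striped <- which(col == ph$hi)
  # bright pixels confined to one contiguous third of the rows,
  # the rest of the column is flat background
  expect_lte(max(striped) - min(striped) + 1, ceiling(128 / 3) + 8)
  outside <- setdiff(1:128, (min(striped) - 4):(max(striped) + 4))
  expect_true(all(col[outside] == ph$lo))
})

test_that("cell-field channels carry signal only where the flags say", {
  fl <- tibble::tibble(actinin = c(TRUE, FALSE), hcn4 = c(FALSE, FALSE),
                       nppa = c(FALSE, FALSE))
  f <- quiet_field(subtype_table = fl, shape = c(256, 256), noise_sd = 0, seed = 3)
  m1 <- f$truth$mask[[1]]; m2 <- f$truth$mask[[2]]
  act <- f$stack$channels$actinin
  expect_gt(mean(act[m1]), 0.3)          # textured inside the actinin cell
  expect_lt(max(act[m2]), 0.1)           # background inside the negative cell
  expect_lt(max(f$stack$channels$hcn4), 0.1)
  expect_lt(max(f$stack$channels$nppa), 0.1)
  # one DAPI blob per nucleus, Otsu-separable
  nuc <- detect_nuclei(f$stack$channels$dapi)
  expect_equal(max(nuc), sum(f$truth$n_nuclei))
})

test_that("all-positive cell renders signal in all three marker channels", {
  fl <- tibble::tibble(actinin = TRUE, hcn4 = TRUE, nppa = TRUE)
  f <- quiet_field(subtype_table = fl, shape = c(224, 224), noise_sd = 0, seed = 4)
  m <- f$truth$mask[[1]]
  expect_gt(mean(f$stack$channels$actinin[m]), 0.3)
  expect_gt(mean(f$stack$channels$hcn4[m]), 0.3)
  expect_gt(max(f$stack$channels$nppa[m]), 0.3)
})

test_that("binucleate cells place nucleus centers under 25 px apart and fields regenerate bit-identically", {
  f1 <- quiet_field(seed = 8)
  f2 <- quiet_field(seed = 8)
  expect_identical(f1$stack$channels, f2$stack$channels)
  bin <- f1$truth[f1$truth$n_nuclei == 2, ]
  for (k in seq_len(nrow(bin))) {
    ctrs <- bin$nucleus_centers[[k]]
    expect_lt(sqrt(sum((ctrs[1, ] - ctrs[2, ])^2)), 25)
  }
  # nuclei lie inside their cell boundary
  for (k in seq_len(nrow(f1$truth))) {
    ctrs <- f1$truth$nucleus_centers[[k]]
    msk <- f1$truth$mask[[k]]
    for (j in seq_len(nrow(ctrs))) {
      expect_true(msk[round(ctrs[j, 1]) + 1, round(ctrs[j, 2]) + 1])
    }
  }
})

test_that("impossible placements raise a placement error", {
  fl <- tibble::tibble(actinin = rep(TRUE, 12), hcn4 = FALSE, nppa = FALSE)
  expect_error(quiet_field(subtype_table = fl, shape = c(160, 160), seed = 1),
               class = "sarcotex_placement_error")
})
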