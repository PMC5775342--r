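test_that("bleed-through correction zeroes marker-dominated pixels only", {
  dapi <- matrix(c(0.9, 0.3, 0.02, 0.5), 2, 2)
  ref  <- matrix(c(0.1, 0.3, 0.50, 0.0), 2, 2)
  out <- correct_dapi_bleedthrough(dapi, nppa = ref)
  expect_equal(out[1, 1], 0.9)    # bright nucleus over dark marker: kept
  expect_equal(out[2, 1], 0.3)    # ratio 1: kept
  expect_equal(out[1, 2], 0)      # marker >> dapi: bleed-through, zeroed
  expect_equal(out[2, 2], 0.5)    # zero reference: kept
  expect_message(correct_dapi_bleedthrough(dapi), "skipped")
  expect_equal(suppressMessages(correct_dapi_bleedthrough(dapi)), dapi)
})

test_that("nucleus detection finds each blob once and applies the size filter", {
  set.seed(1)
  img <- matrix(0.02, 200, 200)
  centers <- cbind(c(40, 40, 120, 160, 100), c(40, 150, 60, 170, 120))
  for (k in 1:5) {
    rr <- outer(1:200, 1:200, function(r, c)
      exp(-((r - centers[k, 1])^2 + (c - centers[k, 2])^2) / (2 * 4.5^2)))
    img <- pmax(img, 0.9 * rr)
  }
  lab <- detect_nuclei(img)
  expect_equal(max(lab), 5)
  expect_equal(sort(unique(as.vector(lab))), 0:5)

  expect_warning(detect_nuclei(matrix(0.5, 64, 64)), "no nuclei")
  # a blob smaller than min_area is removed
  tiny <- matrix(0.02, 64, 64); tiny[30:32, 30:32] <- 0.9
  expect_warning(lab2 <- detect_nuclei(tiny, min_area = 60), "min_area")
  expect_equal(max(lab2), 0)
})

test_that("marker classification follows the strict fully-within rule", {
  nuclei <- matrix(0L, 120, 120); nuclei[50:60, 50:60] <- 1L
  actinin <- matrix(0.02, 120, 120)
  actinin[30:90, 30:90] <- 0.8          # nucleus fully enclosed
  rec <- classify_nucleus_markers(nuclei, actinin, hcn4 = NULL)
  expect_equal(rec$marker_class, "actinin")

  # shift the foreground so one nucleus edge pokes out: strict rule declassifies
  act2 <- matrix(0.02, 120, 120); act2[52:90, 30:90] <- 0.8
  rec2 <- classify_nucleus_markers(nuclei, act2, hcn4 = NULL)
  expect_equal(rec2$marker_class, "none")
  # a relaxed coverage fraction restores it
  rec3 <- classify_nucleus_markers(nuclei, act2, hcn4 = NULL,
                                   coverage_frac = 0.5)
  expect_equal(rec3$marker_class, "actinin")

  # inside both foregrounds -> dual class
  hcn <- matrix(0.02, 120, 120); hcn[35:85, 35:85] <- 0.7
  rec4 <- classify_nucleus_markers(nuclei, actinin, hcn)
  expect_equal(rec4$marker_class, "actinin+hcn4")
})

test_that("classification is invariant to a global intensity rescaling", {
  f <- quiet_field(seed = 5)
  ch <- f$stack$channels
  nuc <- detect_nuclei(correct_dapi_bleedthrough(ch$dapi, ch$nppa, ch$hcn4))
  r1 <- classify_nucleus_markers(nuc, ch$actinin, ch$hcn4)
  r2 <- classify_nucleus_markers(nuc, ch$actinin * 0.5, ch$hcn4 * 0.5)
  expect_equal(r1$marker_class, r2$marker_class)
})

test_that("perinuclear Nppa scoring matches a direct percentile oracle", {
  nuclei <- matrix(0L, 80, 80); nuclei[35:45, 35:45] <- 1L
  ring_mask <- {
    sub <- nuclei == 1
    EBImage::dilate(sub, EBImage::makeBrush(17, "disc")) & !sub
  }
  # uniform ring intensity above threshold
  nppa <- matrix(0, 80, 80); nppa[ring_mask] <- 0.2
  expect_true(classify_nppa(nuclei, nppa)[["1"]])
  # all-zero ring
  expect_false(classify_nppa(nuclei, matrix(0, 80, 80))[["1"]])
  # sparse bright ring: decided by the interpolated 90th percentile
  set.seed(3)
  vals <- rep(0, sum(ring_mask)); vals[sample(length(vals), ceiling(0.05 * length(vals)))] <- 0.9
  nppa2 <- matrix(0, 80, 80); nppa2[ring_mask] <- vals
  oracle <- unname(quantile(vals, 0.9, type = 7)) > 0.1
  expect_equal(unname(classify_nppa(nuclei, nppa2)[["1"]]), oracle)
})

test_that("binucleate joining respects distance, class, and transitivity", {
  mk <- function(centers) {
    nuc <- matrix(0L, 200, 200)
    for (k in seq_len(nrow(centers))) {
      nuc[outer(1:200, 1:200, function(r, c)
        (r - centers[k, 1])^2 + (c - centers[k, 2])^2 <= 36)] <- k
    }
    nuc
  }
  rec <- function(nuc, classes) {
    tibble::tibble(label = seq_along(classes),
                   area_px = tabulate(nuc[nuc > 0]),
                   centroid_r = 0, centroid_c = 0, marker_class = classes)
  }
  # 10 px gap (boundary-to-boundary): joined
  nuc <- mk(rbind(c(100, 80), c(100, 102)))
  out <- join_binucleates(nuc, rec(nuc, c("actinin", "actinin")))
  expect_equal(out$group_id, c(1L, 1L))
  # 30 px gap: separate
  nuc2 <- mk(rbind(c(100, 60), c(100, 102)))
  out2 <- join_binucleates(nuc2, rec(nuc2, c("actinin", "actinin")))
  expect_equal(length(unique(out2$group_id)), 2)
  # different classes never join
  out3 <- join_binucleates(nuc, rec(nuc, c("actinin", "hcn4")))
  expect_equal(length(unique(out3$group_id)), 2)
  # chain A-B close, B-C close, A-C far: one transitive group (union-find oracle)
  nuc4 <- mk(rbind(c(100, 60), c(100, 80), c(100, 100)))
  out4 <- join_binucleates(nuc4, rec(nuc4, rep("actinin", 3)))
  expect_equal(length(unique(out4$group_id)), 1)
})

test_that("cell segmentation recovers truth masks within 2 px and tallies match flags", {
  f <- quiet_field(seed = 1)
  seg <- segment_field(f)
  expect_equal(nrow(seg$cells), nrow(f$truth))

  br <- EBImage::makeBrush(5, "disc")   # radius-2 erosion/dilation
  for (i in seq_len(nrow(f$truth))) {
    tm <- f$truth$mask[[i]]
    d <- (seg$cells$centroid_r - f$truth$centroid_r[i])^2 +
         (seg$cells$centroid_c - f$truth$centroid_c[i])^2
    cm <- seg$labels == seg$cells$cell_id[which.min(d)]
    expect_equal(sum(EBImage::erode(tm, br) & !cm), 0,
                 info = sprintf("cell %d under-segmented", i))
    expect_equal(sum(cm & !EBImage::dilate(tm, br)), 0,
                 info = sprintf("cell %d over-segmented", i))
  }
  got <- dplyr::count(seg$cells, subtype)
  want <- dplyr::count(tibble::tibble(subtype = truth_subtype(f$truth)), subtype)
  expect_equal(dplyr::arrange(got, subtype), dplyr::arrange(want, subtype))
})

test_that("cell masks are disjoint and each contains its nuclei", {
  f <- quiet_field(seed = 2)
  seg <- segment_field(f)
  # disjointness is structural (single label map); every nucleus pixel set of
  # a segmented group lies inside its cell mask
  for (k in seq_len(nrow(seg$cells))) {
    gid <- seg$cells$group_id[k]
    labs <- seg$records$label[seg$records$group_id == gid]
    inside <- seg$labels[seg$nuclei %in% labs]
    expect_true(all(inside == seg$cells$cell_id[k]))
  }
  expect_equal(sort(unique(as.vector(seg$labels))),
               c(0L, seg$cells$cell_id))
})

test_that("adjacent cells of different classes respect each other's marker territory", {
  fl <- tibble::tibble(actinin = c(TRUE, FALSE), hcn4 = c(FALSE, TRUE),
                       nppa = FALSE)
  f <- quiet_field(subtype_table = fl, shape = c(256, 256), seed = 6)
  seg <- segment_field(f)
  expect_equal(nrow(seg$cells), 2)
  act_cell <- seg$labels == seg$cells$cell_id[seg$cells$marker_class == "actinin"]
  hcn_cell <- seg$labels == seg$cells$cell_id[seg$cells$marker_class == "hcn4"]
  # neither mask intrudes into the other's exclusive truth region
  m_act <- f$truth$mask[[which(f$truth$actinin)]]
  m_hcn <- f$truth$mask[[which(f$truth$hcn4)]]
  expect_equal(sum(act_cell & m_hcn), 0)
  expect_equal(sum(hcn_cell & m_act), 0)
})

test_that("a field with no classified nuclei yields no cells", {
  f <- quiet_field(subtype_table = tibble::tibble(actinin = FALSE,
                                                  hcn4 = FALSE, nppa = FALSE),
                   shape = c(224, 224), seed = 9)
  seg <- segment_field(f)
  expect_equal(nrow(seg$cells), 0)
  expect_equal(max(seg$labels), 0)
})
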