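#' Correct marker bleed-through into the DAPI channel
#'
#' Perinuclear Nppa and membrane Hcn4-GFP signal can bleed into the DAPI
#' channel and create spurious nuclear foreground. A bleed-through pixel is
#' one whose apparent DAPI signal is dominated by the marker channels:
#' wherever the reference marker intensity (pixelwise maximum of the
#' available Nppa and Hcn4 channels) exceeds `ratio` times the DAPI
#' intensity, the DAPI pixel is assigned zero. True nuclei (bright DAPI over
#' a dark reference) are never touched. With neither reference channel
#' available the image is returned unchanged with a message.
#'
#' @param dapi DAPI intensity matrix in [0, 1].
#' @param nppa,hcn4 reference channels (either may be `NULL`).
#' @param ratio bleed-through ratio threshold.
#' @return Corrected DAPI matrix.
#' @export
correct_dapi_bleedthrough <- function(dapi, nppa = NULL, hcn4 = NULL,
                                      ratio = 1.5) {
  refs <- Filter(Negate(is.null), list(nppa, hcn4))
  if (!length(refs)) {
    inform("no Nppa/Hcn4 reference channel; bleed-through correction skipped.")
    return(dapi)
  }
  ref <- Reduce(pmax, refs)
  stopifnot(identical(dim(ref), dim(dapi)))
  out <- dapi
  out[ref > ratio * dapi] <- 0
  out
}

# Gaussian-smooth and Otsu-binarize a channel; optional morphological closing
# first. A single-valued image has no Otsu threshold and yields an empty
# foreground.
smooth_binarize <- function(image, gaussian_radius_px = 4,
                            closing_radius_px = 0) {
  img <- image
  if (closing_radius_px > 0) {
    img <- as.matrix(EBImage::closing(
      img, EBImage::makeBrush(2 * closing_radius_px + 1, "disc")))
  }
  if (gaussian_radius_px > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = gaussian_radius_px / 2,
                                    radius = 2 * gaussian_radius_px + 1))
  }
  if (diff(range(img)) < .Machine$double.eps) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  th <- EBImage::otsu(EBImage::Image(img), range = range(img))
  img > th
}

#' Detect nuclei in a (corrected) DAPI image
#'
#' Morphological closing, Gaussian smoothing, Otsu binarization, small-object
#' removal, and connected-component labelling.
#'
#' @param dapi corrected DAPI matrix.
#' @param min_area minimum nucleus area in pixels.
#' @param closing_radius_px disc radius of the closing structuring element.
#' @param gaussian_radius_px Gaussian kernel radius (sigma = radius / 2).
#' @return Integer label matrix with labels contiguous from 1; all zero (with
#'   a warning) if no foreground survives.
#' @export
detect_nuclei <- function(dapi, min_area = 60, closing_radius_px = 3,
                          gaussian_radius_px = 4) {
  fg <- smooth_binarize(dapi, gaussian_radius_px, closing_radius_px)
  lab <- EBImage::bwlabel(matrix(as.integer(fg), nrow(fg), ncol(fg)))
  if (max(lab) == 0) {
    warn("no nuclei detected (empty foreground after thresholding).")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(areas < min_area)
  if (length(drop)) lab <- EBImage::rmObjects(lab, drop, reenumerate = TRUE)
  lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  if (max(lab) == 0) warn("all nuclei smaller than `min_area`; none kept.")
  lab
}

nucleus_pixel_sets <- function(nuclei) {
  idx <- which(nuclei > 0)
  split(idx, nuclei[idx])
}

#' Classify nuclei by cardiomyocyte marker enclosure
#'
#' The marker channels are smoothed and Otsu-binarized exactly like DAPI; a
#' nucleus fully inside the alpha-actinin foreground is actinin-positive,
#' fully inside the Hcn4 foreground is hcn4-positive, and fully inside their
#' intersection is dual-positive. "Fully" is strict by default
#' (`coverage_frac = 1`): one pixel outside the foreground declassifies the
#' nucleus.
#'
#' @param nuclei nucleus label matrix from [detect_nuclei()].
#' @param actinin alpha-actinin intensity matrix.
#' @param hcn4 Hcn4-GFP intensity matrix or `NULL` (classification then uses
#'   actinin only).
#' @param gaussian_radius_px smoothing radius used before Otsu.
#' @param coverage_frac fraction of nucleus pixels that must be inside the
#'   foreground to count as enclosed (1 = strict).
#' @return Tibble with one row per nucleus: `label`, `area_px`,
#'   `centroid_r`, `centroid_c`, `marker_class` (one of `"actinin"`,
#'   `"hcn4"`, `"actinin+hcn4"`, `"none"`).
#' @export
classify_nucleus_markers <- function(nuclei, actinin, hcn4 = NULL,
                                     gaussian_radius_px = 4,
                                     coverage_frac = 1) {
  sets <- nucleus_pixel_sets(nuclei)
  act_fg <- smooth_binarize(actinin, gaussian_radius_px)
  hcn_fg <- if (is.null(hcn4)) matrix(FALSE, nrow(nuclei), ncol(nuclei))
            else smooth_binarize(hcn4, gaussian_radius_px)

  rows <- purrr::map(names(sets), function(lb) {
    px <- sets[[lb]]
    a_in <- mean(act_fg[px]) >= coverage_frac
    h_in <- mean(hcn_fg[px]) >= coverage_frac
    both <- mean((act_fg & hcn_fg)[px]) >= coverage_frac
    cls <- if (both) "actinin+hcn4" else if (a_in) "actinin" else if (h_in) "hcn4" else "none"
    rc <- arrayInd(px, dim(nuclei))
    tibble::tibble(label = as.integer(lb), area_px = length(px),
                   centroid_r = mean(rc[, 1]), centroid_c = mean(rc[, 2]),
                   marker_class = cls)
  })
  dplyr::bind_rows(rows)
}

#' Perinuclear Nppa classification
#'
#' Nppa accumulates around, not inside, the nucleus, so each nucleus is
#' scored in a perinuclear ring extending `ring_px` pixels radially from the
#' nucleus edge (nucleus pixels of any label excluded, ring clipped at the
#' image border). A nucleus is Nppa-positive when the 90th-percentile ring
#' intensity exceeds `threshold`.
#'
#' @param nuclei nucleus label matrix.
#' @param nppa Nppa intensity matrix.
#' @param ring_px radial ring extent in pixels.
#' @param threshold relative-intensity threshold on the ring percentile.
#' @param prob percentile used (0.9); computed with linear interpolation
#'   between order statistics (`stats::quantile` type 7).
#' @return Logical vector named by nucleus label, `TRUE` for Nppa-positive.
#'   An empty ring yields `FALSE` with a warning.
#' @export
classify_nppa <- function(nuclei, nppa, ring_px = 8, threshold = 0.1,
                          prob = 0.9) {
  sets <- nucleus_pixel_sets(nuclei)
  any_nuc <- nuclei > 0
  brush <- EBImage::makeBrush(2 * ring_px + 1, "disc")
  out <- vapply(names(sets), function(lb) {
    rc <- arrayInd(sets[[lb]], dim(nuclei))
    r0 <- max(1, min(rc[, 1]) - ring_px - 1); r1 <- min(nrow(nuclei), max(rc[, 1]) + ring_px + 1)
    c0 <- max(1, min(rc[, 2]) - ring_px - 1); c1 <- min(ncol(nuclei), max(rc[, 2]) + ring_px + 1)
    sub <- nuclei[r0:r1, c0:c1] == as.integer(lb)
    ring <- EBImage::dilate(sub, brush) & !any_nuc[r0:r1, c0:c1]
    v <- nppa[r0:r1, c0:c1][ring]
    if (!length(v)) {
      warn(sprintf("nucleus %s has an empty perinuclear ring; scored negative.", lb))
      return(FALSE)
    }
    unname(quantile(v, prob, type = 7)) > threshold
  }, logical(1))
  out
}

# boundary pixels of one nucleus, as (row, col)
boundary_coords <- function(mask) {
  er <- EBImage::erode(mask, EBImage::makeBrush(3, "box"))
  which(mask & !er, arr.ind = TRUE)
}

#' Join nearby same-class nuclei into binucleate groups
#'
#' Nuclei of the same marker classification whose boundary-to-boundary
#' distance is at most `max_dist_px` are assumed to belong to one binucleated
#' cell and share a group id; the relation is closed transitively. Nuclei of
#' different classes are never joined, and Nppa status does not participate.
#'
#' @param nuclei nucleus label matrix.
#' @param records tibble from [classify_nucleus_markers()].
#' @param max_dist_px joining distance in pixels.
#' @return `records` with an integer `group_id` column (contiguous from 1).
#' @export
join_binucleates <- function(nuclei, records, max_dist_px = 25) {
  n <- nrow(records)
  if (n == 0) return(dplyr::mutate(records, group_id = integer()))
  bnd <- purrr::map(records$label, function(lb) boundary_coords(nuclei == lb))

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (records$marker_class[i] != records$marker_class[j]) next
      # cheap bounding check before the exact pairwise minimum
      ci <- colMeans(bnd[[i]]); cj <- colMeans(bnd[[j]])
      reach_i <- sqrt(max((bnd[[i]][, 1] - ci[1])^2 + (bnd[[i]][, 2] - ci[2])^2))
      reach_j <- sqrt(max((bnd[[j]][, 1] - cj[1])^2 + (bnd[[j]][, 2] - cj[2])^2))
      if (sqrt(sum((ci - cj)^2)) - reach_i - reach_j > max_dist_px) next
      d2 <- outer(bnd[[i]][, 1], bnd[[j]][, 1], "-")^2 +
            outer(bnd[[i]][, 2], bnd[[j]][, 2], "-")^2
      if (sqrt(min(d2)) <= max_dist_px) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  dplyr::mutate(records, group_id = as.integer(factor(roots,
                                                      levels = unique(roots))))
}

# One segmentation pass. Nucleus groups seed a marker-controlled watershed of
# the Sobel gradient (computed on a heavily smoothed image, so that
# striation-scale texture does not raise interior barriers as tall as the
# cell border). Cell extent comes from the solidified pass foreground (Otsu
# foreground, closed and hole-filled so sub-threshold striation bands stay
# inside their cell): a connected foreground component seeded by exactly one
# group is that group's cell, and a component holding several groups is
# partitioned between them along the watershed boundary. Finally a bounded
# closing repairs boundary notches left where dark bands meet the cell edge.
segment_pass <- function(image, nuclei, records, group_ids,
                         gaussian_radius_px = 4, solid_brush_px = 13) {
  if (!length(group_ids)) {
    return(list(labels = matrix(0L, nrow(image), ncol(image)),
                groups = integer()))
  }
  fg <- smooth_binarize(image, gaussian_radius_px)
  markers <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(group_ids)) {
    labs <- records$label[records$group_id == group_ids[i]]
    markers[nuclei %in% labs] <- i
  }
  smoothed <- as.matrix(EBImage::gblur(image, sigma = gaussian_radius_px,
                                       radius = 4 * gaussian_radius_px + 1))
  ws <- watershed_markers(sobel_gradient(smoothed), markers)

  brush <- EBImage::makeBrush(solid_brush_px, "disc")
  solid <- EBImage::fillHull(EBImage::closing(fg, brush))
  comp <- EBImage::bwlabel(matrix(as.integer(solid), nrow(solid), ncol(solid)))

  base <- vector("list", length(group_ids))
  for (i in seq_along(group_ids)) {
    own <- setdiff(unique(comp[markers == i]), 0L)
    m <- matrix(comp %in% own, nrow(comp), ncol(comp))
    shared <- vapply(seq_along(group_ids), function(j) {
      j != i && any(comp[markers == j] %in% own)
    }, logical(1))
    if (any(shared)) m <- m & ws == i
    m[markers == i] <- TRUE
    base[[i]] <- m
  }
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(group_ids)) {
    m <- EBImage::fillHull(EBImage::closing(base[[i]], brush))
    for (j in seq_along(group_ids)) if (j != i) m <- m & !base[[j]]
    out[m & out == 0L] <- i
  }
  list(labels = out, groups = group_ids)
}

#' Sequential-masking marker-controlled watershed cell segmentation
#'
#' Cell boundaries are found in three passes so that adjacent cells of
#' different subtypes do not merge: (1) actinin-only cells are segmented on
#' the alpha-actinin image with the Hcn4 foreground masked out; (2) hcn4-only
#' cells on the Hcn4 image with the actinin foreground masked out; (3)
#' dual-positive cells on the pixelwise-combined image with the
#' already-segmented cell regions masked out. In each pass the Sobel gradient
#' magnitude is flooded by a marker-controlled watershed seeded with that
#' pass's nucleus groups plus a background marker of eroded sub-Otsu pixels.
#'
#' @param stack a [channel_stack()] with at least `actinin` (and `dapi`,
#'   already consumed upstream); `hcn4` optional.
#' @param nuclei nucleus label matrix.
#' @param records classified and grouped nucleus tibble
#'   (from [join_binucleates()]).
#' @param nppa_positive optional logical vector named by nucleus label
#'   (from [classify_nppa()]); a cell is Nppa-positive if any of its nuclei
#'   is.
#' @param gaussian_radius_px smoothing used for the pass foregrounds.
#' @return List with `cells` (tibble: `cell_id`, `group_id`, `marker_class`,
#'   `nppa_positive`, `subtype`, `n_nuclei`, `area_px`, `centroid_r`,
#'   `centroid_c`, `on_border`) and `labels` (integer cell label matrix).
#'   Nucleus groups whose catchment basin is empty are dropped with a
#'   warning.
#' @export
segment_cells <- function(stack, nuclei, records, nppa_positive = NULL,
                          gaussian_radius_px = 4) {
  stopifnot(inherits(stack, "channel_stack"))
  act <- stack$channels$actinin
  if (is.null(act)) abort("stack has no 'actinin' channel.",
                          class = "sarcotex_config_error")
  hcn <- stack$channels$hcn4
  dims <- dim(act)
  cells_lab <- matrix(0L, dims[1], dims[2])
  out_rows <- list()

  if (nrow(records) == 0 || all(records$marker_class == "none")) {
    return(list(cells = empty_cell_table(), labels = cells_lab))
  }

  act_fg <- smooth_binarize(act, gaussian_radius_px)
  hcn_fg <- if (is.null(hcn)) matrix(FALSE, dims[1], dims[2])
            else smooth_binarize(hcn, gaussian_radius_px)

  groups_of <- function(cls) unique(records$group_id[records$marker_class == cls])

  img1 <- act; img1[hcn_fg] <- 0
  img2 <- if (is.null(hcn)) NULL else { x <- hcn; x[act_fg] <- 0; x }

  p1 <- segment_pass(img1, nuclei, records, groups_of("actinin"),
                     gaussian_radius_px)
  p2 <- if (is.null(img2)) list(labels = matrix(0L, dims[1], dims[2]), groups = integer())
        else segment_pass(img2, nuclei, records, groups_of("hcn4"),
                          gaussian_radius_px)

  merged <- if (is.null(hcn)) act else pmax(act, hcn)
  merged[p1$labels > 0 | p2$labels > 0] <- 0
  p3 <- segment_pass(merged, nuclei, records, groups_of("actinin+hcn4"),
                     gaussian_radius_px)

  next_id <- 1L
  for (pass in list(p1, p2, p3)) {
    for (i in seq_along(pass$groups)) {
      gid <- pass$groups[i]
      mask <- pass$labels == i & cells_lab == 0L
      # a cell always contains its seed nuclei
      mask[nuclei %in% records$label[records$group_id == gid]] <- TRUE
      if (sum(mask) == 0) {
        warn(sprintf("nucleus group %d has an empty catchment; cell dropped.", gid))
        next
      }
      cells_lab[mask] <- next_id
      nuc <- records[records$group_id == gid, ]
      npos <- if (is.null(nppa_positive)) FALSE
              else any(nppa_positive[as.character(nuc$label)])
      rc <- which(mask, arr.ind = TRUE)
      on_border <- any(rc[, 1] %in% c(1, dims[1])) || any(rc[, 2] %in% c(1, dims[2]))
      out_rows[[length(out_rows) + 1L]] <- tibble::tibble(
        cell_id = next_id, group_id = gid,
        marker_class = nuc$marker_class[1],
        nppa_positive = isTRUE(npos),
        subtype = paste0(nuc$marker_class[1], if (isTRUE(npos)) "+nppa" else ""),
        n_nuclei = nrow(nuc), area_px = sum(mask),
        centroid_r = mean(rc[, 1]), centroid_c = mean(rc[, 2]),
        on_border = on_border
      )
      next_id <- next_id + 1L
    }
  }
  cells <- if (length(out_rows)) dplyr::bind_rows(out_rows) else empty_cell_table()
  list(cells = cells, labels = cells_lab)
}

empty_cell_table <- function() {
  tibble::tibble(cell_id = integer(), group_id = integer(),
                 marker_class = character(), nppa_positive = logical(),
                 subtype = character(), n_nuclei = integer(),
                 area_px = integer(), centroid_r = numeric(),
                 centroid_c = numeric(), on_border = logical())
}
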