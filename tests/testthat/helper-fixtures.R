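# shared in-code fixtures; everything is generated deterministically

# brute-force GLCM oracle: enumerate every pixel pair by double loop
oracle_glcm <- function(image, mask, offset, levels, symmetric = TRUE) {
  v <- image[mask]
  lo <- min(v); hi <- max(v)
  binof <- function(val) {
    if (hi == lo) return(1L)
    min(floor((val - lo) / (hi - lo) * levels) + 1, levels)
  }
  counts <- matrix(0, levels, levels)
  nr <- nrow(image); nc <- ncol(image)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!mask[r, c] || !mask[r2, c2]) next
    i <- binof(image[r, c]); j <- binof(image[r2, c2])
    counts[i, j] <- counts[i, j] + 1
  }
  if (symmetric) counts <- counts + t(counts)
  counts
}

# direct evaluation of the correlation formula on a probability matrix
oracle_correlation <- function(p) {
  g <- nrow(p); i <- seq_len(g)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(i * pi_); mu_j <- sum(i * pj_)
  sd_i <- sqrt(sum((i - mu_i)^2 * pi_)); sd_j <- sqrt(sum((i - mu_j)^2 * pj_))
  tot <- 0
  for (a in i) for (b in i) tot <- tot + (a - mu_i) * (b - mu_j) * p[a, b]
  tot / (sd_i * sd_j)
}

raster_disc <- function(radius, pad = 10) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  outer(1:n, 1:n, function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius^2)
}

raster_ellipse <- function(a_col, b_row, pad = 10, angle_deg = 0) {
  n <- 2 * (max(a_col, b_row) + pad) + 1
  ctr <- max(a_col, b_row) + pad + 1
  th <- angle_deg * pi / 180
  outer(1:n, 1:n, function(r, c) {
    x <- c - ctr; y <- -(r - ctr)          # math convention, y up
    xp <- x * cos(th) + y * sin(th)
    yp <- -x * sin(th) + y * cos(th)
    (xp / a_col)^2 + (yp / b_row)^2 <= 1
  })
}

quiet_field <- function(...) {
  suppressWarnings(make_cell_field(...))
}

# run the segmentation stages on a field, silently
segment_field <- function(field, ...) {
  ch <- field$stack$channels
  suppressWarnings({
    dapi <- correct_dapi_bleedthrough(ch$dapi, ch$nppa, ch$hcn4)
    nuclei <- detect_nuclei(dapi)
    rec <- classify_nucleus_markers(nuclei, ch$actinin, ch$hcn4)
    rec <- join_binucleates(nuclei, rec)
    npos <- classify_nppa(nuclei, ch$nppa)
    seg <- segment_cells(field$stack, nuclei, rec, npos)
  })
  c(seg, list(nuclei = nuclei, records = rec, nppa_positive = npos))
}

truth_subtype <- function(truth) {
  paste0(ifelse(truth$actinin & truth$hcn4, "actinin+hcn4",
                ifelse(truth$actinin, "actinin",
                       ifelse(truth$hcn4, "hcn4", "none"))),
         ifelse(truth$nppa, "+nppa", ""))
}
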