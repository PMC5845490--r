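# Independent brute-force oracles and small generators used across tests.
# Oracles are deliberately written as naive per-element loops, not via the
# package's vectorized code paths.

# random chromaticity frame: per-pixel uniform simplex sample, with a few
# invalid pixels
rand_chrom <- function(nr, nc, p_invalid = 0.1) {
  n <- nr * nc
  x <- matrix(stats::runif(3 * n), n, 3)
  x <- x / rowSums(x)
  valid <- matrix(stats::runif(n) > p_invalid, nr, nc)
  r <- matrix(x[, 1], nr, nc); g <- matrix(x[, 2], nr, nc); b <- matrix(x[, 3], nr, nc)
  r[!valid] <- 0; g[!valid] <- 0; b[!valid] <- 0
  chrom_frame(r, g, b, valid)
}

rand_mask <- function(nr, nc, p = 0.5) matrix(stats::runif(nr * nc) < p, nr, nc)

# per-pixel ROI conjunction oracle
oracle_roi <- function(chrom, m, n) {
  out <- matrix(FALSE, nrow(chrom$r), ncol(chrom$r))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- chrom$valid[i, j] &&
        chrom$r[i, j] >= m * chrom$b[i, j] &&
        chrom$r[i, j] >= n * chrom$g[i, j]
    }
  }
  out
}

# exhaustive distance-sort KNN oracle with the documented tie rules
oracle_knn <- function(train_x, train_y, q, k) {
  d <- numeric(nrow(train_x))
  for (i in seq_len(nrow(train_x))) d[i] <- sqrt(sum((train_x[i, ] - q)^2))
  ord <- seq_len(nrow(train_x))[order(d, seq_len(nrow(train_x)))]
  nn <- ord[seq_len(k)]
  tab <- table(train_y[nn])
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) winners else as.character(train_y[ord[1L]])
}

# per-pixel erosion/dilation oracles; outside the image is background
oracle_erode <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      keep <- TRUE
      for (a in -r:r) {
        for (b in -r:r) {
          if (!se[a + r + 1L, b + r + 1L]) next
          ii <- i + a; jj <- j + b
          inside <- ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask)
          if (!inside || !mask[ii, jj]) { keep <- FALSE; break }
        }
        if (!keep) break
      }
      out[i, j] <- keep
    }
  }
  out
}

oracle_dilate <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      hit <- FALSE
      for (a in -r:r) {
        for (b in -r:r) {
          if (!se[a + r + 1L, b + r + 1L]) next
          ii <- i - a; jj <- j - b
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj]) { hit <- TRUE; break }
        }
        if (hit) break
      }
      out[i, j] <- hit
    }
  }
  out
}

# single-pass label smoothing oracle
oracle_postprocess <- function(l) {
  out <- l
  if (length(l) >= 3L) {
    for (i in 2:(length(l) - 1L)) {
      if (l[i] == "nonbleeding" && l[i - 1] == "bleeding" && l[i + 1] == "bleeding")
        out[i] <- "bleeding"
    }
  }
  out
}

# small phantom configuration for fast tests
small_phantom <- function(...) {
  args <- utils::modifyList(list(image_size = 96, border_band = 8), list(...))
  do.call(phantom_config, args)
}

# strip + normalize + ROI + cropped truth for a generated phantom frame
process_phantom <- function(fr, params = roi_params()) {
  st <- strip_border(fr$frame)
  ch <- normalize_rgb(st$frame, st$validity)
  list(chrom = ch, roi = extract_roi(ch, params),
       truth = crop_mask(fr$truth, st), valid = ch$valid)
}

# uniform-intensity frame with a black band of the given width on all sides
banded_frame <- function(size, band, value = 100) {
  m <- matrix(0, size, size)
  inner <- (band + 1):(size - band)
  m[inner, inner] <- value
  rgb_frame(m, m, m)
}
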