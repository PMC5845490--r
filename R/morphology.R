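#' Binary structuring element
#'
#' A symmetric disk or square neighbourhood used by erosion and dilation.
#' The disk contains the pixels at Euclidean distance <= radius from the
#' center; the square is the full (2*radius+1)^2 block.
#'
#' @param shape `"disk"` or `"square"`.
#' @param radius positive integer half-width in pixels.
#' @return Logical (2*radius+1) x (2*radius+1) matrix.
#' @export
structuring_element <- function(shape = c("disk", "square"), radius = 2) {
  shape <- match.arg(shape)
  if (radius < 1) stop("radius must be a positive integer", call. = FALSE)
  radius <- as.integer(radius)
  if (shape == "square") {
    matrix(TRUE, 2L * radius + 1L, 2L * radius + 1L)
  } else {
    outer((-radius):radius, (-radius):radius,
          function(a, b) a^2 + b^2 <= radius^2)
  }
}

# Shifted copy of a logical matrix: out[i, j] = m[i + dr, j + dc],
# pixels outside the image read as FALSE (background).
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ri <- max(1L, 1L - dr):min(nr, nr - dr)
  ci <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(ri) && length(ci))
    out[ri, ci] <- m[ri + dr, ci + dc, drop = FALSE]
  out
}

se_offsets <- function(se) {
  if (!is.logical(se) || nrow(se) %% 2L == 0L || ncol(se) %% 2L == 0L)
    stop("structuring element must be a logical odd-sized matrix", call. = FALSE)
  w <- which(se, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("structuring element is empty", call. = FALSE)
  cbind(w[, 1] - (nrow(se) + 1L) %/% 2L, w[, 2] - (ncol(se) + 1L) %/% 2L)
}

#' Binary erosion
#'
#' A pixel survives iff the structuring element, centered on it, fits
#' entirely inside the mask. Pixels outside the image are background, so
#' foreground touching the image border erodes.
#'
#' @param mask logical matrix.
#' @param se structuring element from [structuring_element()].
#' @return Logical matrix.
#' @export
binary_erode <- function(mask, se = structuring_element("disk", 2)) {
  off <- se_offsets(se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(mask, off[i, 1], off[i, 2])
  out
}

#' Binary dilation
#'
#' A pixel turns on iff the reflected structuring element, centered on it,
#' hits any foreground pixel; joins nearby disparate components.
#'
#' @inheritParams binary_erode
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask, se = structuring_element("disk", 2)) {
  off <- se_offsets(se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(mask, -off[i, 1], -off[i, 2])
  out
}

#' Refine a candidate bleeding region by erosion then dilation
#'
#' Erosion removes small-scale detail (isolated ROI pixels that are not
#' credible bleeding), then dilation rejoins and smooths the surviving
#' region. With equal structuring elements this is a morphological opening:
#' anti-extensive (never adds pixels outside the input) and idempotent.
#'
#' @param roi logical candidate mask (typically [extract_roi()] output on a
#'   frame the classifier labelled bleeding).
#' @param erode_se,dilate_se structuring elements; defaults are disk radius 2
#'   for both. A larger dilation element joins more disparate fragments.
#' @return Logical refined region mask.
#' @export
refine_region <- function(roi,
                          erode_se = structuring_element("disk", 2),
                          dilate_se = erode_se) {
  binary_dilate(binary_erode(roi, erode_se), dilate_se)
}

#' Pixel-level region detection metrics
#'
#' Confusion of a detected bleeding region against ground truth over the
#' valid pixels, and the three derived rates:
#' `FNR = FN / (FN + TP)`, `FPR = FP / (FP + TN)`,
#' `precision = TP / (TP + FP)`. A rate with zero denominator is undefined
#' and reported as `NA`.
#'
#' @param pred,truth,valid logical matrices of identical dimensions.
#' @return A list of class `region_metrics` with elements `fnr`, `fpr`,
#'   `precision` and `confusion` (list `tp`, `fp`, `tn`, `fn`).
#' @export
region_metrics <- function(pred, truth, valid) {
  if (!all(dim(pred) == dim(truth)) || !all(dim(pred) == dim(valid)))
    stop("mask dimensions differ", call. = FALSE)
  tp <- sum(pred & truth & valid)
  fp <- sum(pred & !truth & valid)
  tn <- sum(!pred & !truth & valid)
  fn <- sum(!pred & truth & valid)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(fnr = ratio(fn, fn + tp), fpr = ratio(fp, fp + tn),
         precision = ratio(tp, tp + fp),
         confusion = list(tp = tp, fp = fp, tn = tn, fn = fn)),
    class = "region_metrics"
  )
}
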