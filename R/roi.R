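#' ROI slope parameters
#'
#' The region of interest is cut out of chromaticity space by two straight
#' lines through the origin: pixels are kept when \eqn{r \ge m b} (r--b plane)
#' and then when \eqn{r \ge n g} (r--g plane). The defaults m = 2.8, n = 2.0 are
#' the values calibrated against clinician-marked bleeding masks.
#'
#' @param m slope of the r--b separating line (> 0).
#' @param n slope of the r--g separating line (> 0).
#' @return A list of class `roi_params`.
#' @export
roi_params <- function(m = 2.8, n = 2.0) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    stop("m must be a positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0)
    stop("n must be a positive number", call. = FALSE)
  structure(list(m = m, n = n), class = "roi_params")
}

#' First-stage ROI condition in the r--b chromaticity plane
#'
#' Keeps valid pixels with \eqn{r \ge m b} (non-strict: boundary pixels are
#' kept). Invalid pixels are always `FALSE`.
#'
#' @param chrom a [chrom_frame()].
#' @param m positive slope.
#' @return Logical pixel mask.
#' @export
apply_rb_condition <- function(chrom, m = 2.8) {
  stopifnot(inherits(chrom, "chrom_frame"))
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    stop("m must be a positive number", call. = FALSE)
  chrom$valid & (chrom$r >= m * chrom$b)
}

#' Second-stage ROI condition in the r--g chromaticity plane
#'
#' Keeps pixels already selected by `prior` that satisfy \eqn{r \ge n g}
#' (non-strict).
#'
#' @param chrom a [chrom_frame()].
#' @param n positive slope.
#' @param prior logical mask from the first stage.
#' @return Logical pixel mask.
#' @export
apply_rg_condition <- function(chrom, n = 2.0, prior) {
  stopifnot(inherits(chrom, "chrom_frame"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0)
    stop("n must be a positive number", call. = FALSE)
  if (!all(dim(prior) == dim(chrom)))
    stop("prior mask dimensions differ from the frame", call. = FALSE)
  prior & (chrom$r >= n * chrom$g)
}

#' Extract the region of interest by both chromaticity conditions
#'
#' Sequential application of the r--b then r--g condition; equivalently the
#' per-pixel conjunction \eqn{r \ge m b \wedge r \ge n g} on valid pixels. The surviving
#' pixels are the candidate bleeding pixels.
#'
#' @param chrom a [chrom_frame()].
#' @param params an [roi_params()].
#' @return Logical pixel mask (always a subset of the validity mask).
#' @export
extract_roi <- function(chrom, params = roi_params()) {
  stopifnot(inherits(params, "roi_params"))
  apply_rg_condition(chrom, params$n, apply_rb_condition(chrom, params$m))
}

#' Pixel-level segmentation accuracy
#'
#' Accuracy of a predicted bleeding mask against ground truth, counting only
#' valid pixels: `(N_tbp + N_tnbp) / N_t` where `N_tbp` is the number of true
#' bleeding pixels, `N_tnbp` the number of true nonbleeding pixels and `N_t`
#' the number of valid pixels.
#'
#' @param pred,truth,valid logical matrices of identical dimensions.
#' @return A list of class `pixel_accuracy` with elements `n_true_bleeding`,
#'   `n_true_nonbleeding`, `n_total`, `accuracy`.
#' @export
pixel_accuracy <- function(pred, truth, valid) {
  if (!all(dim(pred) == dim(truth)) || !all(dim(pred) == dim(valid)))
    stop("mask dimensions differ", call. = FALSE)
  n_t <- sum(valid)
  if (n_t == 0L) stop("no valid pixels", call. = FALSE)
  tbp <- sum(pred & truth & valid)
  tnbp <- sum(!pred & !truth & valid)
  structure(
    list(
      n_true_bleeding = tbp,
      n_true_nonbleeding = tnbp,
      n_total = n_t,
      accuracy = (tbp + tnbp) / n_t
    ),
    class = "pixel_accuracy"
  )
}

#' Calibrate an ROI slope by a grid sweep against ground truth
#'
#' For each candidate slope value, computes the pixel-level accuracy of the
#' thresholded mask on every image and reports the mean and standard
#' deviation across images, plus the argmax of the mean. `stage = "rb"`
#' sweeps the first-stage slope m (mask = r--b condition alone);
#' `stage = "rg"` sweeps n over the full ROI while keeping m fixed at
#' `fixed_m`, mirroring the sequential search (m first, then n). Ties in the
#' argmax are broken toward the smaller slope, i.e. the more inclusive ROI.
#'
#' @param images list of `list(chrom = , truth = )` pairs: a [chrom_frame()]
#'   and its ground-truth bleeding mask.
#' @param grid numeric vector of candidate slope values.
#' @param stage `"rb"` or `"rg"`.
#' @param fixed_m first-stage slope, required when `stage = "rg"`.
#' @return A list of class `sweep_table`: `table` (data.frame with columns
#'   `value`, `mean_accuracy`, `std_accuracy`), `argmax`, `stage`, and the
#'   per-image accuracy matrix `accuracy` (images x grid).
#' @export
sweep_slope <- function(images, grid, stage = c("rb", "rg"), fixed_m = NULL) {
  stage <- match.arg(stage)
  if (length(images) == 0L) stop("empty image set", call. = FALSE)
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  if (any(grid <= 0)) stop("slopes must be positive", call. = FALSE)
  if (stage == "rg" && is.null(fixed_m))
    stop("stage 'rg' requires fixed_m", call. = FALSE)
  grid <- sort(grid)
  acc <- matrix(NA_real_, length(images), length(grid))
  for (i in seq_along(images)) {
    ch <- images[[i]]$chrom
    tr <- images[[i]]$truth
    for (j in seq_along(grid)) {
      mask <- if (stage == "rb") {
        apply_rb_condition(ch, grid[j])
      } else {
        extract_roi(ch, roi_params(m = fixed_m, n = grid[j]))
      }
      acc[i, j] <- pixel_accuracy(mask, tr, ch$valid)$accuracy
    }
  }
  mean_acc <- colMeans(acc)
  std_acc <- apply(acc, 2, function(v) if (length(v) > 1L) stats::sd(v) else 0)
  tab <- data.frame(value = grid, mean_accuracy = mean_acc, std_accuracy = std_acc)
  # grid is sorted ascending and which.max returns the first maximum,
  # so ties resolve to the smaller (more inclusive) slope
  structure(
    list(table = tab, argmax = grid[which.max(mean_acc)], stage = stage,
         fixed_m = fixed_m, accuracy = acc),
    class = "sweep_table"
  )
}

#' Joint grid calibration of both ROI slopes
#'
#' Off-default alternative to the sequential sweep: evaluates mean pixel
#' accuracy of the full ROI over the cartesian product of candidate m and n
#' values. Ties resolve to the smallest m, then the smallest n.
#'
#' @param images as in [sweep_slope()].
#' @param m_grid,n_grid numeric candidate vectors.
#' @return A list with the mean-accuracy matrix `mean_accuracy`
#'   (m values x n values) and `argmax = c(m, n)`.
#' @export
sweep_slope_joint <- function(images, m_grid, n_grid) {
  if (length(images) == 0L) stop("empty image set", call. = FALSE)
  if (length(m_grid) == 0L || length(n_grid) == 0L) stop("empty grid", call. = FALSE)
  m_grid <- sort(m_grid)
  n_grid <- sort(n_grid)
  acc <- matrix(NA_real_, length(m_grid), length(n_grid),
                dimnames = list(m_grid, n_grid))
  for (a in seq_along(m_grid)) {
    for (b in seq_along(n_grid)) {
      p <- roi_params(m_grid[a], n_grid[b])
      acc[a, b] <- mean(vapply(images, function(im) {
        pixel_accuracy(extract_roi(im$chrom, p), im$truth, im$chrom$valid)$accuracy
      }, numeric(1)))
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(mean_accuracy = acc, argmax = c(m = m_grid[best[1]], n = n_grid[best[2]]))
}
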