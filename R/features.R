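#' ROI-restricted chromaticity histogram
#'
#' Counts the ROI pixels of one chromaticity plane into `bins` equal-width
#' bins partitioning \[0, 1\]. Bins are half-open `[edge_k, edge_{k+1})` with
#' the final bin closed at 1.0. Bin edges are fixed on the global range
#' \[0, 1\] for every image so that bin k means the same chromaticity range
#' in every frame; this is what makes bin counts comparable across frames.
#' An empty ROI yields all-zero counts.
#'
#' @param chrom a [chrom_frame()].
#' @param roi logical pixel mask (intersected with the validity mask).
#' @param plane `"r"`, `"g"` or `"b"`.
#' @param bins number of bins (>= 2); the classifier default is 64.
#' @return A list of class `roi_histogram` with elements `plane`, `bins`,
#'   `breaks` (length `bins + 1`) and integer `counts`.
#' @export
roi_histogram <- function(chrom, roi, plane = "g", bins = 64) {
  stopifnot(inherits(chrom, "chrom_frame"))
  if (!plane %in% c("r", "g", "b"))
    stop("unknown plane '", plane, "' (expected r, g or b)", call. = FALSE)
  if (bins < 2) stop("bins must be at least 2", call. = FALSE)
  if (!all(dim(roi) == dim(chrom)))
    stop("roi dimensions differ from the frame", call. = FALSE)
  v <- chrom[[plane]][roi & chrom$valid]
  idx <- pmin(floor(v * bins), bins - 1) + 1  # value 1.0 falls in the last bin
  structure(
    list(plane = plane, bins = as.integer(bins),
         breaks = seq(0, 1, length.out = bins + 1),
         counts = tabulate(idx, nbins = bins)),
    class = "roi_histogram"
  )
}

#' Classification feature vector from ROI histograms
#'
#' Concatenates the raw bin counts of one or more chromaticity-plane
#' histograms over the ROI. Counts are deliberately not normalized: the
#' absolute number of ROI pixels per bin is itself discriminative, since
#' bleeding frames produce far more ROI pixels than nonbleeding ones. The
#' default — g plane only, 64 bins — is the configuration found to classify
#' best.
#'
#' @param chrom a [chrom_frame()].
#' @param roi logical pixel mask.
#' @param planes character vector of plane ids to concatenate.
#' @param bins bins per plane.
#' @return Numeric vector of length `length(planes) * bins`, named
#'   `<plane>_bin_<k>`.
#' @export
feature_vector <- function(chrom, roi, planes = "g", bins = 64) {
  parts <- lapply(planes, function(p) {
    h <- roi_histogram(chrom, roi, plane = p, bins = bins)
    stats::setNames(h$counts, sprintf("%s_bin_%03d", p, seq_len(bins) - 1L))
  })
  unlist(parts)
}

#' Summary statistics of an ROI histogram
#'
#' The baseline feature set: mean, variance, skewness, kurtosis and energy
#' of the histogram, computed on the bin centers of the normalized
#' (probability) histogram. Energy is the sum of squared bin probabilities.
#' For a point-mass histogram (zero variance) skewness and kurtosis are
#' reported as 0.
#'
#' @param feature an [roi_histogram()] with at least one count.
#' @return A list with elements `mean`, `variance`, `skewness`, `kurtosis`,
#'   `energy`.
#' @export
histogram_stats <- function(feature) {
  stopifnot(inherits(feature, "roi_histogram"))
  n <- sum(feature$counts)
  if (n == 0L) stop("empty histogram: all bin counts are zero", call. = FALSE)
  p <- feature$counts / n
  centers <- (feature$breaks[-1] + feature$breaks[-length(feature$breaks)]) / 2
  mu <- sum(p * centers)
  v <- sum(p * (centers - mu)^2)
  if (v > 0) {
    sk <- sum(p * (centers - mu)^3) / v^1.5
    ku <- sum(p * (centers - mu)^4) / v^2
  } else {
    sk <- 0
    ku <- 0
  }
  list(mean = mu, variance = v, skewness = sk, kurtosis = ku,
       energy = sum(p^2))
}
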