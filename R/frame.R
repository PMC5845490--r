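#' RGB frame container
#'
#' An `rgb_frame` holds the three colour channels of an 8-bit endoscopy image
#' as numeric matrices on the scale 0--255, indexed `[row, column]`. Channel
#' values may be non-integer (e.g. after synthetic generation before
#' quantization); they must lie in \[0, 255\].
#'
#' @param R,G,B numeric matrices of identical dimensions with values in
#'   \[0, 255\].
#' @return An object of class `rgb_frame`: a list with elements `R`, `G`, `B`.
#' @export
rgb_frame <- function(R, G, B) {
  if (!is.matrix(R) || !is.matrix(G) || !is.matrix(B))
    stop("R, G and B must be matrices", call. = FALSE)
  if (!all(dim(R) == dim(G)) || !all(dim(R) == dim(B)))
    stop("channel dimensions differ", call. = FALSE)
  if (nrow(R) < 1L || ncol(R) < 1L)
    stop("frame dimensions must be positive", call. = FALSE)
  vals <- c(R, G, B)
  if (anyNA(vals)) stop("channel values must not be NA", call. = FALSE)
  if (min(vals) < 0 || max(vals) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(list(R = R, G = G, B = B), class = "rgb_frame")
}

#' @export
dim.rgb_frame <- function(x) dim(x$R)

#' @export
print.rgb_frame <- function(x, ...) {
  cat(sprintf("<rgb_frame %d x %d>\n", nrow(x$R), ncol(x$R)))
  invisible(x)
}

#' Strip the peripheral black border from a frame
#'
#' Capsule endoscopy frames carry a meaningless peripheral black region around
#' a circular informative field. This crops the frame to the tight bounding
#' box of non-black content and returns a validity mask that additionally
#' excludes residual black corner pixels inside the crop. A pixel is
#' considered black iff `max(R, G, B) <= black_threshold`.
#'
#' @param frame an [rgb_frame()].
#' @param black_threshold intensity below or at which a pixel counts as black
#'   (default 10, tolerant of sensor noise in the border).
#' @return A list with elements `frame` (the cropped [rgb_frame()]),
#'   `validity` (logical matrix, `TRUE` on informative pixels) and
#'   `rows`/`cols` (the integer index ranges of the crop in the input frame,
#'   useful to crop companion masks).
#' @export
strip_border <- function(frame, black_threshold = 10) {
  stopifnot(inherits(frame, "rgb_frame"))
  if (black_threshold < 0) stop("black_threshold must be nonnegative", call. = FALSE)
  nonblack <- pmax(frame$R, frame$G, frame$B) > black_threshold
  if (!any(nonblack))
    stop("empty frame: every pixel is black at the given threshold", call. = FALSE)
  rr <- range(which(rowSums(nonblack) > 0))
  cc <- range(which(colSums(nonblack) > 0))
  rows <- rr[1]:rr[2]
  cols <- cc[1]:cc[2]
  cropped <- rgb_frame(
    frame$R[rows, cols, drop = FALSE],
    frame$G[rows, cols, drop = FALSE],
    frame$B[rows, cols, drop = FALSE]
  )
  list(
    frame = cropped,
    validity = nonblack[rows, cols, drop = FALSE],
    rows = rows,
    cols = cols
  )
}

#' Crop a companion mask to a stripped frame
#'
#' Applies the crop computed by [strip_border()] to a mask defined on the
#' original (unstripped) frame, e.g. a ground-truth bleeding mask.
#'
#' @param mask logical matrix on the original frame's grid.
#' @param strip the list returned by [strip_border()].
#' @return Logical matrix on the cropped grid.
#' @export
crop_mask <- function(mask, strip) {
  stopifnot(is.matrix(mask))
  mask[strip$rows, strip$cols, drop = FALSE]
}

#' Chromaticity (normalized RGB) frame
#'
#' Holds per-pixel chromaticity components r, g, b in \[0, 1\] with
#' r + g + b = 1 on valid pixels, plus the validity mask.
#'
#' @param r,g,b numeric matrices of chromaticity components.
#' @param valid logical matrix; `FALSE` pixels carry no chromaticity (their
#'   components are stored as 0 and must be ignored).
#' @return An object of class `chrom_frame`.
#' @export
chrom_frame <- function(r, g, b, valid) {
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b)) || !all(dim(r) == dim(valid)))
    stop("component dimensions differ", call. = FALSE)
  if (!is.logical(valid)) stop("valid must be a logical matrix", call. = FALSE)
  vals <- c(r[valid], g[valid], b[valid])
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stop("chromaticity components must lie in [0, 1]", call. = FALSE)
  s <- r[valid] + g[valid] + b[valid]
  if (length(s) && max(abs(s - 1)) > 1e-9)
    stop("chromaticity components must sum to 1 on valid pixels", call. = FALSE)
  structure(list(r = r, g = g, b = b, valid = valid), class = "chrom_frame")
}

#' @export
dim.chrom_frame <- function(x) dim(x$r)

#' Transform an RGB frame to normalized RGB (chromaticity) space
#'
#' Each valid pixel's components are divided by the channel sum,
#' \eqn{r = R/(R+G+B)} and likewise for g and b, removing overall
#' brightness. Pixels with `R + G + B = 0` cannot be normalized and are
#' marked invalid in the output.
#'
#' @param frame an [rgb_frame()].
#' @param validity optional logical matrix restricting which pixels are
#'   informative (e.g. from [strip_border()]); defaults to all pixels.
#' @return A [chrom_frame()].
#' @export
normalize_rgb <- function(frame, validity = NULL) {
  stopifnot(inherits(frame, "rgb_frame"))
  d <- dim(frame)
  if (is.null(validity)) validity <- matrix(TRUE, d[1], d[2])
  if (!all(dim(validity) == d))
    stop("frame and validity mask dimensions differ", call. = FALSE)
  s <- frame$R + frame$G + frame$B
  ok <- validity & s > 0
  r <- g <- b <- matrix(0, d[1], d[2])
  r[ok] <- frame$R[ok] / s[ok]
  g[ok] <- frame$G[ok] / s[ok]
  b[ok] <- frame$B[ok] / s[ok]
  chrom_frame(r, g, b, ok)
}
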