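#' Read an 8-bit RGB image as an rgb_frame
#'
#' PNG is read via the png package, TIFF via the tiff package (if
#' installed). Grayscale images are replicated across channels; an alpha
#' channel, if present, is dropped. Pixel values are rescaled to 0--255.
#'
#' @param path image file path (.png, .tif/.tiff).
#' @return An [rgb_frame()].
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read TIFF files", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  rgb_frame(round(img[, , 1] * 255), round(img[, , 2] * 255),
            round(img[, , 3] * 255))
}

#' Write an rgb_frame as PNG
#'
#' @param frame an [rgb_frame()].
#' @param path output path.
#' @export
write_frame_png <- function(frame, path) {
  stopifnot(inherits(frame, "rgb_frame"))
  arr <- array(c(frame$R, frame$G, frame$B) / 255, c(dim(frame), 3))
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Any nonzero pixel is `TRUE` (masks are conventionally stored as 0/255).
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write a feature matrix (plus labels) as CSV
#'
#' One row per image; feature columns keep their `<plane>_bin_<k>` names and
#' an optional `label` column is appended.
#'
#' @param features numeric matrix with column names.
#' @param path output CSV path.
#' @param labels optional label vector, one per row.
#' @export
write_features_csv <- function(features, path, labels = NULL) {
  df <- as.data.frame(features)
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_features_csv()]
#'
#' @param path CSV path.
#' @return A list with `features` (numeric matrix) and `labels` (or `NULL`).
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  list(features = as.matrix(df), labels = labels)
}

#' Write a slope sweep table as CSV
#'
#' Columns `value`, `mean_accuracy`, `std_accuracy`.
#'
#' @param sweep a `sweep_table` from [sweep_slope()].
#' @param path output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_table"))
  utils::write.csv(sweep$table, path, row.names = FALSE)
  invisible(path)
}
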