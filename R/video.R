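#' Smooth per-frame labels of a continuous video
#'
#' In a continuous bleeding video a single nonbleeding frame sandwiched
#' between two bleeding frames is almost surely a classifier error, so it is
#' relabelled bleeding. The rule is evaluated in a single pass against the
#' input labels (not the partially-updated sequence); bleeding labels are
#' never changed, and the first and last frames are never flipped (they lack
#' a neighbour on one side). Set `iterate = TRUE` to re-apply the rule until
#' a fixed point — off by default, as one application is the intended
#' behaviour.
#'
#' @param labels character vector of `"bleeding"` / `"nonbleeding"` labels in
#'   acquisition order, length >= 1.
#' @param iterate re-apply until no label changes.
#' @return Character vector of smoothed labels, same length.
#' @export
postprocess_labels <- function(labels, iterate = FALSE) {
  if (length(labels) < 1L) stop("label sequence must be nonempty", call. = FALSE)
  bad <- setdiff(unique(labels), c("bleeding", "nonbleeding"))
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  pass <- function(l) {
    n <- length(l)
    if (n < 3L) return(l)
    i <- 2:(n - 1)
    flip <- l[i] == "nonbleeding" & l[i - 1] == "bleeding" & l[i + 1] == "bleeding"
    l[i][flip] <- "bleeding"
    l
  }
  out <- pass(labels)
  if (iterate) {
    repeat {
      nxt <- pass(out)
      if (identical(nxt, out)) break
      out <- nxt
    }
  }
  out
}
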