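#' K-nearest-neighbour prediction
#'
#' Labels each query vector by majority vote among its K Euclidean-nearest
#' training vectors. Vote ties are broken by the single nearest neighbour's
#' label; ties in distance are broken by the lower training index, so
#' predictions are fully deterministic.
#'
#' @param train_x numeric matrix of training vectors (rows).
#' @param train_y label vector, one per training row.
#' @param query numeric vector, or matrix of query rows.
#' @param k neighbour count (1 <= k <= nrow(train_x)).
#' @return A label per query row (same type as `train_y`).
#' @export
knn_predict <- function(train_x, train_y, query, k = 5) {
  train_x <- as.matrix(train_x)
  n <- nrow(train_x)
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (length(train_y) != n)
    stop("train_y length must match nrow(train_x)", call. = FALSE)
  if (k < 1 || k > n) stop("k must lie in [1, nrow(train_x)]", call. = FALSE)
  if (!is.matrix(query)) query <- matrix(query, nrow = 1)
  if (ncol(query) != ncol(train_x))
    stop("query length must match training vector length", call. = FALSE)
  out <- vapply(seq_len(nrow(query)), function(i) {
    d2 <- rowSums(sweep(train_x, 2, query[i, ])^2)
    ord <- order(d2, seq_len(n))  # secondary key: lower index wins distance ties
    votes <- table(train_y[ord[seq_len(k)]])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1L) winners else as.character(train_y[ord[1L]])
  }, character(1))
  if (is.factor(train_y)) factor(out, levels = levels(train_y)) else out
}

#' Frame-level confusion counts
#'
#' Tallies true bleeding (T_b), false nonbleeding (F_nb), true nonbleeding
#' (T_nb) and false bleeding (F_b) detections.
#'
#' @param pred,truth label vectors of equal length.
#' @param positive the bleeding class label (default `"bleeding"`).
#' @return A list of class `confusion_counts` with integer elements `t_b`,
#'   `f_nb`, `t_nb`, `f_b`.
#' @export
confusion_counts <- function(pred, truth, positive = "bleeding") {
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ", call. = FALSE)
  p <- pred == positive
  t <- truth == positive
  structure(
    list(t_b = sum(p & t), f_nb = sum(!p & t),
         t_nb = sum(!p & !t), f_b = sum(p & !t)),
    class = "confusion_counts"
  )
}

#' Frame-level sensitivity, specificity and accuracy
#'
#' `sensitivity = T_b / (T_b + F_nb)`, `specificity = T_nb / (T_nb + F_b)`,
#' `accuracy = (T_b + T_nb) / n`. A metric whose denominator is zero (e.g.
#' specificity on an all-bleeding video) is undefined and reported as `NA`.
#'
#' @param counts a [confusion_counts()].
#' @return A list with elements `sensitivity`, `specificity`, `accuracy`.
#' @export
frame_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  n <- counts$t_b + counts$f_nb + counts$t_nb + counts$f_b
  list(
    sensitivity = ratio(counts$t_b, counts$t_b + counts$f_nb),
    specificity = ratio(counts$t_nb, counts$t_nb + counts$f_b),
    accuracy = ratio(counts$t_b + counts$t_nb, n)
  )
}

#' Stratified fold assignment
#'
#' Assigns samples to folds so that each class is spread as evenly as
#' possible across folds (guards against bleeding-free folds under class
#' imbalance). With `folds = length(labels)` this degenerates to
#' leave-one-out.
#'
#' @param labels class label vector.
#' @param folds number of folds.
#' @param seed integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(labels, folds, seed = 1) {
  n <- length(labels)
  if (folds < 2 || folds > n) stop("folds must lie in [2, n]", call. = FALSE)
  if (folds == n) return(seq_len(n))
  assign <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated KNN classification
#'
#' Predicts every sample exactly once with a model trained on the remaining
#' folds, and pools the confusion counts over folds. Fold assignment is
#' stratified by class (seeded); `folds = nrow(x)` gives leave-one-out.
#'
#' @param x feature matrix (rows = samples).
#' @param y label vector.
#' @param folds number of folds (default 10).
#' @param k KNN neighbour count (default 5).
#' @param seed seed for the fold shuffle.
#' @param positive the bleeding class label.
#' @return A list of class `cv_result`: `predictions`, `fold` (assignment),
#'   `counts` ([confusion_counts()]), `metrics` ([frame_metrics()]).
#' @export
cross_validate <- function(x, y, folds = 10, k = 5, seed = 1,
                           positive = "bleeding") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("label length must match nrow(x)", call. = FALSE)
  fold <- stratified_folds(y, folds, seed = seed)
  sizes <- tabulate(fold, nbins = max(fold))
  if (any(n - sizes < k))
    stop("a training fold has fewer than k samples", call. = FALSE)
  pred <- rep(NA_character_, n)
  for (f in sort(unique(fold))) {
    test <- fold == f
    pred[test] <- knn_predict(x[!test, , drop = FALSE], y[!test],
                              x[test, , drop = FALSE], k = k)
  }
  counts <- confusion_counts(pred, y, positive = positive)
  structure(
    list(predictions = pred, fold = fold, counts = counts,
         metrics = frame_metrics(counts), k = k, folds = folds, seed = seed),
    class = "cv_result"
  )
}
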