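#' Deterministic k-nearest-neighbor classification
#'
#' Euclidean k-NN with fully deterministic tie handling, used both as the
#' MENN editing classifier and as the `knn` pipeline backend. Distance ties
#' resolve to the lowest training-row index; vote ties (possible for even
#' `k`) resolve toward the patient class (label 1). Both rules are fixed so
#' that editing traces and predictions are exactly reproducible.
#'
#' @param train_x numeric matrix of training features.
#' @param train_y integer 0/1 labels for `train_x` rows.
#' @param test_x numeric matrix of query features (same column count).
#' @param k number of neighbors (>= 1, capped at `nrow(train_x)`).
#' @return integer vector of predicted 0/1 labels, one per query row.
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 1L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x))
    stop_data("feature dimension mismatch between training and query sets")
  if (nrow(train_x) == 0L) stop_data("empty training set for k-NN")
  k <- min(as.integer(k), nrow(train_x))
  if (k < 1L) stop_config("k must be >= 1")
  d2 <- sq_dist(test_x, train_x)
  if (k == 1L) {
    # which.min returns the first (lowest-index) minimizer: the tie rule
    nn <- apply(d2, 1L, which.min)
    return(as.integer(train_y[nn]))
  }
  apply(d2, 1L, function(row) {
    nn <- order(row, seq_along(row))[seq_len(k)]
    votes1 <- sum(train_y[nn] == 1L)
    if (votes1 * 2L >= k) 1L else 0L
  })
}

# squared Euclidean distances, queries x references
sq_dist <- function(a, b) {
  d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) +
    matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE) -
    2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
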