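#' Fit and apply z-score standardization
#'
#' Distance-based editing and sigmoid hidden layers both need features on a
#' common scale, so pipelines standardize with parameters fitted on the
#' *training* samples only. `standardize_fit` records the per-feature mean
#' and population standard deviation (denominator `n`); constant features
#' get scale 1 so they map to exactly 0 rather than NaN.
#'
#' @param train a [pd_dataset()] or numeric matrix of training features.
#' @return `standardize_fit`: a `pd_scaler` with `center` and `scale`
#'   vectors; `standardize_apply` / `standardize_invert`: a transformed
#'   copy of `data`.
#' @export
#' @examples
#' sc <- standardize_fit(matrix(c(0, 2, 1, 1), ncol = 2))
#' standardize_apply(sc, matrix(c(0, 2, 1, 1), ncol = 2))
standardize_fit <- function(train) {
  x <- if (inherits(train, "pd_dataset")) features_of(train) else as.matrix(train)
  if (nrow(x) == 0L) stop_data("cannot fit a scaler on an empty dataset")
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
  scale[scale <= 0 | !is.finite(scale)] <- 1
  structure(list(center = center, scale = scale), class = "pd_scaler")
}

#' @rdname standardize_fit
#' @param params a `pd_scaler` from `standardize_fit`.
#' @param data a [pd_dataset()] or feature matrix to transform.
#' @export
standardize_apply <- function(params, data) {
  stopifnot(inherits(params, "pd_scaler"))
  scale_mat <- function(x)
    sweep(sweep(x, 2L, params$center), 2L, params$scale, "/")
  if (inherits(data, "pd_dataset")) {
    d <- dataset_dim(data)
    data[, paste0("f", seq_len(d))] <- scale_mat(features_of(data))
    data
  } else scale_mat(as.matrix(data))
}

#' @rdname standardize_fit
#' @export
standardize_invert <- function(params, data) {
  stopifnot(inherits(params, "pd_scaler"))
  unscale <- function(x)
    sweep(sweep(x, 2L, params$scale, "*"), 2L, params$center, "+")
  if (inherits(data, "pd_dataset")) {
    d <- dataset_dim(data)
    data[, paste0("f", seq_len(d))] <- unscale(features_of(data))
    data
  } else unscale(as.matrix(data))
}
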