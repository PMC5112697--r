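#' Construct a sample-major feature dataset
#'
#' A `pd_dataset` is a plain `data.frame` with one row per speech sample:
#' a `subject_id` column, `d` numeric feature columns `f1..fd`, a binary
#' `label` column (0 = healthy, 1 = patient), and optionally a
#' `sample_kind` factor (vowel, number, sentence, word, unknown). All
#' samples of one subject must carry the same label; feature values must be
#' finite.
#'
#' @param subject_id character or factor vector of subject identifiers.
#' @param features numeric matrix, one row per sample.
#' @param label integer vector of 0/1 class labels (1 = patient).
#' @param sample_kind optional character/factor of per-sample kinds.
#' @return a `pd_dataset` (also a `data.frame`) with attribute `d`.
#' @export
#' @examples
#' x <- matrix(rnorm(12), nrow = 6)
#' pd_dataset(rep(c("a", "b"), each = 3), x, rep(c(0L, 1L), each = 3))
pd_dataset <- function(subject_id, features, label, sample_kind = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (length(subject_id) != n || length(label) != n)
    stop_data("subject_id, features and label must have one entry per sample")
  if (n > 0 && !all(is.finite(features)))
    stop_data("non-finite feature values in rows: ",
              paste(utils::head(which(!stats::complete.cases(features) |
                                        rowSums(!is.finite(features)) > 0), 5),
                    collapse = ", "))
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L)))
    stop_data("labels must be coded 0 (healthy) / 1 (patient)")
  d <- ncol(features)
  colnames(features) <- paste0("f", seq_len(d))
  out <- data.frame(subject_id = as.character(subject_id), features,
                    label = label, stringsAsFactors = FALSE)
  if (!is.null(sample_kind)) {
    kinds <- c("vowel", "number", "sentence", "word", "unknown")
    sk <- as.character(sample_kind)
    sk[!sk %in% kinds] <- "unknown"
    out$sample_kind <- factor(sk, levels = kinds)
  }
  validate_subject_labels(out)
  structure(out, d = d, class = c("pd_dataset", "data.frame"))
}

validate_subject_labels <- function(df) {
  nlab <- tapply(df$label, df$subject_id, function(l) length(unique(l)))
  bad <- names(nlab)[nlab > 1]
  if (length(bad))
    stop_data("subjects with conflicting labels: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' @export
print.pd_dataset <- function(x, ...) {
  cat(sprintf("pd_dataset: %d samples, %d subjects, d = %d features\n",
              nrow(x), length(unique(x$subject_id)), dataset_dim(x)))
  tab <- table(labels_of(x)[!duplicated(x$subject_id)])
  cat(sprintf("  subjects per class: healthy %d, patient %d\n",
              sum(x$label[!duplicated(x$subject_id)] == 0),
              sum(x$label[!duplicated(x$subject_id)] == 1)))
  invisible(x)
}

#' Accessors for `pd_dataset` columns
#'
#' @param data a [pd_dataset()].
#' @return `features_of`: the numeric `n x d` feature matrix; `labels_of`:
#'   the integer 0/1 label vector; `subjects_of`: the character subject-id
#'   vector; `dataset_dim`: the feature dimension `d`.
#' @export
features_of <- function(data) {
  as.matrix(data[, paste0("f", seq_len(dataset_dim(data))), drop = FALSE])
}

#' @rdname features_of
#' @export
labels_of <- function(data) data$label

#' @rdname features_of
#' @export
subjects_of <- function(data) data$subject_id

#' @rdname features_of
#' @export
dataset_dim <- function(data) {
  d <- attr(data, "d")
  if (is.null(d)) d <- sum(grepl("^f[0-9]+$", names(data)))
  d
}

#' Row-subset a dataset, keeping its class and dimension
#'
#' @param data a [pd_dataset()].
#' @param idx logical mask or integer row indices.
#' @return the subsetted `pd_dataset` (row names reset).
#' @export
subset_dataset <- function(data, idx) {
  out <- data[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, d = dataset_dim(data), class = class(data))
}

#' Column layouts for the UCI Parkinson speech feature tables
#'
#' The public Sakar et al. deposit ("Parkinson speech dataset with multiple
#' types of sound recordings") ships two delimited-text files. The training
#' file has 29 columns: subject id, 26 acoustic features, a UPDRS severity
#' score (ignored here), and the class label. The test file omits the
#' severity column. These helpers return the matching layout descriptors
#' for [read_sakar()]; `sakar_layout()` builds a custom one.
#'
#' @param id_col 1-based column index of the subject identifier.
#' @param feature_cols integer vector of feature column indices.
#' @param label_col column index of the class label.
#' @param ignore_cols columns to skip (e.g. a severity score).
#' @param kind_from_position if `TRUE`, assign each subject's i-th sample a
#'   `sample_kind` by recording-protocol position (1-3 sustained vowels,
#'   4-13 numbers, 14-17 sentences, 18-26 words).
#' @return a `sakar_layout` list.
#' @export
sakar_layout <- function(id_col, feature_cols, label_col,
                         ignore_cols = integer(), kind_from_position = FALSE) {
  stopifnot(length(id_col) == 1L, length(label_col) == 1L,
            length(feature_cols) >= 1L)
  structure(list(id_col = as.integer(id_col),
                 feature_cols = as.integer(feature_cols),
                 label_col = as.integer(label_col),
                 ignore_cols = as.integer(ignore_cols),
                 kind_from_position = isTRUE(kind_from_position)),
            class = "sakar_layout")
}

#' @rdname sakar_layout
#' @export
sakar_layout_train <- function() {
  sakar_layout(id_col = 1L, feature_cols = 2:27, label_col = 29L,
               ignore_cols = 28L, kind_from_position = TRUE)
}

#' @rdname sakar_layout
#' @export
sakar_layout_test <- function() {
  sakar_layout(id_col = 1L, feature_cols = 2:27, label_col = 28L)
}

#' Sample kind by protocol position
#'
#' Maps the position of a sample within its subject's 26-recording session
#' to the recording type: sustained vowels (1-3), spoken numbers (4-13),
#' short sentences (14-17), words (18-26).
#'
#' @param i integer position(s) within the subject, 1-based.
#' @return character vector of kinds.
#' @export
sakar_sample_kind <- function(i) {
  k <- rep("unknown", length(i))
  k[i >= 1 & i <= 3] <- "vowel"
  k[i >= 4 & i <= 13] <- "number"
  k[i >= 14 & i <= 17] <- "sentence"
  k[i >= 18 & i <= 26] <- "word"
  k
}

#' Read a delimited Sakar-style feature table
#'
#' Parses a comma- or whitespace-delimited text file with one speech sample
#' per row into a [pd_dataset()]. Labels are normalized to 0 = healthy,
#' 1 = patient; any source coding with exactly two distinct values is
#' accepted when `label_map` names them, otherwise labels must already be
#' 0/1. Malformed rows (wrong column count, non-numeric feature) raise a
#' parse error naming the offending line; subjects whose rows disagree on
#' the label raise a validation error.
#'
#' @param path path to the delimited text file.
#' @param layout a [sakar_layout()]; default matches the UCI training file.
#' @param sep field separator: `","` (default) or `""` for whitespace.
#' @param header does the file carry a header line?
#' @param label_map optional named vector mapping source label values to
#'   0/1, e.g. `c(H = 0, P = 1)`.
#' @return a [pd_dataset()].
#' @export
read_sakar <- function(path, layout = sakar_layout_train(), sep = ",",
                       header = FALSE, label_map = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           blank.lines.skip = TRUE)
  offset <- if (header) 1L else 0L
  needed <- max(layout$id_col, layout$feature_cols, layout$label_col)
  if (ncol(raw) < needed)
    stop_data("file has ", ncol(raw), " columns but the layout needs ", needed)
  # rows padded by fill= show up as "" in trailing columns
  short <- which(apply(raw[, seq_len(needed), drop = FALSE], 1L,
                       function(r) any(is.na(r) | r == "")))
  if (length(short))
    stop_data("malformed row (wrong column count) at line ",
              short[1] + offset)
  feat_chr <- as.matrix(raw[, layout$feature_cols, drop = FALSE])
  feat <- suppressWarnings(matrix(as.numeric(feat_chr), nrow = nrow(raw)))
  bad <- which(rowSums(is.na(feat)) > 0)
  if (length(bad)) {
    col_bad <- which(is.na(feat[bad[1], ]))[1]
    stop_data("non-numeric feature value ",
              shQuote(feat_chr[bad[1], col_bad]), " at line ",
              bad[1] + offset)
  }
  lab_chr <- raw[[layout$label_col]]
  if (!is.null(label_map)) {
    if (!all(lab_chr %in% names(label_map)))
      stop_data("labels outside label_map at line ",
                which(!lab_chr %in% names(label_map))[1] + offset)
    lab <- as.integer(label_map[lab_chr])
  } else {
    lab <- suppressWarnings(as.numeric(lab_chr))
    if (any(is.na(lab)) || !all(lab %in% c(0, 1)))
      stop_data("labels must be 0/1 (or supply label_map); first bad line ",
                which(is.na(lab) | !lab %in% c(0, 1))[1] + offset)
    lab <- as.integer(lab)
  }
  ids <- raw[[layout$id_col]]
  kind <- NULL
  if (isTRUE(layout$kind_from_position)) {
    pos <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    kind <- sakar_sample_kind(pos)
  }
  pd_dataset(ids, feat, lab, sample_kind = kind)
}

#' Write a dataset as CSV
#'
#' Serializes a [pd_dataset()] with header `subject_id, f1..fd, label`
#' (plus `sample_kind` and any extra columns when `extras = TRUE`). The
#' output re-reads losslessly with [read_dataset_csv()] for finite decimal
#' inputs.
#'
#' @param data a [pd_dataset()].
#' @param path output file path.
#' @param extras keep non-standard columns (e.g. the synthetic generator's
#'   `is_contaminated` flag)?
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, extras = FALSE) {
  cols <- c("subject_id", paste0("f", seq_len(dataset_dim(data))), "label")
  if (extras) cols <- union(cols, names(data))
  df <- as.data.frame(data)[, intersect(cols, names(data)), drop = FALSE]
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param ... passed through to the reader.
#' @export
read_dataset_csv <- function(path, ...) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE, ...)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  pd_dataset(df$subject_id, as.matrix(df[, fcols, drop = FALSE]), df$label,
             sample_kind = df$sample_kind)
}
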