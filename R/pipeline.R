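#' Configure a MENN + classifier pipeline
#'
#' A pipeline optionally edits the training set with [multi_edit()] and
#' then trains one of five classifier backends on the retained samples:
#' `"dnne"` (the closed-form decorrelated RVFL ensemble), `"rf"` (random
#' forest, 500 trees by default), `"svm_linear"` / `"svm_rbf"` (libsvm via
#' e1071), or `"knn"` (the package's deterministic k-NN, k = 1 by
#' default). MENN always edits on standardized features — editing is
#' distance-based — while `scale_features` controls whether the backend
#' itself sees standardized inputs (trees are scale-invariant, so `rf`
#' commonly runs on raw features).
#'
#' One `seed` drives everything: the MENN partition seed, the backend seed
#' and any subsampling seeds are derived from it by fixed stream offsets
#' (see [derive_seed()]), so a (dataset, config) pair fully determines the
#' trained pipeline and its predictions.
#'
#' @param backend one of `"dnne"`, `"rf"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"knn"`.
#' @param use_menn edit the training set first?
#' @param menn list of MENN settings: `s` (default 4), `k` (1),
#'   `max_iter` (20), `stratify` (FALSE).
#' @param backend_params backend-specific settings: `rf`: `ntree` (500),
#'   `mtry` (sqrt(d)); `dnne`: `M` (5), `L` (20), `lambda` (0.5),
#'   `bag_fraction` (1); `svm_*`: `cost` (1), `gamma` (1/d); `knn`:
#'   `k` (1).
#' @param scale_features standardize features for the backend? Default
#'   `TRUE` except for `"rf"`.
#' @param tie_rule subject-vote tie handling for [predict_subjects()]:
#'   `"patient"` (default), `"healthy"`, or `"by_mean_score"`.
#' @param seed integer master seed.
#' @return a `pipeline_config` list.
#' @export
#' @examples
#' pipeline_config("knn", use_menn = TRUE, seed = 7)
pipeline_config <- function(backend = c("dnne", "rf", "svm_linear",
                                        "svm_rbf", "knn"),
                            use_menn = TRUE, menn = list(),
                            backend_params = list(),
                            scale_features = !identical(backend[1], "rf"),
                            tie_rule = c("patient", "healthy",
                                         "by_mean_score"),
                            seed = 1L) {
  backend <- match.arg(backend)
  tie_rule <- match.arg(tie_rule)
  menn_def <- list(s = 4L, k = 1L, max_iter = 20L, stratify = FALSE)
  menn <- utils::modifyList(menn_def, menn)
  bp_def <- switch(backend,
    rf = list(ntree = 500L, mtry = NULL),
    dnne = list(M = 5L, L = 20L, lambda = 0.5, bag_fraction = 1),
    svm_linear = list(cost = 1),
    svm_rbf = list(cost = 1, gamma = NULL),
    knn = list(k = 1L))
  extra <- setdiff(names(backend_params), names(bp_def))
  if (length(extra))
    stop_config("unknown backend_params for ", backend, ": ",
                paste(extra, collapse = ", "))
  structure(list(backend = backend, use_menn = isTRUE(use_menn),
                 menn = menn,
                 backend_params = utils::modifyList(bp_def, backend_params),
                 scale_features = isTRUE(scale_features),
                 tie_rule = tie_rule, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Train a MENN + classifier pipeline
#'
#' Runs the editing stage (when enabled) on the training set, drops the
#' removed samples, fits the scaler on the retained samples (when
#' enabled), and trains the configured backend. Training aborts with a
#' diagnostic if editing is so aggressive that a class would be emptied.
#'
#' @param train a [pd_dataset()] with both classes present.
#' @param config a [pipeline_config()].
#' @return a `pd_pipeline` with the config, edit trace (or `NULL`),
#'   scaler (or `NULL`), the backend model, and a `training_summary` of
#'   per-class counts before and after editing.
#' @export
train_pipeline <- function(train, config) {
  stopifnot(inherits(train, "pd_dataset"), inherits(config, "pipeline_config"))
  y <- labels_of(train)
  if (length(unique(y)) < 2L)
    stop_data("training data must contain both classes")
  before <- c(healthy = sum(y == 0L), patient = sum(y == 1L))

  trace <- NULL
  retained <- train
  if (config$use_menn) {
    trace <- multi_edit(train, s = config$menn$s, k = config$menn$k,
                        seed = derive_seed(config$seed, 101L),
                        max_iter = config$menn$max_iter,
                        stratify = config$menn$stratify)
    retained <- subset_dataset(train, trace$retained)
  }
  yr <- labels_of(retained)
  if (length(unique(yr)) < 2L)
    stop_data("editing left a single class; cannot train a classifier")
  after <- c(healthy = sum(yr == 0L), patient = sum(yr == 1L))

  xr <- features_of(retained)
  scaler <- NULL
  if (config$scale_features) {
    scaler <- standardize_fit(xr)
    xr <- standardize_apply(scaler, xr)
  }
  backend_seed <- derive_seed(config$seed, 202L)
  bp <- config$backend_params
  model <- switch(config$backend,
    knn = list(x = xr, y = yr, k = bp$k),
    dnne = dnne_train(xr, yr, M = bp$M, L = bp$L, lambda = bp$lambda,
                      seed = backend_seed, bag_fraction = bp$bag_fraction,
                      standardize = FALSE),
    rf = local_seed(backend_seed,
      randomForest::randomForest(
        x = xr, y = factor(yr, levels = c(0L, 1L)),
        ntree = bp$ntree,
        mtry = bp$mtry %||% max(1L, floor(sqrt(ncol(xr)))))),
    svm_linear = e1071::svm(x = xr, y = factor(yr, levels = c(0L, 1L)),
                            kernel = "linear", cost = bp$cost,
                            scale = FALSE),
    svm_rbf = e1071::svm(x = xr, y = factor(yr, levels = c(0L, 1L)),
                         kernel = "radial", cost = bp$cost,
                         gamma = bp$gamma %||% 1 / ncol(xr),
                         scale = FALSE))
  structure(list(config = config, edit_trace = trace, scaler = scaler,
                 model = model, d = dataset_dim(train),
                 training_summary = list(before = before, after = after)),
            class = "pd_pipeline")
}

#' @export
print.pd_pipeline <- function(x, ...) {
  s <- x$training_summary
  cat(sprintf(
    "pd_pipeline [%s%s]: trained on %d/%d samples (healthy %d->%d, patient %d->%d)\n",
    if (x$config$use_menn) "MENN + " else "", x$config$backend,
    sum(s$after), sum(s$before),
    s$before["healthy"], s$after["healthy"],
    s$before["patient"], s$after["patient"]))
  invisible(x)
}

#' Per-sample predictions from a trained pipeline
#'
#' Applies the stored scaler (if any) and the backend to new samples.
#' Deterministic given the trained pipeline; row order in equals row order
#' out.
#'
#' @param pipeline a `pd_pipeline` from [train_pipeline()].
#' @param data a [pd_dataset()] or feature matrix.
#' @return list with integer `label` (0/1 per sample) and numeric `score`
#'   (`NA` for backends without a natural score).
#' @export
predict_samples <- function(pipeline, data) {
  stopifnot(inherits(pipeline, "pd_pipeline"))
  x <- if (inherits(data, "pd_dataset")) features_of(data) else as.matrix(data)
  if (ncol(x) != pipeline$d)
    stop_data("data has ", ncol(x), " features; pipeline expects ",
              pipeline$d)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(pipeline$scaler)) x <- standardize_apply(pipeline$scaler, x)
  m <- pipeline$model
  switch(pipeline$config$backend,
    knn = list(label = knn_classify(m$x, m$y, x, k = m$k),
               score = rep(NA_real_, nrow(x))),
    dnne = {
      p <- predict(m, x)
      list(label = p$label, score = p$score)
    },
    rf = {
      pr <- predict(m, x, type = "prob")[, "1"]
      list(label = as.integer(pr >= 0.5), score = as.numeric(pr))
    },
    {
      # svm backends
      dv <- attr(predict(m, x, decision.values = TRUE), "decision.values")
      lab <- as.integer(as.character(predict(m, x)))
      sc <- as.numeric(dv[, 1])
      # orient the decision value so larger means "patient"
      if (grepl("^0", colnames(dv)[1])) sc <- -sc
      list(label = lab, score = sc)
    })
}

#' @export
predict.pd_pipeline <- function(object, newdata, ...) {
  predict_samples(object, newdata)
}

#' Subject-level decisions by majority vote
#'
#' Aggregates per-sample predictions to one decision per subject: a
#' subject is deemed a patient when the majority of its samples are
#' predicted patient. Ties (possible with an even per-subject sample
#' count) follow the tie rule — `"patient"` (default, favors sensitivity
#' in a screening context), `"healthy"`, or `"by_mean_score"` (mean sample
#' score against the backend threshold, falling back to patient when no
#' scores exist).
#'
#' @param pipeline a `pd_pipeline`.
#' @param data a [pd_dataset()] carrying subject ids.
#' @param tie_rule overrides the config's tie rule when given.
#' @param sample_pred optional precomputed result of
#'   [predict_samples()] on `data` (avoids re-predicting).
#' @return data.frame with `subject_id`, `label` (true subject label),
#'   `pred` (voted 0/1), `votes_patient`, `n_samples`.
#' @export
predict_subjects <- function(pipeline, data, tie_rule = NULL,
                             sample_pred = NULL) {
  stopifnot(inherits(data, "pd_dataset"))
  tie_rule <- tie_rule %||% pipeline$config$tie_rule
  sp <- sample_pred %||% predict_samples(pipeline, data)
  vote_subjects(subjects_of(data), labels_of(data), sp$label, sp$score,
                tie_rule)
}

#' Majority vote over arbitrary per-sample predictions
#'
#' The voting core behind [predict_subjects()], exposed directly so that
#' cross-validated per-sample predictions (or any other source) can be
#' aggregated to subject decisions.
#'
#' @param subject subject id per sample.
#' @param y_true true 0/1 label per sample (subject-consistent).
#' @param y_pred predicted 0/1 label per sample.
#' @param score optional numeric score per sample (used by the
#'   `"by_mean_score"` tie rule).
#' @param tie_rule `"patient"`, `"healthy"` or `"by_mean_score"`.
#' @return data.frame with one row per subject: `subject_id`, `label`,
#'   `pred`, `votes_patient`, `n_samples`.
#' @export
vote_subjects <- function(subject, y_true, y_pred, score = NULL,
                          tie_rule = "patient") {
  ids <- unique(subject)
  out <- data.frame(subject_id = ids,
                    label = NA_integer_, pred = NA_integer_,
                    votes_patient = NA_integer_, n_samples = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    j <- subject == ids[i]
    v1 <- sum(y_pred[j] == 1L)
    n <- sum(j)
    pred <- if (2L * v1 > n) 1L
            else if (2L * v1 < n) 0L
            else switch(tie_rule,
                        patient = 1L,
                        healthy = 0L,
                        by_mean_score = {
                          ms <- if (is.null(score)) NA_real_
                                else mean(score[j])
                          if (is.finite(ms)) as.integer(ms >= 0.5) else 1L
                        })
    out$label[i] <- y_true[j][1]
    out$pred[i] <- pred
    out$votes_patient[i] <- v1
    out$n_samples[i] <- n
  }
  out
}

#' Save / load a trained pipeline bundle
#'
#' Serializes a trained pipeline to a directory: `config.json`,
#' `edit_trace.json` (when present), and a backend model file. The `knn`
#' and `dnne` backends round-trip bit-exactly through plain JSON; `rf` and
#' `svm` backends are stored via base R serialization (`.rds`).
#'
#' @param pipeline a `pd_pipeline`.
#' @param dir bundle directory (created if missing).
#' @return `save_pipeline`: `dir` invisibly; `load_pipeline`: the
#'   restored `pd_pipeline`.
#' @export
save_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "pd_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(pipeline$config)
  meta <- list(config = cfg, d = pipeline$d,
               training_summary = lapply(pipeline$training_summary, as.list),
               scaler = if (!is.null(pipeline$scaler))
                 list(center = pipeline$scaler$center,
                      scale = pipeline$scaler$scale))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "config.json"))
  if (!is.null(pipeline$edit_trace))
    menn_trace_json(pipeline$edit_trace, file.path(dir, "edit_trace.json"))
  m <- pipeline$model
  if (pipeline$config$backend == "knn") {
    writeLines(jsonlite::toJSON(list(x = m$x, y = m$y, k = m$k),
                                digits = NA, auto_unbox = TRUE),
               file.path(dir, "model_knn.json"))
  } else if (pipeline$config$backend == "dnne") {
    writeLines(jsonlite::toJSON(
      list(weights = m$spec$weights, biases = m$spec$biases,
           M = m$spec$M, L = m$spec$L, d = m$spec$d,
           lambda = m$spec$lambda, seed = m$spec$seed,
           B_ens = m$B_ens, threshold = m$threshold,
           scaler = if (!is.null(m$scaler))
             list(center = m$scaler$center, scale = m$scaler$scale),
           solver_note = m$solver_note),
      digits = NA, auto_unbox = TRUE, null = "null"),
      file.path(dir, "model_dnne.json"))
  } else {
    saveRDS(m, file.path(dir, "model.rds"))
  }
  invisible(dir)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg <- pipeline_config(backend = meta$config$backend,
                         use_menn = meta$config$use_menn,
                         menn = meta$config$menn,
                         backend_params = meta$config$backend_params,
                         scale_features = meta$config$scale_features,
                         tie_rule = meta$config$tie_rule,
                         seed = meta$config$seed)
  scaler <- NULL
  if (!is.null(meta$scaler))
    scaler <- structure(list(center = meta$scaler$center,
                             scale = meta$scaler$scale),
                        class = "pd_scaler")
  trace <- NULL
  tf <- file.path(dir, "edit_trace.json")
  if (file.exists(tf)) {
    tj <- jsonlite::fromJSON(tf, simplifyVector = TRUE)
    trace <- structure(list(retained = tj$retained, iterations = list(),
                            s = tj$s, k = tj$k, seed = tj$seed,
                            converged = tj$converged, flagged = tj$flagged),
                       class = "menn_trace")
  }
  model <- if (cfg$backend == "knn") {
    mj <- jsonlite::fromJSON(file.path(dir, "model_knn.json"))
    list(x = as.matrix(mj$x), y = as.integer(mj$y), k = as.integer(mj$k))
  } else if (cfg$backend == "dnne") {
    mj <- jsonlite::fromJSON(file.path(dir, "model_dnne.json"))
    spec <- structure(list(weights = as.matrix(mj$weights),
                           biases = mj$biases, M = mj$M, L = mj$L,
                           d = mj$d, lambda = mj$lambda,
                           base_function = "sigmoid", seed = mj$seed),
                      class = "rvfl_spec")
    msc <- NULL
    if (!is.null(mj$scaler))
      msc <- structure(list(center = mj$scaler$center,
                            scale = mj$scaler$scale), class = "pd_scaler")
    structure(list(spec = spec, B_ens = mj$B_ens, scaler = msc,
                   threshold = mj$threshold, solver_note = mj$solver_note),
              class = "dnne_model")
  } else readRDS(file.path(dir, "model.rds"))
  ts <- meta$training_summary
  structure(list(config = cfg, edit_trace = trace, scaler = scaler,
                 model = model, d = meta$d,
                 training_summary = list(
                   before = unlist(ts$before), after = unlist(ts$after))),
            class = "pd_pipeline")
}
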