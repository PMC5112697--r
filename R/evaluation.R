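#' Confusion-matrix metrics with patient as the positive class
#'
#' Computes TP/TN/FP/FN and the three headline rates: accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, sensitivity (true positive rate)
#' `TP/(TP+FN)`, and specificity (true negative rate) `TN/(TN+FP)`.
#' A rate whose denominator is zero (e.g. specificity on an all-patient
#' test set) is reported as `NA`, never silently as 0.
#'
#' @param y_true integer 0/1 true labels (1 = patient = positive).
#' @param y_pred integer 0/1 predicted labels.
#' @return a `metrics_report` list: `TP`, `TN`, `FP`, `FN`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_data("y_true and y_pred lengths differ")
  if (length(y_true) == 0L) stop_data("empty prediction vectors")
  keep <- !is.na(y_pred)
  y_true <- y_true[keep]; y_pred <- y_pred[keep]
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop_data("labels must be 0/1")
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = rate(tp + tn, tp + tn + fp + fn),
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics: ACC %.4f  SEN %s  SPE %s  (TP %d FN %d TN %d FP %d)\n",
    x$accuracy,
    ifelse(is.na(x$sensitivity), "NA", sprintf("%.4f", x$sensitivity)),
    ifelse(is.na(x$specificity), "NA", sprintf("%.4f", x$specificity)),
    x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

# assemble a cv_result from per-fold predictions
make_cv_result <- function(protocol, data, config, pred, fold_id, folds,
                           subject_level = FALSE, failed_folds = integer()) {
  y <- labels_of(data)
  ok <- !is.na(pred)
  res <- list(protocol = protocol,
              pred = pred, fold_id = fold_id, folds = folds,
              y_true = y, subject = subjects_of(data),
              sample_metrics = confusion_metrics(y[ok], pred[ok]),
              subject_metrics = NULL, subject_table = NULL,
              config = config, seed = config$seed,
              failed_folds = failed_folds)
  if (subject_level) {
    st <- vote_subjects(subjects_of(data)[ok], y[ok], pred[ok],
                        tie_rule = config$tie_rule)
    res$subject_table <- st
    res$subject_metrics <- confusion_metrics(st$label, st$pred)
  }
  structure(res, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s], %d samples%s\n", x$protocol, length(x$pred),
              if (length(x$failed_folds))
                sprintf(" (%d failed folds)", length(x$failed_folds))
              else ""))
  cat("  sample  "); print(x$sample_metrics)
  if (!is.null(x$subject_metrics)) {
    cat("  subject "); print(x$subject_metrics)
  }
  invisible(x)
}

# core fold loop shared by all protocols: `fold_of` maps each sample to a
# fold; training excludes the whole fold of the predicted sample.
run_folds <- function(data, config, fold_of, protocol,
                      subject_level = FALSE) {
  n <- nrow(data)
  pred <- rep(NA_integer_, n)
  folds <- vector("list", length(unique(fold_of)))
  failed <- integer()
  uf <- sort(unique(fold_of))
  for (fi in seq_along(uf)) {
    f <- uf[fi]
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    folds[[fi]] <- list(fold = f, test = test_idx, train = train_idx)
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, 1000L + fi)
    fit <- tryCatch(
      train_pipeline(subset_dataset(data, train_idx), cfg_f),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, f)
      warning("fold ", f, " failed: ", conditionMessage(fit), call. = FALSE)
      next
    }
    pred[test_idx] <-
      predict_samples(fit, subset_dataset(data, test_idx))$label
  }
  make_cv_result(protocol, data, config, pred, fold_of, folds,
                 subject_level = subject_level, failed_folds = failed)
}

#' Leave-one-out cross-validation
#'
#' For each sample the full pipeline — MENN editing included, re-run
#' inside every fold so no selection information leaks — is trained on the
#' other `N - 1` samples and predicts the held-out sample. Samples from
#' the same subject *remain* in the training fold; that within-subject
#' leakage is exactly what [run_independent()] removes.
#'
#' @param data a [pd_dataset()] with both classes.
#' @param config a [pipeline_config()]; per-fold seeds derive from
#'   `config$seed`.
#' @return a `cv_result` with per-sample predictions, fold provenance and
#'   sample-level metrics.
#' @export
run_loo <- function(data, config) {
  if (nrow(data) < 2L || length(unique(labels_of(data))) < 2L)
    stop_data("LOO needs at least two samples and both classes")
  run_folds(data, config, seq_len(nrow(data)), "loo")
}

#' Leave-one-subject-out evaluation
#'
#' Computes the per-sample leave-one-out predictions of [run_loo()] and
#' aggregates each subject's predictions into one decision by majority
#' vote (patient if most samples are predicted patient). Subject-level and
#' sample-level metrics are both reported. Note that training folds still
#' contain the other samples of the test sample's subject; the
#' subject-independent protocol is [run_independent()].
#'
#' @inheritParams run_loo
#' @return a `cv_result` with `subject_table` and `subject_metrics`.
#' @export
run_loso <- function(data, config) {
  if (length(unique(subjects_of(data))) < 2L ||
      length(unique(labels_of(data))) < 2L)
    stop_data("LOSO needs at least two subjects and both classes")
  run_folds(data, config, seq_len(nrow(data)), "loso",
            subject_level = TRUE)
}

#' Subject-independent cross-validation
#'
#' Each fold holds out *all* samples of one subject: the training set
#' never contains any sample from the predicted sample's subject, so
#' within-subject leakage is eliminated. `level = "sample"` reports
#' sample-level metrics; `level = "subject"` additionally aggregates each
#' held-out subject's predictions by majority vote.
#'
#' @inheritParams run_loo
#' @param level report at `"sample"` or `"subject"` level.
#' @return a `cv_result`.
#' @export
run_independent <- function(data, config, level = c("sample", "subject")) {
  level <- match.arg(level)
  if (length(unique(subjects_of(data))) < 2L)
    stop_data("independent protocol needs at least two subjects")
  fold_of <- as.integer(factor(subjects_of(data),
                               levels = unique(subjects_of(data))))
  run_folds(data, config, fold_of,
            paste0("independent_", level),
            subject_level = identical(level, "subject"))
}

#' Repeated evaluation runs with re-randomized seeds
#'
#' Executes a protocol `n_runs` times with seeds `base_seed + 1` through
#' `base_seed + n_runs` (each run re-randomizes both the MENN partitions
#' and the backend), returning the run-level metric reports plus
#' mean / standard deviation / best summaries in the conventional
#' Mean-Std-Best layout. Undefined metrics are excluded from the
#' summaries, with the exclusion count recorded.
#'
#' @param data a [pd_dataset()].
#' @param config a [pipeline_config()]; its seed is replaced per run.
#' @param protocol `"loo"`, `"loso"`, `"independent_sample"` or
#'   `"independent_subject"`.
#' @param n_runs number of runs (>= 1); the reference experiments use 10.
#' @param base_seed integer; run `r` uses seed `base_seed + r`.
#' @param level `"sample"` or `"subject"`: which metrics feed the summary
#'   (subject metrics exist only for loso / independent_subject).
#' @return list with `runs` (per-run `metrics_report`s), `results` (full
#'   `cv_result`s), `summary` (data.frame: metric x Mean/Std/Best) and
#'   `n_undefined` counts.
#' @export
repeated_runs <- function(data, config,
                          protocol = c("loso", "loo", "independent_sample",
                                       "independent_subject"),
                          n_runs = 10L, base_seed = 0L,
                          level = NULL) {
  protocol <- match.arg(protocol)
  if (n_runs < 1L) stop_config("n_runs must be >= 1")
  level <- level %||%
    if (protocol %in% c("loso", "independent_subject")) "subject" else "sample"
  results <- vector("list", n_runs)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    res <- tryCatch(switch(protocol,
      loo = run_loo(data, cfg),
      loso = run_loso(data, cfg),
      independent_sample = run_independent(data, cfg, "sample"),
      independent_subject = run_independent(data, cfg, "subject")),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("run ", r, " failed: ", conditionMessage(res), call. = FALSE)
      next
    }
    results[[r]] <- res
    runs[[r]] <- if (level == "subject" && !is.null(res$subject_metrics))
      res$subject_metrics else res$sample_metrics
  }
  done <- !vapply(runs, is.null, TRUE)
  if (!any(done)) stop_data("every run failed")
  list(runs = runs[done], results = results[done],
       summary = summarize_runs(runs[done]),
       protocol = protocol, level = level,
       n_failed = sum(!done))
}

#' Summarize run-level metric reports
#'
#' @param runs list of `metrics_report`s (as produced by
#'   [repeated_runs()]).
#' @return data.frame with rows accuracy/sensitivity/specificity and
#'   columns Mean, Std, Best, n, n_undefined.
#' @export
summarize_runs <- function(runs) {
  metric <- c("accuracy", "sensitivity", "specificity")
  do.call(rbind, lapply(metric, function(m) {
    v <- vapply(runs, function(r) r[[m]], numeric(1))
    ok <- !is.na(v)
    data.frame(metric = m,
               Mean = if (any(ok)) mean(v[ok]) else NA_real_,
               Std = if (sum(ok) > 1) stats::sd(v[ok]) else
                 if (any(ok)) 0 else NA_real_,
               Best = if (any(ok)) max(v[ok]) else NA_real_,
               n = sum(ok), n_undefined = sum(!ok),
               stringsAsFactors = FALSE)
  }))
}

#' Between-algorithm significance test over repeated runs
#'
#' Welch's two-sided two-sample t-test on run-level metric values of two
#' algorithms, one p-value per metric — the conventional way of asking
#' whether the accuracy/sensitivity/specificity difference across, say,
#' ten repeated runs is larger than the run-to-run noise. When both run
#' sets are constant the t statistic is undefined: equal constants give
#' p = 1, different constants give p = 0, and either case is flagged as
#' degenerate.
#'
#' @param runs_a,runs_b either lists of `metrics_report`s or plain numeric
#'   vectors of a single metric.
#' @param metrics metric names to compare when reports are supplied.
#' @return a `comparison_report` data.frame: metric, p_value, mean_a,
#'   mean_b, n_a, n_b, degenerate.
#' @export
#' @examples
#' compare_algorithms(c(0.9, 0.91, 0.89, 0.9), c(0.5, 0.52, 0.49, 0.51))
compare_algorithms <- function(runs_a, runs_b,
                               metrics = c("accuracy", "sensitivity",
                                           "specificity")) {
  pull <- function(runs, m) {
    if (is.numeric(runs)) runs
    else vapply(runs, function(r) r[[m]], numeric(1))
  }
  if (is.numeric(runs_a)) metrics <- "value"
  out <- do.call(rbind, lapply(metrics, function(m) {
    a <- pull(runs_a, m); b <- pull(runs_b, m)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      stop_data("need at least two finite runs per algorithm for ", m)
    degen <- stats::var(a) == 0 && stats::var(b) == 0
    p <- if (degen) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = FALSE,
                    alternative = "two.sided")$p.value
    }
    data.frame(metric = m, p_value = p, mean_a = mean(a), mean_b = mean(b),
               n_a = length(a), n_b = length(b), degenerate = degen,
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("comparison_report", "data.frame"))
}

#' Check the structural hygiene of a cross-validation result
#'
#' Verifies, for every fold, that the predicted samples are absent from
#' their own training fold (and, for subject-grouped folds, that no
#' same-subject sample is present either), that every sample was predicted
#' exactly once, and that the metric identities hold (accuracy equals the
#' prevalence-weighted mean of sensitivity and specificity). Intended for
#' tests and audits; errors on the first violation.
#'
#' @param result a `cv_result`.
#' @return `TRUE` invisibly.
#' @export
check_cv_hygiene <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  n <- length(result$pred)
  covered <- integer(n)
  subj <- result$subject
  independent <- grepl("^independent", result$protocol)
  for (f in result$folds) {
    if (length(intersect(f$test, f$train)))
      stop_data("fold ", f$fold, ": test samples inside the training fold")
    if (independent &&
        length(intersect(unique(subj[f$test]), unique(subj[f$train]))))
      stop_data("fold ", f$fold, ": same-subject samples leak into training")
    covered[f$test] <- covered[f$test] + 1L
  }
  if (!all(covered == 1L))
    stop_data("fold coverage violated: each sample must be predicted once")
  for (mr in list(result$sample_metrics, result$subject_metrics)) {
    if (is.null(mr)) next
    p <- mr$TP + mr$FN; ng <- mr$TN + mr$FP
    if (p > 0 && ng > 0) {
      lhs <- mr$accuracy
      rhs <- (mr$sensitivity * p + mr$specificity * ng) / (p + ng)
      if (abs(lhs - rhs) > 1e-12)
        stop_data("metric identity violated")
    }
  }
  invisible(TRUE)
}

#' Export a cv_result to JSON or table form
#'
#' @param result a `cv_result`.
#' @param path optional JSON output file.
#' @return the JSON string (invisibly when written).
#' @export
cv_result_json <- function(result, path = NULL) {
  obj <- list(protocol = result$protocol, seed = result$seed,
              pred = result$pred, y_true = result$y_true,
              subject = result$subject,
              sample_metrics = unclass(result$sample_metrics),
              subject_metrics = if (!is.null(result$subject_metrics))
                unclass(result$subject_metrics),
              subject_table = result$subject_table,
              failed_folds = result$failed_folds)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Tabulate repeated-run summaries in the Mean/Std/Best layout
#'
#' Produces one row per algorithm with Mean/Std/Best columns for each
#' metric, mirroring the conventional results-table layout, ready for
#' `write.csv`.
#'
#' @param ... named `repeated_runs()` results.
#' @return a data.frame with one row per supplied result.
#' @export
summary_table <- function(...) {
  lst <- list(...)
  stopifnot(length(lst) > 0, !is.null(names(lst)), all(nzchar(names(lst))))
  do.call(rbind, lapply(names(lst), function(nm) {
    s <- lst[[nm]]$summary
    row <- data.frame(algorithm = nm, protocol = lst[[nm]]$protocol,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(s))) {
      m <- s$metric[i]
      row[[paste0(m, "_mean")]] <- s$Mean[i]
      row[[paste0(m, "_std")]] <- s$Std[i]
      row[[paste0(m, "_best")]] <- s$Best[i]
    }
    row
  }))
}
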