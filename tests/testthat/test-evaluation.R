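test_that("confusion metrics follow the printed formulas and NA rules", {
  y_true <- c(rep(1L, 10), rep(0L, 10))
  y_pred <- c(rep(1L, 9), 0L, rep(0L, 7), rep(1L, 3))
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(c(m$TP, m$FN, m$TN, m$FP), c(9L, 1L, 7L, 3L))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.7)

  perfect <- confusion_metrics(y_true, y_true)
  expect_equal(c(perfect$accuracy, perfect$sensitivity,
                 perfect$specificity), c(1, 1, 1))

  # all-patient ground truth: specificity undefined, accuracy = sensitivity
  ap <- confusion_metrics(rep(1L, 8), c(rep(1L, 6), 0L, 0L))
  expect_true(is.na(ap$specificity))
  expect_equal(ap$accuracy, ap$sensitivity)

  expect_error(confusion_metrics(1L, c(1L, 0L)), "lengths")
  expect_error(confusion_metrics(integer(), integer()), "empty")
})

test_that("accuracy equals the prevalence-weighted mean of sen and spe", {
  set.seed(5)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- rbinom(30, 1, 0.5)
    m <- confusion_metrics(y, p)
    pos <- sum(y); neg <- sum(1 - y)
    expect_equal(m$accuracy,
                 (m$sensitivity * pos + m$specificity * neg) / (pos + neg))
  }
})

test_that("LOO builds one fold per sample and nails separable data", {
  ds <- separable_dataset(subjects_per_class = 3, samples_per_subject = 4)
  cfg <- pipeline_config("knn", use_menn = FALSE, seed = 1)
  res <- run_loo(ds, cfg)
  expect_equal(length(res$folds), nrow(ds))
  expect_true(all(vapply(res$folds, function(f) length(f$train), 1L) ==
                    nrow(ds) - 1L))
  expect_equal(res$sample_metrics$accuracy, 1)
  expect_silent(check_cv_hygiene(res))
  # deterministic under a fixed config seed
  res2 <- run_loo(ds, cfg)
  expect_identical(res2$pred, res$pred)
})

test_that("LOSO aggregates LOO predictions per subject by majority vote", {
  ds <- small_mixed_dataset(seed = 3)
  cfg <- pipeline_config("knn", use_menn = FALSE, seed = 2)
  res <- run_loso(ds, cfg)
  expect_equal(nrow(res$subject_table), 8L)  # 4 subjects per class
  # subject correctness == majority arithmetic on its sample predictions
  for (i in seq_len(nrow(res$subject_table))) {
    s <- res$subject_table$subject_id[i]
    j <- res$subject == s
    expect_equal(res$subject_table$votes_patient[i],
                 sum(res$pred[j] == 1L))
  }
  expect_silent(check_cv_hygiene(res))
})

test_that("the independent protocol excludes the whole test subject", {
  ds <- small_mixed_dataset(seed = 8)
  cfg <- pipeline_config("knn", use_menn = FALSE, seed = 4)
  res <- run_independent(ds, cfg, level = "subject")
  n_subj_samples <- table(subjects_of(ds))
  for (f in res$folds) {
    expect_equal(length(f$train),
                 nrow(ds) - unname(n_subj_samples[subjects_of(ds)[f$test[1]]]))
    expect_length(intersect(unique(res$subject[f$test]),
                            unique(res$subject[f$train])), 0L)
  }
  expect_silent(check_cv_hygiene(res))
})

test_that("hygiene checker actually catches violations", {
  ds <- separable_dataset(subjects_per_class = 3, samples_per_subject = 4)
  res <- run_loo(ds, pipeline_config("knn", use_menn = FALSE, seed = 1))
  broken <- res
  broken$folds[[1]]$train <- c(broken$folds[[1]]$train,
                               broken$folds[[1]]$test)
  expect_error(check_cv_hygiene(broken), "training fold")
  broken2 <- res
  broken2$folds[[2]] <- NULL
  expect_error(check_cv_hygiene(broken2), "coverage")
})

test_that("repeated runs summarize correctly; deterministic backends have zero std", {
  ds <- separable_dataset(subjects_per_class = 3, samples_per_subject = 4)
  cfg <- pipeline_config("svm_linear", use_menn = FALSE, seed = 1)
  rr <- repeated_runs(ds, cfg, protocol = "loso", n_runs = 3, base_seed = 10)
  expect_length(rr$runs, 3L)
  expect_true(all(rr$summary$Std == 0))

  one <- repeated_runs(ds, cfg, protocol = "loo", n_runs = 1, base_seed = 0)
  expect_equal(one$summary$Mean, one$summary$Best)

  # summaries recompute exactly from the returned run list
  accs <- vapply(rr$runs, function(r) r$accuracy, numeric(1))
  expect_equal(rr$summary$Mean[rr$summary$metric == "accuracy"], mean(accs))
  expect_equal(rr$summary$Best[rr$summary$metric == "accuracy"], max(accs))
})

test_that("algorithm comparison is symmetric, degenerate-aware, and powerful", {
  a <- c(0.9, 0.91, 0.89, 0.9, 0.92, 0.9, 0.89, 0.91, 0.9, 0.9)
  b <- c(0.5, 0.52, 0.49, 0.51, 0.5, 0.5, 0.48, 0.52, 0.5, 0.51)
  cmp <- compare_algorithms(a, b)
  expect_lt(cmp$p_value, 1e-4)
  expect_false(cmp$degenerate)
  expect_equal(compare_algorithms(b, a)$p_value, cmp$p_value)

  same <- compare_algorithms(rep(0.8, 5), rep(0.8, 5))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  expect_error(compare_algorithms(c(0.5), c(0.4, 0.6)), "at least two")
})

test_that("cv results serialize to JSON with their metrics", {
  ds <- separable_dataset(subjects_per_class = 3, samples_per_subject = 4)
  res <- run_loso(ds, pipeline_config("knn", use_menn = FALSE, seed = 1))
  js <- jsonlite::fromJSON(cv_result_json(res))
  expect_equal(js$protocol, "loso")
  expect_equal(js$sample_metrics$accuracy, res$sample_metrics$accuracy)
  expect_equal(length(js$pred), nrow(ds))
})

test_that("summary tables lay out Mean/Std/Best per algorithm", {
  ds <- separable_dataset(subjects_per_class = 3, samples_per_subject = 4)
  rr1 <- repeated_runs(ds, pipeline_config("knn", use_menn = FALSE),
                       protocol = "loso", n_runs = 2)
  rr2 <- repeated_runs(ds, pipeline_config("svm_linear", use_menn = FALSE),
                       protocol = "loso", n_runs = 2)
  tab <- summary_table(knn = rr1, svm = rr2)
  expect_equal(tab$algorithm, c("knn", "svm"))
  expect_true(all(c("accuracy_mean", "sensitivity_std", "specificity_best")
                  %in% names(tab)))
})
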