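test_that("delimited tables parse into datasets and invariants are enforced", {
  path <- write_lines_tmp(c("s1,0.1,0.2,1", "s1,0.3,0.4,1", "s2,0.0,0.1,0"))
  ds <- read_sakar(path, toy_layout())
  expect_s3_class(ds, "pd_dataset")
  expect_equal(nrow(ds), 3L)
  expect_equal(length(unique(subjects_of(ds))), 2L)
  expect_equal(dataset_dim(ds), 2L)
  expect_equal(labels_of(ds), c(1L, 1L, 0L))

  # a subject carrying both labels is rejected
  bad <- write_lines_tmp(c("s1,0.1,0.2,1", "s1,0.3,0.4,1",
                           "s2,0.0,0.1,0", "s2,0.0,0.1,1"))
  expect_error(read_sakar(bad, toy_layout()), "conflicting labels.*s2")

  # non-numeric feature names the line
  nn <- write_lines_tmp(c("s1,abc,0.2,1", "s1,0.3,0.4,1", "s2,0.0,0.1,0"))
  expect_error(read_sakar(nn, toy_layout()), "line 1")

  # wrong column count names the line
  short <- write_lines_tmp(c("s1,0.1,0.2,1", "s1,0.3,0.4", "s2,0.0,0.1,0"))
  expect_error(read_sakar(short, toy_layout()), "line 2")
})

test_that("UCI-style layouts skip ignored columns and tag sample kinds", {
  # 2 subjects x 3 samples, 26 features + severity + label, training layout
  mk_row <- function(id, sev, lab)
    paste(c(id, sprintf("%.3f", seq(0.01, 0.26, by = 0.01)), sev, lab),
          collapse = ",")
  path <- write_lines_tmp(c(mk_row("a", 10, 1), mk_row("a", 11, 1),
                            mk_row("a", 12, 1), mk_row("b", 0, 0)))
  ds <- read_sakar(path, sakar_layout_train())
  expect_equal(dataset_dim(ds), 26L)
  expect_false("severity" %in% names(ds))
  expect_equal(as.character(ds$sample_kind), c("vowel", "vowel", "vowel",
                                               "vowel"))
  expect_equal(sakar_sample_kind(c(1, 4, 14, 18, 27)),
               c("vowel", "number", "sentence", "word", "unknown"))
})

test_that("datasets round-trip through CSV for decimal inputs", {
  ds <- pd_dataset(rep(c("u1", "u2"), each = 3),
                   matrix(c(0.1, 2.25, -3.5, 0.125, 7, -0.625,
                            1.5, 0.2, 0.3, 0.4, 0.5, 0.6), ncol = 2),
                   rep(c(0L, 1L), each = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset_csv(path)
  expect_identical(features_of(back), features_of(ds))
  expect_identical(labels_of(back), labels_of(ds))
  expect_identical(subjects_of(back), subjects_of(ds))
})

test_that("synthetic generation is shape-correct and bit-reproducible", {
  cfg <- synthetic_config(subjects_per_class = 2, samples_per_subject = 3,
                          d = 2, seed = 5)
  ds <- generate_synthetic(cfg)
  expect_equal(nrow(ds), 12L)
  expect_equal(length(unique(subjects_of(ds))), 4L)
  expect_silent(pd_dataset(subjects_of(ds), features_of(ds), labels_of(ds)))

  expect_identical(generate_synthetic(cfg), ds)
  cfg2 <- synthetic_config(subjects_per_class = 2, samples_per_subject = 3,
                           d = 2, seed = 6)
  expect_false(identical(features_of(generate_synthetic(cfg2)),
                         features_of(ds)))

  expect_error(synthetic_config(rho = 1), "rho")
  expect_error(synthetic_config(sigma_noise = 0), "sigma_noise")
})

test_that("contamination count follows floor(rho * m) per subject", {
  cfg <- synthetic_config(subjects_per_class = 3, samples_per_subject = 7,
                          d = 2, rho = 0.3, seed = 8)
  ds <- generate_synthetic(cfg)
  per_subj <- tapply(ds$is_contaminated, subjects_of(ds), sum)
  expect_true(all(per_subj == floor(0.3 * 7)))
})

test_that("sample-level error of the oracle threshold rule matches the closed form", {
  # delta chosen so the single-sample Bayes error of the uncontaminated
  # marginals is 0.25: delta = 2 * qnorm(0.75) * sigma_marginal
  sigma_subj <- 1; sigma_noise <- 1
  sig <- sqrt(sigma_subj^2 + sigma_noise^2)
  delta <- 2 * stats::qnorm(0.75) * sig
  cfg <- synthetic_config(subjects_per_class = 20, samples_per_subject = 26,
                          d = 26, delta_sep = delta, sigma_subj = sigma_subj,
                          sigma_noise = sigma_noise, rho = 0.15, seed = 42)
  ds <- generate_synthetic(cfg)
  # Bayes rule for the marginals thresholds the first coordinate at delta/2;
  # contaminated samples (features from the other class, label kept) are
  # misclassified with probability 1 - Phi(-delta / (2 sigma)).
  pred <- as.integer(features_of(ds)[, 1] > delta / 2)
  mc_err <- mean(pred != labels_of(ds))
  p_err <- stats::pnorm(-delta / (2 * sig))
  rho_eff <- floor(0.15 * 26) / 26
  closed <- (1 - rho_eff) * p_err + rho_eff * (1 - p_err)
  expect_lt(abs(mc_err - closed), 0.02)
})

test_that("1-NN achieves perfect LOSO subject accuracy on separable data", {
  ds <- separable_dataset(seed = 21)
  res <- run_loso(ds, pipeline_config("knn", use_menn = FALSE, seed = 1))
  expect_equal(res$subject_metrics$accuracy, 1)
  expect_equal(res$sample_metrics$accuracy, 1)
})

test_that("standardization fits on training data and inverts exactly", {
  sc <- standardize_fit(matrix(c(0, 2), ncol = 1))
  expect_equal(unname(sc$center), 1)
  expect_equal(unname(sc$scale), 1)  # population sd of {0, 2}
  expect_equal(unname(standardize_apply(sc, matrix(0))[1, 1]), -1)

  # constant column: scale 1, transformed values 0
  sc2 <- standardize_fit(matrix(c(5, 5, 5, 1, 2, 3), ncol = 2))
  expect_equal(unname(sc2$scale[1]), 1)
  expect_equal(unname(standardize_apply(sc2, matrix(c(5, 5, 1, 2),
                                                    ncol = 2))[, 1]),
               c(0, 0))

  x <- matrix(rnorm(40), ncol = 4)
  sc3 <- standardize_fit(x)
  expect_equal(standardize_invert(sc3, standardize_apply(sc3, x)), x,
               tolerance = 1e-12)
  expect_error(standardize_fit(matrix(numeric(), ncol = 2)), "empty")
})
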