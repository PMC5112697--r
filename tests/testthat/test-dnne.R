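test_that("decorrelation constants match hand substitution and conserve", {
  expect_equal(unname(c_constants(0, 7)), c(1, 0))
  expect_equal(unname(c_constants(0.5, 2)), c(0.75, 0.25))
  expect_equal(unname(c_constants(1, 10)), c(1 - 162 / 100, 18 / 100))
  for (M in 2:15) for (lambda in seq(0, 1, 0.1)) {
    cc <- c_constants(lambda, M)
    expect_identical(unname(cc[1] + (M - 1) * cc[2]), 1)
  }
  expect_error(c_constants(1.2, 3), "lambda")
  expect_error(c_constants(0.5, 1), "M")
})

test_that("flat indexing follows the ceiling/mod rule and round-trips", {
  expect_equal(unname(index_map(1, 5)), c(1L, 1L))
  expect_equal(unname(index_map(7, 5)), c(2L, 2L))
  for (p in 1:12) {
    mn <- index_map(p, 4)
    expect_identical(flatten_index(mn[1], mn[2], 4), as.integer(p))
  }
  expect_error(index_map(0, 5), "index")
})

test_that("hidden activations are sigmoids of the random projections", {
  spec <- rvfl_spec(2, 3, 4, seed = 1)
  # forced zero weights -> all activations exactly 0.5
  spec0 <- spec
  spec0$weights[] <- 0
  spec0$biases[] <- 0
  G0 <- hidden_activations(spec0, matrix(rnorm(20), 5, 4))
  expect_true(all(G0 == 0.5))

  G <- hidden_activations(spec, matrix(rnorm(40), 10, 4))
  expect_true(all(G > 0 & G < 1))
  expect_equal(dim(G), c(10L, 6L))
  expect_error(hidden_activations(spec, matrix(0, 2, 3)), "columns")

  # hidden parameters are a pure function of the seed
  expect_identical(rvfl_spec(4, 7, 3, 0.2, seed = 9),
                   rvfl_spec(4, 7, 3, 0.2, seed = 9))
})

test_that("the hand-derived two-network system reproduces exactly", {
  G <- cbind(c(1, 2), c(3, 4))
  sys <- build_normal_system(G, c(1, 0), lambda = 0.5, M = 2, L = 1)
  expect_equal(unname(sys$H_corr),
               matrix(c(3.75, 2.75, 2.75, 18.75), 2), tolerance = 1e-15)
  expect_equal(sys$T_h, c(1, 3))
  sol <- solve_output_weights(sys)
  expect_equal(sol$B_ens, c(10.5 / 62.75, 8.5 / 62.75), tolerance = 1e-12)
  expect_identical(sol$solver_note, "direct")
})

test_that("H_corr equals the blockdiag + cross-correlation construction", {
  set.seed(31)
  for (lambda in c(0, 0.3, 0.7, 1.0)) {
    M <- 3; L <- 5
    spec <- rvfl_spec(M, L, 4, lambda, seed = sample.int(1e6, 1))
    G <- hidden_activations(spec, matrix(rnorm(200), 50, 4))
    y <- rbinom(50, 1, 0.5)
    sys <- build_normal_system(G, y, lambda, M, L)
    cc <- c_constants(lambda, M)
    bd <- matrix(0, M * L, M * L)
    for (i in seq_len(M)) {
      idx <- (i - 1) * L + seq_len(L)
      bd[idx, idx] <- crossprod(G[, idx])
    }
    oracle <- (cc[1] - cc[2]) * bd + cc[2] * crossprod(G)
    expect_lt(max(abs(sys$H_corr - oracle)) / max(abs(oracle)), 1e-10)
    expect_lt(max(abs(sys$H_corr - t(sys$H_corr))), 1e-10)
    if (lambda == 0) {
      off <- sys$H_corr
      for (i in seq_len(M)) {
        idx <- (i - 1) * L + seq_len(L)
        off[idx, idx] <- 0
      }
      expect_true(all(off == 0))   # block-diagonal at lambda = 0
    }
  }
})

test_that("the solver honors its residual contract and identity systems", {
  sys <- structure(list(H_corr = diag(4), T_h = c(1, -2, 0, 3),
                        M = 2L, L = 2L, lambda = 0),
                   class = "normal_system")
  sol <- solve_output_weights(sys)
  expect_equal(sol$B_ens, c(1, -2, 0, 3))

  set.seed(7)
  spec <- rvfl_spec(3, 5, 4, 0.3, seed = 77)
  G <- hidden_activations(spec, matrix(rnorm(200), 50, 4))
  sys2 <- build_normal_system(G, rbinom(50, 1, 0.5), 0.3, 3, 5)
  sol2 <- solve_output_weights(sys2)
  if (identical(sol2$solver_note, "direct")) {
    resid <- max(abs(sys2$H_corr %*% sol2$B_ens - sys2$T_h))
    expect_lte(resid, 1e-8 * max(1, max(abs(sys2$T_h))))
  }
  # generic dense solve agrees
  expect_equal(sol2$B_ens, as.vector(solve(sys2$H_corr, sys2$T_h)),
               tolerance = 1e-8)
  sys_bad <- sys
  sys_bad$T_h[1] <- NaN
  expect_error(solve_output_weights(sys_bad), "non-finite")
})

test_that("lambda = 0 decouples training into per-network least squares", {
  set.seed(13)
  x <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, 0.5)
  fit <- dnne_train(x, y, M = 3, L = 5, lambda = 0, seed = 21)
  spec <- rvfl_spec(3, 5, 4, 0, seed = 21)
  xs <- standardize_apply(standardize_fit(x), x)
  G <- hidden_activations(spec, xs)
  oracle <- unlist(lapply(1:3, function(i) {
    idx <- (i - 1) * 5 + 1:5
    solve(crossprod(G[, idx]), crossprod(G[, idx], y))
  }))
  expect_equal(fit$B_ens, unname(oracle), tolerance = 1e-8)
  # prediction = mean of per-network OLS outputs
  pr <- predict(fit, x)
  per_net <- sapply(1:3, function(i) {
    idx <- (i - 1) * 5 + 1:5
    G[, idx] %*% oracle[idx]
  })
  expect_equal(pr$score, unname(rowMeans(per_net)), tolerance = 1e-8)
})

test_that("training is deterministic and fits separable data perfectly", {
  ds <- separable_dataset()
  x <- features_of(ds); y <- labels_of(ds)
  f1 <- dnne_train(x, y, M = 5, L = 20, lambda = 0.5, seed = 4)
  f2 <- dnne_train(x, y, M = 5, L = 20, lambda = 0.5, seed = 4)
  expect_identical(f1$B_ens, f2$B_ens)
  expect_equal(mean(predict(f1, x)$label == y), 1)
  expect_error(dnne_train(x, rep(1L, length(y))), "both classes")
})

test_that("predictions are permutation-equivariant and zero weights score zero", {
  ds <- separable_dataset()
  fit <- dnne_train(features_of(ds), labels_of(ds), M = 3, L = 5, seed = 2)
  x <- features_of(ds)
  perm <- sample(nrow(x))
  expect_equal(predict(fit, x[perm, ])$score, predict(fit, x)$score[perm])
  fit0 <- fit
  fit0$B_ens[] <- 0
  p0 <- predict(fit0, x)
  expect_true(all(p0$score == 0))
  expect_true(all(p0$label == 0L))
})

test_that("grid search honors tie rules and wins on separable data", {
  ds <- separable_dataset(subjects_per_class = 4, samples_per_subject = 4)
  gs1 <- dnne_grid_search(ds, M_grid = 3, L_grid = 5, lambda_grid = 0.5,
                          inner_folds = 3, seed = 1)
  expect_equal(unname(gs1$best), c(3, 5, 0.5))
  expect_equal(nrow(gs1$table), 1L)

  gs <- dnne_grid_search(ds, M_grid = c(2, 4), L_grid = 5,
                         lambda_grid = c(0, 0.5), inner_folds = 3, seed = 1)
  expect_equal(gs$score, 1)           # separable: winning cell is perfect
  top <- gs$table[gs$table$score == gs$score, ]
  # tie rule: the reported winner is the smallest (M, L, lambda) among ties
  expect_equal(unname(gs$best["M"]), min(top$M))
  expect_error(dnne_grid_search(ds, M_grid = integer(), L_grid = 5,
                                lambda_grid = 0), "empty grid")
})
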