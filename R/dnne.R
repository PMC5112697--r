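#' Decorrelation constants of the joint ensemble objective
#'
#' The joint least-squares objective of an `M`-network ensemble with a
#' negative-correlation penalty weighted by `lambda` reduces, after
#' differentiation, to a linear system whose coefficients carry only two
#' constants: `C1 = 1 - 2*lambda*(M-1)^2/M^2` on same-network terms and
#' `C2 = 2*lambda*(M-1)/M^2` on cross-network terms. They satisfy
#' `C1 + (M-1)*C2 = 1` identically; `C1` turns negative for large
#' `lambda` and `M`, which is why the solver carries a ridge fallback.
#'
#' @param lambda decorrelation strength in `[0, 1]`.
#' @param M number of base networks (>= 2).
#' @return named numeric vector `c(C1 = ..., C2 = ...)`.
#' @export
#' @examples
#' c_constants(0.5, 2)  # C1 = 0.75, C2 = 0.25
c_constants <- function(lambda, M) {
  if (lambda < 0 || lambda > 1) stop_config("lambda must lie in [0, 1]")
  if (M < 2) stop_config("M must be >= 2")
  c2 <- 2 * lambda * (M - 1) / M^2
  # C1 = 1 - 2*lambda*(M-1)^2/M^2, grouped so the conservation identity
  # C1 + (M-1)*C2 = 1 holds exactly in floating point
  c(C1 = 1 - (M - 1) * c2, C2 = c2)
}

#' Flat-index bookkeeping for the hidden-correlation system
#'
#' The `M * L` output weights are stacked network-major:
#' `beta[1,1] .. beta[1,L], beta[2,1] .. beta[M,L]`. `index_map` recovers
#' the (network, neuron) pair of a flat position `p` via
#' `m = ceiling(p / L)`, `n = ((p - 1) mod L) + 1`; `flatten_index` is its
#' inverse.
#'
#' @param p flat index in `1..M*L`.
#' @param L hidden neurons per network.
#' @param m,n network and neuron indices (1-based).
#' @return `index_map`: integer vector `c(network, neuron)`;
#'   `flatten_index`: the flat index.
#' @export
#' @examples
#' index_map(7, L = 5)        # network 2, neuron 2
#' flatten_index(2, 2, L = 5) # 7
index_map <- function(p, L) {
  if (any(p < 1)) stop_config("flat index must be >= 1")
  c(network = as.integer(ceiling(p / L)),
    neuron = as.integer(((p - 1) %% L) + 1))
}

#' @rdname index_map
#' @export
flatten_index <- function(m, n, L) as.integer((m - 1) * L + n)

#' Draw the random hidden layer of an RVFL ensemble
#'
#' Hidden weights and biases are drawn independently per (network, neuron)
#' pair from Uniform(-1, 1), deterministically from the seed, and stay
#' fixed forever: only the output weights are learned. Weights are drawn
#' first (network-major, neuron, then input coordinate), then biases, so a
#' given `(M, L, d, seed)` always yields the identical ensemble.
#'
#' @param M number of base networks (>= 2).
#' @param L hidden neurons per network.
#' @param d input dimension.
#' @param lambda decorrelation strength in `[0, 1]`.
#' @param seed integer seed.
#' @return an `rvfl_spec`: `weights` (`(M*L) x d`, rows in flat order),
#'   `biases` (length `M*L`), plus `M`, `L`, `d`, `lambda`, `seed`.
#' @export
rvfl_spec <- function(M, L, d, lambda = 0.5, seed = 1L) {
  if (M < 2 || L < 1 || d < 1) stop_config("need M >= 2, L >= 1, d >= 1")
  c_constants(lambda, M)  # validates lambda
  local_seed(seed, {
    w <- matrix(stats::runif(M * L * d, -1, 1), M * L, d, byrow = TRUE)
    b <- stats::runif(M * L, -1, 1)
    structure(list(weights = w, biases = b, M = as.integer(M),
                   L = as.integer(L), d = as.integer(d), lambda = lambda,
                   base_function = "sigmoid", seed = as.integer(seed)),
              class = "rvfl_spec")
  })
}

#' Hidden-layer activations of every base network
#'
#' Column `(i-1)*L + j` of the returned matrix holds
#' `sigmoid(w_ij . x_n + b_ij)` for each input row `n`, i.e. the response
#' of neuron `j` of network `i`. All entries lie strictly in (0, 1).
#'
#' @param spec an [rvfl_spec()].
#' @param x numeric `N x d` matrix of (standardized) features.
#' @return `N x (M*L)` activation matrix `G`.
#' @export
hidden_activations <- function(spec, x) {
  x <- as.matrix(x)
  if (ncol(x) != spec$d)
    stop_data("input has ", ncol(x), " columns; spec expects ", spec$d)
  z <- tcrossprod(x, spec$weights) +
    matrix(spec$biases, nrow(x), spec$M * spec$L, byrow = TRUE)
  stats::plogis(z)
}

#' Assemble the hidden-correlation normal system
#'
#' Builds the `(M*L) x (M*L)` system `H_corr B = T_h` whose solution is
#' the ensemble's joint output-weight vector. The co-activation sums
#' `phi(i,j,k,l) = sum_n g_ij(x_n) g_kl(x_n)` fill `H_corr` scaled by `C1`
#' when the two flat indices belong to the same network and `C2`
#' otherwise; `T_h` holds the activation-target correlations
#' `phi(i,j) = sum_n g_ij(x_n) y_n`. Structurally,
#' `H_corr = (C1 - C2) * blockdiag(G_i' G_i) + C2 * G'G`.
#'
#' @param G `N x (M*L)` activation matrix from [hidden_activations()].
#' @param y numeric target vector (0/1 class codes in this package).
#' @param lambda decorrelation strength.
#' @param M,L ensemble shape; `ncol(G)` must equal `M*L`.
#' @param row_weights optional `N x M` 0/1 matrix; column `i` marks the
#'   rows contributing to network `i`'s correlation sums (per-network
#'   bagging). Default: all rows for every network.
#' @return a `normal_system` with `H_corr`, `T_h`, `M`, `L`, `lambda`.
#' @export
build_normal_system <- function(G, y, lambda, M, L, row_weights = NULL) {
  G <- as.matrix(G)
  if (ncol(G) != M * L)
    stop_data("G has ", ncol(G), " columns; expected M*L = ", M * L)
  if (nrow(G) != length(y)) stop_data("G and y disagree on sample count")
  if (!all(is.finite(G)) || !all(is.finite(y)))
    stop_data("non-finite entries in G or y")
  cc <- c_constants(lambda, M)
  net <- rep(seq_len(M), each = L)
  if (is.null(row_weights)) {
    phi <- crossprod(G)            # phi(i,j,k,l) over the shared sample set
    t_h <- as.vector(crossprod(G, y))
  } else {
    # mask rows per network: phi over rows used by *both* networks
    Gm <- G * row_weights[, net, drop = FALSE]
    phi <- crossprod(Gm)
    t_h <- as.vector(crossprod(Gm, y))
  }
  same <- outer(net, net, "==")
  H <- ifelse(same, cc["C1"], cc["C2"]) * phi
  structure(list(H_corr = H, T_h = t_h, M = as.integer(M),
                 L = as.integer(L), lambda = lambda),
            class = "normal_system")
}

#' Solve the normal system for the global output weights
#'
#' Direct dense solve when the system is well conditioned; otherwise ridge
#' jitter `eps * mean(diag(H)) * I` is added, with `eps` escalating from
#' `1e-8` by factors of 10 up to `1e-2` (each escalation recorded), and a
#' Moore-Penrose pseudo-inverse as final fallback. Indefiniteness is a
#' real possibility here: `C1 < 0` for large `lambda` and `M`.
#'
#' @param system a `normal_system` from [build_normal_system()].
#' @param rcond_min reciprocal-condition threshold below which the direct
#'   solve is not trusted (default `1e-12`).
#' @return list with `B_ens` (length `M*L` weight vector) and
#'   `solver_note` (character record of any stabilization applied).
#' @export
solve_output_weights <- function(system, rcond_min = 1e-12) {
  H <- system$H_corr; t_h <- system$T_h
  if (!all(is.finite(H)) || !all(is.finite(t_h)))
    stop_data("non-finite normal system")
  note <- character()
  rc <- tryCatch(rcond(H), error = function(e) 0)
  if (rc > rcond_min) {
    b <- tryCatch(solve(H, t_h), error = function(e) NULL)
    if (!is.null(b))
      return(list(B_ens = as.vector(b), solver_note = "direct"))
  }
  diag_mean <- mean(abs(diag(H)))
  if (diag_mean == 0) diag_mean <- 1
  for (eps in 10^seq(-8, -2)) {
    Hr <- H + eps * diag_mean * diag(nrow(H))
    note <- c(note, sprintf("ridge eps=%.0e", eps))
    b <- tryCatch(solve(Hr, t_h), error = function(e) NULL)
    if (!is.null(b) && all(is.finite(b)))
      return(list(B_ens = as.vector(b), solver_note = note))
  }
  note <- c(note, "pseudo-inverse")
  b <- MASS::ginv(H) %*% t_h
  if (!all(is.finite(b)))
    stop_data("output-weight solve failed after all stabilizations: ",
              paste(note, collapse = "; "))
  list(B_ens = as.vector(b), solver_note = note)
}

#' Train a decorrelated RVFL ensemble
#'
#' Fits the closed-form decorrelated neural-network ensemble: features are
#' z-score standardized (scaler kept in the model), the random hidden
#' layer is drawn from the seed, the hidden-correlation system is built
#' with the 0/1 labels as regression targets, and the joint output-weight
#' vector is obtained by a single linear solve — no gradient descent.
#' `lambda = 0` decouples the networks into independent least-squares
#' fits; larger `lambda` trades individual fit for ensemble diversity.
#'
#' @param x numeric feature matrix (or a [pd_dataset()]).
#' @param y integer 0/1 labels (taken from the dataset when omitted).
#' @param M number of base networks (default 5).
#' @param L hidden neurons per network (default 20).
#' @param lambda decorrelation strength in `[0, 1]` (default 0.5).
#' @param seed integer seed for the hidden layer (and bagging, if used).
#' @param threshold decision cut on the ensemble score (default 0.5).
#' @param bag_fraction optional fraction in (0, 1]; below 1, each network's
#'   correlation sums use only a random `bag_fraction` subset of rows
#'   (per-network bagging). Default 1: all networks share the full set.
#' @param standardize standardize features (recommended)?
#' @return a `dnne_model` holding the hidden-layer [rvfl_spec()], `B_ens`,
#'   the fitted scaler, the decision threshold and the solver note.
#' @export
#' @examples
#' cfg <- synthetic_config(subjects_per_class = 3, samples_per_subject = 4,
#'                         d = 3, delta_sep = 6, rho = 0, seed = 2)
#' ds <- generate_synthetic(cfg)
#' fit <- dnne_train(features_of(ds), labels_of(ds), M = 3, L = 5, seed = 1)
#' mean(predict(fit, features_of(ds))$label == labels_of(ds))
dnne_train <- function(x, y = NULL, M = 5L, L = 20L, lambda = 0.5,
                       seed = 1L, threshold = 0.5, bag_fraction = 1,
                       standardize = TRUE) {
  if (inherits(x, "pd_dataset")) {
    y <- y %||% labels_of(x)
    x <- features_of(x)
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop_data("dnne_train needs samples from both classes")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop_config("bag_fraction must lie in (0, 1]")
  scaler <- if (standardize) standardize_fit(x) else NULL
  xs <- if (standardize) standardize_apply(scaler, x) else x
  spec <- rvfl_spec(M, L, ncol(x), lambda, seed)
  G <- hidden_activations(spec, xs)
  rw <- NULL
  if (bag_fraction < 1) {
    n_keep <- max(2L, floor(bag_fraction * nrow(xs)))
    rw <- local_seed(derive_seed(seed, 1L), {
      vapply(seq_len(M), function(i) {
        v <- numeric(nrow(xs)); v[sample.int(nrow(xs), n_keep)] <- 1; v
      }, numeric(nrow(xs)))
    })
  }
  sys <- build_normal_system(G, y, lambda, M, L, row_weights = rw)
  sol <- solve_output_weights(sys)
  structure(list(spec = spec, B_ens = sol$B_ens, scaler = scaler,
                 threshold = threshold, solver_note = sol$solver_note),
            class = "dnne_model")
}

#' Predict with a decorrelated RVFL ensemble
#'
#' The ensemble score of a point is the mean of the base-network outputs,
#' `(1/M) * sum_i sum_j beta_ij g_ij(x)`; the predicted label is patient
#' (1) when the score reaches the model's threshold.
#'
#' @param object a `dnne_model` from [dnne_train()].
#' @param newdata feature matrix (or [pd_dataset()]) to score.
#' @param ... unused.
#' @return list with numeric `score` and integer `label` vectors.
#' @export
predict.dnne_model <- function(object, newdata, ...) {
  if (inherits(newdata, "pd_dataset")) newdata <- features_of(newdata)
  x <- as.matrix(newdata)
  if (ncol(x) != object$spec$d)
    stop_data("newdata has ", ncol(x), " columns; model expects ",
              object$spec$d)
  if (!is.null(object$scaler)) x <- standardize_apply(object$scaler, x)
  G <- hidden_activations(object$spec, x)
  score <- as.vector(G %*% object$B_ens) / object$spec$M
  list(score = score, label = as.integer(score >= object$threshold))
}

#' @export
print.dnne_model <- function(x, ...) {
  cat(sprintf(
    "dnne_model: M = %d networks x L = %d neurons, lambda = %g (%s)\n",
    x$spec$M, x$spec$L, x$spec$lambda,
    paste(x$solver_note, collapse = " -> ")))
  invisible(x)
}

#' Exhaustive grid search over ensemble shape and decorrelation strength
#'
#' Scores every `(M, L, lambda)` cell by mean sample accuracy under
#' subject-grouped inner cross-validation and returns the winner together
#' with the full score table. Ties break toward smaller `M`, then smaller
#' `L`, then smaller `lambda`. The reference search ranges are
#' `M in 2..15`, `L in 5..50` and `lambda in {0, 0.1, ..., 1}`; smaller
#' grids are accepted (and advisable off-interactive use: the full grid is
#' 7084 cells).
#'
#' @param x feature matrix or [pd_dataset()]; `subject` is taken from the
#'   dataset when available.
#' @param y labels (from the dataset when omitted).
#' @param M_grid,L_grid,lambda_grid candidate values.
#' @param inner_folds grouped CV folds (default 5).
#' @param seed seed for fold assignment and the per-fit hidden layers.
#' @param subject subject ids for grouped folds; when absent, plain
#'   sample-level folds are used.
#' @return list with `best` (named vector M, L, lambda), `score` of the
#'   winner, and `table` (a data.frame of all cells; failed cells carry
#'   `NA` score).
#' @export
dnne_grid_search <- function(x, y = NULL, M_grid = 2:15, L_grid = 5:50,
                             lambda_grid = seq(0, 1, 0.1), inner_folds = 5L,
                             seed = 1L, subject = NULL) {
  if (inherits(x, "pd_dataset")) {
    y <- y %||% labels_of(x)
    subject <- subject %||% subjects_of(x)
    x <- features_of(x)
  }
  x <- as.matrix(x); y <- as.integer(y)
  if (!length(M_grid) || !length(L_grid) || !length(lambda_grid))
    stop_config("empty grid")
  fold <- grouped_folds(subject %||% as.character(seq_along(y)),
                        inner_folds, derive_seed(seed, 0L))
  cells <- expand.grid(M = M_grid, L = L_grid, lambda = lambda_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$M, cells$L, cells$lambda), , drop = FALSE]
  rownames(cells) <- NULL
  cells$score <- NA_real_
  for (r in seq_len(nrow(cells))) {
    accs <- numeric(0)
    ok <- TRUE
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) { ok <- FALSE; break }
      fit <- tryCatch(
        dnne_train(x[tr, , drop = FALSE], y[tr], M = cells$M[r],
                   L = cells$L[r], lambda = cells$lambda[r],
                   seed = derive_seed(seed, r)),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred <- predict(fit, x[!tr, , drop = FALSE])
      accs <- c(accs, mean(pred$label == y[!tr]))
    }
    if (ok) cells$score[r] <- mean(accs)
  }
  if (all(is.na(cells$score)))
    stop_data("every grid cell failed (degenerate inner folds?)")
  best_i <- which(cells$score == max(cells$score, na.rm = TRUE))[1]
  list(best = c(M = cells$M[best_i], L = cells$L[best_i],
                lambda = cells$lambda[best_i]),
       score = cells$score[best_i], table = cells)
}

# subject-grouped fold ids: every sample of a subject lands in one fold
grouped_folds <- function(subject, n_folds, seed) {
  subj <- unique(subject)
  n_folds <- min(n_folds, length(subj))
  assign <- local_seed(seed, {
    sizes <- rep(length(subj) %/% n_folds, n_folds)
    r <- length(subj) %% n_folds
    if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
    stats::setNames(sample(rep.int(seq_len(n_folds), sizes)), subj)
  })
  as.integer(assign[subject])
}
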