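#' Randomly partition samples into near-equal subsets
#'
#' Step one of each multi-edit iteration: the `n` current samples are
#' divided at random into `s` subsets whose sizes differ by at most one.
#' The classical procedure requires more than three subsets; smaller `s`
#' is permitted only with `allow_small = TRUE` (useful for tiny fixtures).
#'
#' @param n number of samples.
#' @param s number of subsets (default 4, the reference setting).
#' @param seed integer seed; the assignment is a deterministic function of
#'   `(n, s, seed)`.
#' @param allow_small permit `s <= 3`?
#' @return integer vector of subset indices in `1..s`, length `n`.
#' @export
#' @examples
#' table(partition_samples(10, 4, seed = 1))
partition_samples <- function(n, s = 4L, seed, allow_small = FALSE) {
  n <- as.integer(n); s <- as.integer(s)
  if (s <= 3L && !allow_small)
    stop_config("s must exceed 3 (set allow_small = TRUE to override)")
  if (s < 1L) stop_config("s must be positive")
  if (n < s) stop_data("cannot split ", n, " samples into ", s, " subsets")
  sizes <- rep(n %/% s, s)
  r <- n %% s
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  local_seed(seed, sample(rep.int(seq_len(s), sizes)))
}

#' One editing pass over a partition
#'
#' For each subset `i`, the samples of `X_i` are classified by a k-NN
#' classifier whose training set is the *next* subset `X_{i+1}` (subset 1
#' when `i = s`); indices misclassified in any subset are returned for
#' removal. Features are used as given — callers standardize beforehand
#' (see [multi_edit()]).
#'
#' @param x numeric feature matrix (rows already standardized).
#' @param y integer 0/1 labels.
#' @param assignment subset index per row, from [partition_samples()].
#' @param k neighbors used by the editing classifier (default 1, the
#'   classical multi-edit choice).
#' @return integer vector of row indices judged misclassified.
#' @export
edit_pass <- function(x, y, assignment, k = 1L) {
  s <- max(assignment)
  if (!all(tabulate(assignment, s) > 0))
    stop_data("every subset must be nonempty")
  removed <- integer()
  for (i in seq_len(s)) {
    j <- if (i == s) 1L else i + 1L
    val <- which(assignment == i)
    tr <- which(assignment == j)
    pred <- knn_classify(x[tr, , drop = FALSE], y[tr],
                         x[val, , drop = FALSE], k = k)
    removed <- c(removed, val[pred != y[val]])
  }
  sort(unique(removed))
}

#' Multi-edit nearest-neighbor instance selection
#'
#' Iterates partition / edit / merge until an iteration removes no samples:
#' the remaining set then sits at the editing fixed point, with the samples
#' that fall in class-overlap regions (the ones most likely to mislead a
#' downstream classifier) deleted. Each iteration draws a fresh random
#' partition with a seed derived from `seed` and the iteration index.
#'
#' Editing runs on standardized features (a z-score scaler fitted on
#' `data` itself, unless `standardize = FALSE`), since the editing
#' classifier is Euclidean k-NN. A minimum-viability guard refuses any pass
#' that would leave a class empty: the pass is not applied, the trace is
#' flagged, and `converged` is `FALSE`.
#'
#' @param data a [pd_dataset()], or a numeric feature matrix when `y` is
#'   given.
#' @param s number of subsets per iteration (default 4).
#' @param k editing-classifier neighbor count (default 1).
#' @param seed integer seed controlling all partitions.
#' @param max_iter iteration cap (default 20).
#' @param y labels, when `data` is a bare matrix.
#' @param standardize standardize features before editing?
#' @param stratify draw class-stratified partitions instead of plain random
#'   ones?
#' @param allow_small passed to [partition_samples()].
#' @return a `menn_trace`: `retained` logical mask over input rows,
#'   `iterations` (per-iteration removal records), `s`, `k`, `seed`,
#'   `converged`, `flagged`.
#' @export
#' @examples
#' cfg <- synthetic_config(subjects_per_class = 4, samples_per_subject = 6,
#'                         d = 2, delta_sep = 8, sigma_subj = 0.2,
#'                         rho = 0, seed = 7)
#' tr <- multi_edit(generate_synthetic(cfg), seed = 1)
#' sum(tr$retained)
multi_edit <- function(data, s = 4L, k = 1L, seed = 1L, max_iter = 20L,
                       y = NULL, standardize = TRUE, stratify = FALSE,
                       allow_small = FALSE) {
  if (inherits(data, "pd_dataset")) {
    x <- features_of(data)
    y <- labels_of(data)
  } else {
    x <- as.matrix(data)
    if (is.null(y)) stop_config("y is required when data is a matrix")
  }
  n <- nrow(x)
  if (n == 0L) stop_data("empty dataset")
  if (length(unique(y)) < 2L)
    stop_data("multi_edit needs samples from both classes")
  if (standardize) x <- standardize_apply(standardize_fit(x), x)

  retained <- rep(TRUE, n)
  iterations <- list()
  converged <- FALSE
  flagged <- FALSE
  for (t in seq_len(max_iter)) {
    idx <- which(retained)
    if (length(idx) < s) { flagged <- TRUE; break }
    assignment <- draw_partition(y[idx], s, derive_seed(seed, t),
                                 stratify, allow_small)
    rem_local <- edit_pass(x[idx, , drop = FALSE], y[idx], assignment, k = k)
    rem <- idx[rem_local]
    keep_y <- y[setdiff(idx, rem)]
    if (length(rem) > 0 && length(unique(keep_y)) < 2L) {
      # applying this pass would empty a class: stop before it
      flagged <- TRUE
      iterations[[t]] <- list(iteration = t, removed = integer(),
                              blocked = rem, assignment = assignment)
      break
    }
    iterations[[t]] <- list(iteration = t, removed = rem,
                            assignment = assignment)
    if (length(rem) == 0L) { converged <- TRUE; break }
    retained[rem] <- FALSE
  }
  structure(list(retained = retained, iterations = iterations,
                 s = as.integer(s), k = as.integer(k),
                 seed = as.integer(seed), converged = converged,
                 flagged = flagged),
            class = "menn_trace")
}

draw_partition <- function(y, s, seed, stratify, allow_small) {
  n <- length(y)
  if (!stratify)
    return(partition_samples(n, s, seed, allow_small = allow_small))
  # stratified variant: partition each class separately, then interleave
  out <- integer(n)
  local_seed(seed, {
    for (cls in unique(y)) {
      i <- which(y == cls)
      sizes <- rep(length(i) %/% s, s)
      r <- length(i) %% s
      if (r > 0) {
        extra <- sample.int(s, r)
        sizes[extra] <- sizes[extra] + 1L
      }
      out[i] <- sample(rep.int(seq_len(s), sizes))
    }
  })
  if (!all(tabulate(out, s) > 0))
    stop_data("stratified partition produced an empty subset; reduce s")
  out
}

#' @export
print.menn_trace <- function(x, ...) {
  cat(sprintf(
    "menn_trace: %d/%d samples retained after %d iteration(s); %s%s\n",
    sum(x$retained), length(x$retained), length(x$iterations),
    if (x$converged) "converged" else "stopped early",
    if (x$flagged) " [flagged: viability guard]" else ""))
  invisible(x)
}

#' Serialize an edit trace to JSON
#'
#' @param trace a `menn_trace` from [multi_edit()].
#' @param path optional file; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
menn_trace_json <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "menn_trace"))
  obj <- list(retained = trace$retained,
              iterations = lapply(trace$iterations, function(it)
                list(iteration = it$iteration, removed = it$removed,
                     assignment = it$assignment)),
              s = trace$s, k = trace$k, seed = trace$seed,
              converged = trace$converged, flagged = trace$flagged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Asymptotic misclassification rate of the edited nearest-neighbor rule
#'
#' With class posteriors `p` at a point and `M` editing stages, the
#' conditional error of the nearest-neighbor rule on the edited reference
#' set follows a closed-form recursion in powers of the posteriors. Two
#' variants are provided. The `"corrected"` form (default),
#' `1 - sum(p^(2^M + 1)) / sum(p^(2^M))`, decreases monotonically toward
#' the Bayes floor `min(p)` as `M` grows and equals the classical
#' asymptotic NN error `1 - sum(p^2)` at `M = 0`. The `"printed"` form,
#' `1 - sum(p^(2^(M+1))) / sum(p^(2^M))`, is the expression found in some
#' published accounts; it coincides with the corrected form at `M = 0` but
#' tends to 1 rather than to `min(p)` as `M` grows, so it is exposed for
#' comparison only. Evaluation is in log space, since `p^(2^M)` underflows
#' double precision long before the limit is reached.
#'
#' @param p numeric vector of class posteriors (sums to 1).
#' @param M nonnegative integer count of editing stages.
#' @param form `"corrected"` (default) or `"printed"`.
#' @return the conditional error rate, a scalar in `[0, 1]`.
#' @export
#' @examples
#' asymptotic_edit_error(c(0.7, 0.3), M = 0)   # 1 - sum(p^2) = 0.42
#' asymptotic_edit_error(c(0.7, 0.3), M = 30)  # -> min(p) = 0.3
asymptotic_edit_error <- function(p, M, form = c("corrected", "printed")) {
  form <- match.arg(form)
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop_data("posteriors must be nonnegative and sum to 1")
  if (M < 0) stop_config("M must be nonnegative")
  lp <- log(p)
  lp[p == 0] <- -Inf
  a <- 2^M
  # shift by the dominant posterior before exponentiating: v_i <= 0, and
  # doubling a (M -> M+1) scales v exactly in binary floating point, which
  # keeps the corrected form exactly monotone in M
  v <- a * (lp - max(lp))
  w <- exp(v)
  if (form == "corrected") {
    1 - sum(p * w) / sum(w)
  } else {
    # printed variant: numerator exponent 2^(M+1) rather than 2^M + 1
    1 - exp(a * max(lp) + log(sum(exp(2 * v))) - log(sum(w)))
  }
}
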