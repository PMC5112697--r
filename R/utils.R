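`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific seed from a base seed
#'
#' Deterministic fan-out used everywhere the package needs several
#' independent random streams from one user-supplied seed (MENN partitions
#' per iteration, per-fold pipeline seeds, backend seeds). The map is a
#' fixed affine congruence modulo 2^31 - 1, so derived seeds stay valid
#' 32-bit R integers.
#'
#' @param seed integer base seed.
#' @param stream nonnegative integer stream index.
#' @return an integer seed, distinct for distinct streams in practice.
#' @export
#' @examples
#' derive_seed(42, 0)
#' derive_seed(42, 1)
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647
  s <- (abs(seed) %% m) * 1103 + stream * 7919 + 12345
  as.integer(s %% m)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_data <- function(...) {
  stop(structure(class = c("pdmedit_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("pdmedit_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
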