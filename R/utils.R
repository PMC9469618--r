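# Shared numeric helpers and the seed-derivation scheme.

#' Derive a child RNG seed from a parent seed and stream indices
#'
#' All randomness in the package flows from a single integer seed through this
#' mixing function, so multi-restart ensembles are reproducible and independent
#' of execution order. The map is a 31-bit linear congruential mix: starting
#' from `seed mod (2^31 - 1)`, each index `k` updates
#' `x <- (69069 * x + k + 1) mod (2^31 - 1)`.
#'
#' @param seed Integer parent seed.
#' @param ... Integer stream indices (e.g. restart number, refinement
#'   iteration, meta-epoch).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
mix_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.double(seed) %% m
  for (k in c(...)) {
    x <- (69069 * x + as.double(k) + 1) %% m
  }
  as.integer(x)
}

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(m) {
  shifted <- m - apply(m, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

# Clip probabilities away from {0, 1} before taking logs.
clip_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Area under the ROC curve via the rank statistic
#'
#' Computes AUC as the normalized Mann-Whitney U statistic, with ties handled
#' by midranks.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels Logical (or 0/1) vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auc_score() needs at least one positive and one negative")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
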