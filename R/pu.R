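# Positive-unlabeled ensemble protocol: reliable-negative seeding, iterative
# negative relabeling to convergence, multi-restart ensemble, median
# aggregation, and thresholding.
#
# Only positives are known. Each restart seeds k provisional negatives,
# trains the meta-initialized GCN on positives vs negatives, rescores every
# node, and relabels the negatives as the k non-positive nodes with the
# lowest positive-class probability, repeating until the negative set is
# stable. The per-node median over many randomly seeded restarts is the
# final score.

#' Positive-unlabeled protocol configuration
#'
#' @param k_negatives Number of provisional negatives k, default 100.
#' @param n_restarts Ensemble size R, default 1000.
#' @param threshold Candidate selection cutoff on the median score (strict
#'   inequality), default 0.95.
#' @param max_refine_iters Cap on negative-relabeling iterations, default 20.
#' @param negative_seeding `"farthest"` (hop-distance based, deterministic) or
#'   `"random"` (uniform without replacement; the ensemble default).
#' @param rng_seed Integer master seed; per-restart seeds are derived with
#'   [mix_seed()].
#' @return A `pu_config` list.
#' @export
pu_config <- function(k_negatives = 100L, n_restarts = 1000L, threshold = 0.95,
                      max_refine_iters = 20L, negative_seeding = c("random", "farthest"),
                      rng_seed = 1L) {
  negative_seeding <- match.arg(negative_seeding)
  stopifnot(k_negatives >= 1, n_restarts >= 1, threshold > 0, threshold < 1,
            max_refine_iters >= 1)
  list(k_negatives = as.integer(k_negatives), n_restarts = as.integer(n_restarts),
       threshold = threshold, max_refine_iters = as.integer(max_refine_iters),
       negative_seeding = negative_seeding, rng_seed = as.integer(rng_seed))
}

#' Seed provisional negatives
#'
#' In `"farthest"` mode, picks the `k` non-positive nodes with the largest
#' minimum hop distance to the positive set (unreachable nodes rank farthest),
#' breaking ties by larger total hop distance to all positives, then by
#' lexicographic node id; this mode is deterministic and ignores the seed. In
#' `"random"` mode, draws `k` non-positive nodes uniformly without
#' replacement from the seeded RNG stream.
#'
#' @param g An `interaction_graph`.
#' @param positives Character vector of positive node ids (all in the graph).
#' @param k Number of negatives; at most `n_nodes - length(positives)`.
#' @param mode `"farthest"` or `"random"`.
#' @param rng_seed Integer seed (used by `"random"` mode only).
#' @return Character vector of `k` node ids.
#' @export
seed_negatives <- function(g, positives, k, mode = c("farthest", "random"),
                           rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "interaction_graph"))
  positives <- unique(as.character(positives))
  missing <- setdiff(positives, g$node_ids)
  if (length(missing) > 0) stop("positives not in graph: ", paste(missing, collapse = ", "))
  pool <- setdiff(g$node_ids, positives)
  if (k > length(pool)) {
    stop(sprintf("k = %d negatives requested but only %d non-positive nodes available",
                 k, length(pool)))
  }
  if (mode == "random") {
    return(with_seed(rng_seed, sample(pool, k)))
  }
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency > 0, mode = "undirected")
  dmat <- igraph::distances(ig, v = positives, to = igraph::V(ig))
  colnames(dmat) <- g$node_ids
  dmat <- dmat[, pool, drop = FALSE]
  d_min <- apply(dmat, 2L, min)
  d_tot <- colSums(dmat)
  big <- g$n_nodes + 1
  d_min_f <- ifelse(is.finite(d_min), d_min, big)
  d_tot_f <- ifelse(is.finite(d_tot), d_tot, big * length(positives))
  ord <- order(-d_min_f, -d_tot_f, pool)
  pool[ord][seq_len(k)]
}

# Check the three-way label partition invariants inside the refinement loop.
.check_label_state <- function(node_ids, positives, negatives, k) {
  stopifnot(length(intersect(positives, negatives)) == 0,
            length(negatives) == k,
            all(positives %in% node_ids), all(negatives %in% node_ids))
}

# Build the named label vector (node index -> class; 1 background, 2 positive).
.pu_labels <- function(node_ids, positives, negatives) {
  idx_pos <- match(positives, node_ids)
  idx_neg <- match(negatives, node_ids)
  labels <- c(rep(2L, length(idx_pos)), rep(1L, length(idx_neg)))
  names(labels) <- as.character(c(idx_pos, idx_neg))
  labels
}

#' One PU run: train, score, relabel negatives until stable
#'
#' Repeats up to `pu_cfg$max_refine_iters` times: (1) meta-train then
#' base-train the GCN on the current positives/negatives, (2) score all nodes
#' with the positive-class probability, (3) relabel the negatives as the
#' `k` non-positive nodes with the lowest score (ties broken by ascending
#' score then lexicographic node id). Positives never change. The run
#' converges when the relabeled negative set equals the set just trained on;
#' non-convergence within the cap is flagged, not an error. Scores from the
#' final iteration are returned.
#'
#' @param a_hat Normalized adjacency.
#' @param x Feature matrix (identity for featureless graphs).
#' @param node_ids Node ids aligned with the rows of `a_hat`.
#' @param positives Character vector of positive node ids.
#' @param negatives Initial negative seed set (length `pu_cfg$k_negatives`).
#' @param meta_cfg A [meta_config()].
#' @param train_cfg A [train_config()].
#' @param pu_cfg A [pu_config()].
#' @param run_seed Integer seed for this run's training streams.
#' @param score_fn Optional stub for testing: a function
#'   `(positives, negatives, iter) -> named numeric scores` replacing the
#'   train-and-score step.
#' @return List with `scores` (named numeric over all nodes), `negatives`
#'   (final set), `converged` (logical), `n_iters`.
#' @export
pu_run_once <- function(a_hat, x, node_ids, positives, negatives,
                        meta_cfg = meta_config(), train_cfg = train_config(),
                        pu_cfg = pu_config(), run_seed = pu_cfg$rng_seed,
                        score_fn = NULL) {
  k <- pu_cfg$k_negatives
  pool <- setdiff(node_ids, positives)
  converged <- FALSE
  scores <- NULL
  n_iters <- 0L
  for (iter in seq_len(pu_cfg$max_refine_iters)) {
    .check_label_state(node_ids, positives, negatives, k)
    n_iters <- iter
    if (is.null(score_fn)) {
      labels <- .pu_labels(node_ids, positives, negatives)
      # one training stream per run: the same initialization and task-sampling
      # seed across refinement iterations makes the relabeling map a
      # deterministic function of the negative set, so the set-stability
      # convergence criterion is well defined
      mcfg <- meta_cfg; mcfg$rng_seed <- mix_seed(run_seed, 1L)
      mt <- meta_train(a_hat, x, labels, mcfg)
      params <- gcn_train(a_hat, x, mt$params, labels, train_cfg)
      z <- .gcn_forward(a_hat, a_hat %*% x, params)$z
      scores <- stats::setNames(as.double(z[, 2L]), node_ids)
    } else {
      scores <- score_fn(positives, negatives, iter)
    }
    ord <- order(scores[pool], pool)
    new_neg <- pool[ord][seq_len(k)]
    if (setequal(new_neg, negatives)) {
      converged <- TRUE
      break
    }
    negatives <- new_neg
  }
  if (!converged) {
    warning(sprintf("negative relabeling did not converge within %d iterations",
                    pu_cfg$max_refine_iters))
  }
  list(scores = scores, negatives = negatives, converged = converged,
       n_iters = n_iters)
}

#' Multi-restart PU ensemble with median aggregation
#'
#' Runs `pu_cfg$n_restarts` independent PU runs, each seeded by
#' `mix_seed(pu_cfg$rng_seed, r)`: negatives are re-seeded per restart (in
#' the configured mode) and the full refinement loop is re-run. The per-node
#' median over restarts (even counts: mean of the two middle values) is the
#' final score. Runs execute sequentially; the result depends only on the
#' derived seeds, not on execution order. A failed run is recorded and
#' resampled with a fresh derived seed, up to `n_restarts` extra attempts.
#'
#' @param g An `interaction_graph`.
#' @param positives Character vector of positive node ids.
#' @param meta_cfg,train_cfg,pu_cfg Configurations.
#' @param x Optional feature matrix; identity when omitted.
#' @return An `ensemble_result`: list with `run_scores`
#'   (`n_restarts x n_nodes` matrix), `median_scores` (named), `n_runs`,
#'   `converged` (logical per run), `n_iters` (per run), `failed_seeds`.
#' @export
pu_run_ensemble <- function(g, positives, meta_cfg = meta_config(),
                            train_cfg = train_config(), pu_cfg = pu_config(),
                            x = NULL) {
  stopifnot(inherits(g, "interaction_graph"))
  a_hat <- normalize_adjacency(g)
  if (is.null(x)) x <- diag(g$n_nodes)
  R <- pu_cfg$n_restarts
  run_scores <- matrix(NA_real_, R, g$n_nodes, dimnames = list(NULL, g$node_ids))
  converged <- logical(R)
  n_iters <- integer(R)
  failed_seeds <- integer(0)
  extra <- 0L
  for (r in seq_len(R)) {
    seed_r <- mix_seed(pu_cfg$rng_seed, r)
    repeat {
      res <- tryCatch({
        negs <- seed_negatives(g, positives, pu_cfg$k_negatives,
                               mode = pu_cfg$negative_seeding, rng_seed = seed_r)
        suppressWarnings(
          pu_run_once(a_hat, x, g$node_ids, positives, negs,
                      meta_cfg, train_cfg, pu_cfg, run_seed = seed_r)
        )
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed_seeds <- c(failed_seeds, seed_r)
        extra <- extra + 1L
        if (extra > R) stop("ensemble exhausted retry budget: ", conditionMessage(res))
        seed_r <- mix_seed(pu_cfg$rng_seed, R + extra)
      } else {
        run_scores[r, ] <- res$scores[g$node_ids]
        converged[r] <- res$converged
        n_iters[r] <- res$n_iters
        break
      }
    }
  }
  structure(list(run_scores = run_scores,
                 median_scores = apply(run_scores, 2L, stats::median),
                 n_runs = R, converged = converged, n_iters = n_iters,
                 failed_seeds = failed_seeds),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d runs x %d nodes; %.0f%% converged\n",
              x$n_runs, ncol(x$run_scores), 100 * mean(x$converged)))
  invisible(x)
}

#' Select candidates above the median-score threshold
#'
#' Nodes with median score strictly greater than `threshold`, sorted by
#' descending score with ties broken by node id. Seed positives are not
#' excluded: a good run ranks them at the top.
#'
#' @param result An `ensemble_result` (or a named numeric vector of scores).
#' @param threshold Cutoff in (0, 1).
#' @return Data frame with columns `node_id`, `median_score`, ranked.
#' @export
threshold_candidates <- function(result, threshold = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  scores <- if (inherits(result, "ensemble_result")) result$median_scores else result
  sel <- scores[scores > threshold]
  ord <- order(-sel, names(sel))
  data.frame(node_id = names(sel)[ord], median_score = as.double(sel[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write the ranked score table as TSV
#'
#' All nodes, ranked by descending median score (ties by id), with columns
#' `node_id`, `median_score`, `n_runs`, `selected_flag` (1 when the median
#' exceeds the threshold).
#'
#' @param result An `ensemble_result`.
#' @param path Output path.
#' @param threshold Selection cutoff, default 0.95.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(result, path, threshold = 0.95) {
  scores <- result$median_scores
  ord <- order(-scores, names(scores))
  df <- data.frame(node_id = names(scores)[ord],
                   median_score = format(as.double(scores[ord]), digits = 15,
                                         scientific = FALSE, trim = TRUE),
                   n_runs = result$n_runs,
                   selected_flag = as.integer(scores[ord] > threshold))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
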