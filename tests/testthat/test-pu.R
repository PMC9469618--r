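# Positive-unlabeled protocol: negative seeding, refinement, ensemble,
# thresholding.

test_that("farthest-mode negative seeding follows hop distance with tie-breaks", {
  g <- path_graph(c("p", "a", "b", "c"))
  expect_equal(seed_negatives(g, "p", 1, mode = "farthest"), "c")
  expect_equal(seed_negatives(g, "p", 2, mode = "farthest"), c("c", "b"))

  # deterministic regardless of seed
  expect_identical(seed_negatives(g, "p", 2, mode = "farthest", rng_seed = 1),
                   seed_negatives(g, "p", 2, mode = "farthest", rng_seed = 999))

  # unreachable nodes rank farthest
  gz <- interaction_graph(c("p", "a", "z"),
                          data.frame(node_a = "p", node_b = "a", weight = 1))
  expect_equal(seed_negatives(gz, "p", 1, mode = "farthest"), "z")

  # equal min distance: larger total distance to all positives wins
  # star: p1 - m, p2 - m, m - u, v - p1 (v at distance 1 of p1, 3 of p2;
  # u at distance 2 of both)
  gt <- interaction_graph(c("p1", "p2", "m", "u", "v"),
                          data.frame(node_a = c("p1", "p2", "m", "v"),
                                     node_b = c("m", "m", "u", "p1"),
                                     weight = 1))
  d <- hop_distances(gt, c("p1", "p2"))
  expect_equal(d[["u"]], 2); expect_equal(d[["v"]], 1)
  expect_equal(seed_negatives(gt, c("p1", "p2"), 1, mode = "farthest"), "u")
})

test_that("random-mode seeding is uniform without replacement and seeded", {
  g <- path_graph(sprintf("n%02d", 1:12))
  s1 <- seed_negatives(g, "n01", 5, mode = "random", rng_seed = 4)
  s2 <- seed_negatives(g, "n01", 5, mode = "random", rng_seed = 4)
  expect_identical(s1, s2)
  expect_length(unique(s1), 5)
  expect_false("n01" %in% s1)

  # exhaustion: k equal to the non-positive pool returns the whole pool
  expect_setequal(seed_negatives(g, "n01", 11, mode = "random"),
                  sprintf("n%02d", 2:12))
  expect_setequal(seed_negatives(g, "n01", 11, mode = "farthest"),
                  sprintf("n%02d", 2:12))
  expect_error(seed_negatives(g, "n01", 12), "available")
})

test_that("a constant stub scorer converges at the second iteration", {
  ids <- c("p", "a", "b", "c", "d")
  g <- path_graph(ids)
  a_hat <- normalize_adjacency(g)
  stub <- function(positives, negatives, iter) {
    setNames(rep(0.5, length(ids)), ids)
  }
  pcfg <- pu_config(k_negatives = 2, n_restarts = 1, max_refine_iters = 20)
  res <- pu_run_once(a_hat, diag(5), ids, positives = "p",
                     negatives = c("c", "d"), pu_cfg = pcfg, score_fn = stub)
  # ties broken by node id: bottom-2 of {a,b,c,d} at equal score is {a,b}
  expect_setequal(res$negatives, c("a", "b"))
  expect_true(res$converged)
  expect_equal(res$n_iters, 2)

  # starting at the fixed point converges immediately
  res2 <- pu_run_once(a_hat, diag(5), ids, "p", c("a", "b"),
                      pu_cfg = pcfg, score_fn = stub)
  expect_equal(res2$n_iters, 1)

  # iteration cap of 1 without trivial convergence: flag false, one pass
  pcfg1 <- pu_config(k_negatives = 2, n_restarts = 1, max_refine_iters = 1)
  expect_warning(
    res3 <- pu_run_once(a_hat, diag(5), ids, "p", c("c", "d"),
                        pu_cfg = pcfg1, score_fn = stub),
    "did not converge")
  expect_false(res3$converged)
  expect_equal(res3$n_iters, 1)
})

test_that("refinement keeps the label partition invariants in-loop", {
  ids <- sprintf("n%02d", 1:10)
  g <- path_graph(ids)
  a_hat <- normalize_adjacency(g)
  seen <- list()
  stub <- function(positives, negatives, iter) {
    seen[[length(seen) + 1]] <<- negatives
    expect_length(intersect(positives, negatives), 0)
    expect_length(negatives, 3)
    setNames(seq_along(ids) / 20, ids)  # fixed distinct scores
  }
  res <- pu_run_once(a_hat, diag(10), ids, positives = c("n01", "n02"),
                     negatives = c("n08", "n09", "n10"),
                     pu_cfg = pu_config(k_negatives = 3, n_restarts = 1),
                     score_fn = stub)
  # lowest-scoring non-positives are n03..n05
  expect_setequal(res$negatives, c("n03", "n04", "n05"))
  expect_true(res$converged)
})

test_that("median aggregation matches the sort-based oracle and invariances", {
  expect_equal(oracle_median(c(0.2, 0.9, 0.4)), 0.4)
  expect_equal(oracle_median(c(0.2, 0.4)), 0.3)
  set.seed(88)
  for (rep in 1:20) {
    m <- matrix(runif(7 * 5), 7, 5)
    med <- apply(m, 2L, median)
    expect_equal(med, apply(m, 2L, oracle_median))
    # permutation invariance over runs
    expect_equal(apply(m[sample(7), ], 2L, median), med)
  }
})

test_that("a single-restart ensemble equals its one run and scores stay in [0,1]", {
  spec <- planted_graph_spec(n_nodes = 60, community_size = 12,
                             n_seed_positives = 6, p_in = 0.5, p_out = 0.04,
                             rng_seed = 14)
  gen <- generate_graph(spec)
  mcfg <- meta_config(n_tasks = 2, support_per_class = 2, meta_epochs = 5,
                      hidden_dim = 8)
  tcfg <- train_config(epochs = 30, hidden_dim = 8)
  pcfg <- pu_config(k_negatives = 10, n_restarts = 1, max_refine_iters = 6,
                    rng_seed = 77)
  ens <- suppressWarnings(
    pu_run_ensemble(gen$graph, gen$truth$revealed_positives, mcfg, tcfg, pcfg))
  expect_equal(ens$n_runs, 1)
  expect_equal(unname(ens$median_scores), unname(ens$run_scores[1, ]))
  expect_true(all(ens$run_scores >= 0 & ens$run_scores <= 1))

  # reproducible end to end
  ens2 <- suppressWarnings(
    pu_run_ensemble(gen$graph, gen$truth$revealed_positives, mcfg, tcfg, pcfg))
  expect_identical(ens$run_scores, ens2$run_scores)

  # directional sanity: densely connected community members score above the
  # background median
  in_comm <- gen$graph$node_ids %in% gen$truth$community_members
  bg_median <- median(ens$median_scores[!in_comm])
  unrevealed <- setdiff(gen$truth$community_members, gen$truth$revealed_positives)
  expect_gt(median(ens$median_scores[unrevealed]), bg_median)
})

test_that("refined negatives avoid the planted community across seeded runs", {
  spec <- planted_graph_spec(n_nodes = 200, community_size = 25,
                             n_seed_positives = 8, p_in = 0.4, p_out = 0.02,
                             rng_seed = 31)
  gen <- generate_graph(spec)
  a_hat <- normalize_adjacency(gen$graph)
  x <- diag(gen$graph$n_nodes)
  mcfg <- meta_config(n_tasks = 3, support_per_class = 2, meta_epochs = 10,
                      hidden_dim = 12)
  tcfg <- train_config(epochs = 60, hidden_dim = 12)
  pcfg <- pu_config(k_negatives = 40, n_restarts = 1, max_refine_iters = 15)
  clean <- 0L
  for (seed in 1:10) {
    negs <- seed_negatives(gen$graph, gen$truth$revealed_positives, 40,
                           mode = "random", rng_seed = seed)
    res <- suppressWarnings(
      pu_run_once(a_hat, x, gen$graph$node_ids, gen$truth$revealed_positives,
                  negs, mcfg, tcfg, pcfg, run_seed = seed))
    if (!any(res$negatives %in% gen$truth$community_members)) clean <- clean + 1L
  }
  expect_gte(clean, 9)
})

test_that("the rank-statistic AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(66)
  for (rep in 1:10) {
    labels <- c(rep(TRUE, 15), rep(FALSE, 35))
    scores <- rnorm(50, mean = ifelse(labels, 0.8, 0.2), sd = 0.5)
    expect_equal(auc_score(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(auc_score(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("thresholding applies the strict cutoff and deterministic ordering", {
  scores <- c(a = 0.96, b = 0.95, c = 0.99)
  t95 <- threshold_candidates(scores, 0.95)
  expect_equal(t95$node_id, c("c", "a"))  # 0.95 itself excluded
  t50 <- threshold_candidates(scores, 0.5)
  expect_equal(t50$node_id, c("c", "a", "b"))
  expect_equal(nrow(threshold_candidates(c(a = 0.1, b = 0.2), 0.95)), 0)
  # ties broken by node id
  tie <- threshold_candidates(c(z = 0.98, a = 0.98, m = 0.97), 0.5)
  expect_equal(tie$node_id, c("a", "z", "m"))
  expect_error(threshold_candidates(scores, 1.5))
})

test_that("the ranked score table writes the documented columns", {
  ens <- structure(list(run_scores = matrix(c(0.9, 0.8, 0.2, 0.4), 2, 2,
                                            dimnames = list(NULL, c("a", "b"))),
                        median_scores = c(a = 0.85, b = 0.3),
                        n_runs = 2, converged = c(TRUE, TRUE),
                        n_iters = c(2L, 2L), failed_seeds = integer()),
                   class = "ensemble_result")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(ens, path, threshold = 0.5)
  tab <- read.delim(path)
  expect_equal(names(tab), c("node_id", "median_score", "n_runs", "selected_flag"))
  expect_equal(tab$node_id, c("a", "b"))
  expect_equal(tab$selected_flag, c(1L, 0L))
})
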