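# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use different code paths (entry-wise loops, exhaustive
# enumeration, finite differences) from the implementation they check.

# Entry-wise normalization oracle: a_hat[i,j] = (A+I)[i,j] / sqrt(dt_i dt_j).
oracle_normalize <- function(adj) {
  n <- nrow(adj)
  at <- adj
  for (i in seq_len(n)) at[i, i] <- at[i, i] + 1
  dt <- sapply(seq_len(n), function(i) sum(at[i, ]))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- at[i, j] / sqrt(dt[i] * dt[j])
    }
  }
  out
}

# Floyd-Warshall all-pairs hop distances on the unweighted topology.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Step-by-step dense forward oracle with per-row unshifted softmax.
oracle_forward <- function(a_hat, x, W0, W1) {
  s1 <- a_hat %*% x %*% W0
  h1 <- ifelse(s1 > 0, s1, 0)
  logits <- a_hat %*% h1 %*% W1
  t(apply(logits, 1L, function(r) exp(r) / sum(exp(r))))
}

# Central finite differences of the cross-entropy loss w.r.t. all parameters.
oracle_fd_gradients <- function(a_hat, x, params, labels, h = 1e-6) {
  loss_at <- function(p) {
    z <- gcn_forward(a_hat, x, p)$z
    cross_entropy_loss(z, labels)
  }
  out <- list()
  for (nm in c("W0", "W1")) {
    g <- array(0, dim(params[[nm]]))
    for (i in seq_along(g)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      g[i] <- (loss_at(gcn_params(pp$W0, pp$W1)) -
                 loss_at(gcn_params(pm$W0, pm$W1))) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

# Exhaustive hypergeometric upper tail: P(overlap >= k).
oracle_hyper_upper <- function(k, set_size, universe_size, n_draws) {
  j <- k:min(set_size, n_draws)
  sum(choose(set_size, j) * choose(universe_size - set_size, n_draws - j)) /
    choose(universe_size, n_draws)
}

# Sort-based sample median (even count: mean of the two middle values).
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Random small weighted graph for oracle comparisons.
random_test_graph <- function(n, p = 0.3) {
  ids <- sprintf("n%02d", seq_len(n))
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- runif(1, 0.1, 1)
    }
  }
  structure(list(node_ids = ids, adjacency = adj, n_nodes = n),
            class = "interaction_graph")
}

# Small two-clique graph: nodes 1..n1 fully connected, nodes n1+1..n1+n2
# fully connected, one optional bridge. Linearly separable for the GCN.
two_clique_graph <- function(n1 = 5, n2 = 5, bridge = FALSE) {
  n <- n1 + n2
  ids <- sprintf("v%02d", seq_len(n))
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  adj[seq_len(n1), seq_len(n1)] <- 1
  adj[(n1 + 1):n, (n1 + 1):n] <- 1
  diag(adj) <- 0
  if (bridge) adj[n1, n1 + 1] <- adj[n1 + 1, n1] <- 1
  structure(list(node_ids = ids, adjacency = adj, n_nodes = n),
            class = "interaction_graph")
}

# Path graph over the given ids.
path_graph <- function(ids) {
  edges <- data.frame(node_a = ids[-length(ids)], node_b = ids[-1], weight = 1)
  interaction_graph(ids, edges)
}

# Desk-scale training configurations used by the heavier fixtures.
desk_meta_cfg <- function(seed = 1L) {
  meta_config(n_tasks = 4L, support_per_class = 3L, meta_epochs = 20L,
              rng_seed = seed)
}
desk_train_cfg <- function() train_config(epochs = 100L)
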