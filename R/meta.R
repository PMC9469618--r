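# Episodic (first-order MAML-style) meta-learning of GCN initial parameters.
#
# Each episode samples a task: a small per-class support set and the
# remaining labeled nodes as the query set. The inner loop takes plain
# gradient-descent steps on the support loss; the outer loop updates the
# meta-parameters with Adam on the summed query losses, using the first-order
# approximation (the outer gradient is the query-loss gradient evaluated at
# the adapted parameters, no second derivatives).

#' Meta-training configuration
#'
#' @param n_tasks Number of tasks M sampled per meta-epoch, default 8.
#' @param support_per_class Support nodes drawn per class, default 5. Each
#'   class must have strictly more labeled nodes than this.
#' @param inner_lr Inner-loop (plain gradient descent) step size, default 0.1.
#' @param outer_lr Outer-loop Adam step size, default 0.01.
#' @param inner_steps Inner gradient steps per task, default 1.
#' @param meta_epochs Outer rounds, default 50.
#' @param hidden_dim Hidden width of the underlying GCN, default 16.
#' @param rng_seed Integer seed for task sampling and initialization.
#' @return A `meta_config` list.
#' @export
meta_config <- function(n_tasks = 8L, support_per_class = 5L, inner_lr = 0.1,
                        outer_lr = 0.01, inner_steps = 1L, meta_epochs = 50L,
                        hidden_dim = 16L, rng_seed = 1L) {
  stopifnot(n_tasks >= 1, support_per_class >= 1, inner_lr > 0, outer_lr > 0,
            inner_steps >= 1, meta_epochs >= 0, hidden_dim >= 1)
  list(n_tasks = as.integer(n_tasks),
       support_per_class = as.integer(support_per_class),
       inner_lr = inner_lr, outer_lr = outer_lr,
       inner_steps = as.integer(inner_steps),
       meta_epochs = as.integer(meta_epochs),
       hidden_dim = as.integer(hidden_dim),
       rng_seed = as.integer(rng_seed))
}

#' Sample support/query tasks from the labeled training set
#'
#' For each of `cfg$n_tasks` tasks, `cfg$support_per_class` nodes per class
#' are drawn uniformly without replacement as the support set; all remaining
#' labeled nodes form the query set, so support and query partition the
#' training labels.
#'
#' @param train_labels Named integer vector (node index -> class).
#' @param cfg A [meta_config()].
#' @param seed Integer seed; defaults to `cfg$rng_seed`.
#' @return List of tasks, each a list with named label vectors `support` and
#'   `query`.
#' @export
sample_meta_tasks <- function(train_labels, cfg, seed = cfg$rng_seed) {
  classes <- sort(unique(as.integer(train_labels)))
  for (cl in classes) {
    n_cl <- sum(train_labels == cl)
    if (n_cl <= cfg$support_per_class) {
      stop(sprintf("class %d has %d labeled nodes; need more than support_per_class = %d",
                   cl, n_cl, cfg$support_per_class))
    }
  }
  with_seed(seed, {
    lapply(seq_len(cfg$n_tasks), function(t) {
      sup_names <- unlist(lapply(classes, function(cl) {
        pool <- names(train_labels)[train_labels == cl]
        sample(pool, cfg$support_per_class)
      }), use.names = FALSE)
      support <- train_labels[sup_names]
      query <- train_labels[setdiff(names(train_labels), sup_names)]
      list(support = support, query = query)
    })
  })
}

#' Inner-loop adaptation on one task's support set
#'
#' Takes `cfg$inner_steps` plain gradient-descent steps of size
#' `cfg$inner_lr` on the support-set cross-entropy, starting from `params`.
#'
#' @param params Starting `gcn_params` (the current meta-parameters).
#' @param task One task from [sample_meta_tasks()].
#' @param a_hat,x Graph inputs as in [gcn_forward()].
#' @param cfg A [meta_config()].
#' @return Adapted `gcn_params`.
#' @export
inner_adapt <- function(params, task, a_hat, x, cfg) {
  ax <- a_hat %*% x
  .inner_adapt_ax(params, task, a_hat, ax, cfg)
}

.inner_adapt_ax <- function(params, task, a_hat, ax, cfg) {
  for (s in seq_len(cfg$inner_steps)) {
    g <- .gcn_grad(a_hat, ax, params, task$support)
    params$W0 <- params$W0 - cfg$inner_lr * g$W0
    params$W1 <- params$W1 - cfg$inner_lr * g$W1
  }
  params
}

#' Meta-train GCN initial parameters over sampled tasks
#'
#' For each of `cfg$meta_epochs` rounds: sample `cfg$n_tasks` tasks, adapt
#' the meta-parameters on each task's support set ([inner_adapt()]), evaluate
#' the query-set loss and its gradient at the adapted parameters, and take
#' one Adam step (step size `cfg$outer_lr`) on the summed query gradients.
#' First-order approximation throughout. Per-task support and query losses
#' are logged each round.
#'
#' @param a_hat,x Graph inputs.
#' @param train_labels Named integer vector (node index -> class).
#' @param cfg A [meta_config()].
#' @param init_params Optional starting `gcn_params`; Glorot-initialized from
#'   `cfg$rng_seed` when omitted.
#' @param n_classes Number of classes (default 2).
#' @return List with `params` (the meta-learned initialization) and `log`
#'   (data frame: round, task_index, support_loss, query_loss).
#' @export
meta_train <- function(a_hat, x, train_labels, cfg = meta_config(),
                       init_params = NULL, n_classes = 2L) {
  if (is.null(init_params)) {
    init_params <- glorot_init(ncol(x), cfg$hidden_dim, n_classes,
                               seed = mix_seed(cfg$rng_seed, 0L))
  }
  params <- init_params
  ax <- a_hat %*% x
  state <- .adam_init(params)
  log_rows <- vector("list", cfg$meta_epochs)
  for (ep in seq_len(cfg$meta_epochs)) {
    tasks <- sample_meta_tasks(train_labels, cfg, seed = mix_seed(cfg$rng_seed, ep))
    gsum <- list(W0 = array(0, dim(params$W0)), W1 = array(0, dim(params$W1)))
    sup_loss <- query_loss <- numeric(length(tasks))
    for (ti in seq_along(tasks)) {
      task <- tasks[[ti]]
      fw0 <- .gcn_forward(a_hat, ax, params)
      sup_loss[ti] <- cross_entropy_loss(fw0$z, task$support)
      adapted <- .inner_adapt_ax(params, task, a_hat, ax, cfg)
      fw1 <- .gcn_forward(a_hat, ax, adapted)
      query_loss[ti] <- cross_entropy_loss(fw1$z, task$query)
      gq <- .gcn_grad(a_hat, ax, adapted, task$query, fw1)
      gsum$W0 <- gsum$W0 + gq$W0
      gsum$W1 <- gsum$W1 + gq$W1
    }
    if (!all(is.finite(query_loss))) {
      stop(sprintf("non-finite meta-loss at round %d", ep))
    }
    upd <- .adam_step(params, gsum, state, cfg$outer_lr)
    params <- upd$params
    state <- upd$state
    log_rows[[ep]] <- data.frame(round = ep, task_index = seq_along(tasks),
                                 support_loss = sup_loss, query_loss = query_loss)
  }
  log <- if (cfg$meta_epochs > 0) do.call(rbind, log_rows) else
    data.frame(round = integer(), task_index = integer(),
               support_loss = numeric(), query_loss = numeric())
  list(params = params, log = log)
}

#' Write a meta-training log as TSV
#' @param log Log data frame from [meta_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
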