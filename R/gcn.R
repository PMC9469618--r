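# Two-layer graph convolutional classifier: forward pass, cross-entropy
# loss, analytic backpropagation, and Adam training.
#
# The forward map is
#   Z = softmax( A_hat %*% ReLU(A_hat %*% X %*% W0) %*% W1 )
# so each output row aggregates its second-order neighbourhood through the
# symmetric normalized adjacency A_hat. With identity features (the default
# for the cytokine graph) X %*% W0 is just W0, and the model is effectively
# learning a per-node embedding smoothed twice over the graph.

#' Construct a GCN parameter pair
#'
#' @param W0 Numeric matrix `n_features x hidden_dim`.
#' @param W1 Numeric matrix `hidden_dim x n_classes`.
#' @return A `gcn_params` object.
#' @export
gcn_params <- function(W0, W1) {
  W0 <- as.matrix(W0); W1 <- as.matrix(W1)
  if (ncol(W0) != nrow(W1)) {
    stop(sprintf("shape mismatch: W0 is %dx%d but W1 is %dx%d (need ncol(W0) == nrow(W1))",
                 nrow(W0), ncol(W0), nrow(W1), ncol(W1)))
  }
  if (!all(is.finite(W0)) || !all(is.finite(W1))) stop("parameters must be finite")
  structure(list(W0 = W0, W1 = W1), class = "gcn_params")
}

#' Glorot-uniform initialization of GCN parameters
#'
#' Each weight matrix is drawn uniformly on `[-L, L]` with
#' `L = sqrt(6 / (fan_in + fan_out))`, from an RNG stream seeded with `seed`;
#' the caller's RNG state is untouched.
#'
#' @param n_features,hidden_dim,n_classes Layer sizes.
#' @param seed Integer seed.
#' @return A `gcn_params` object.
#' @export
glorot_init <- function(n_features, hidden_dim, n_classes, seed) {
  with_seed(seed, {
    l0 <- sqrt(6 / (n_features + hidden_dim))
    W0 <- matrix(runif(n_features * hidden_dim, -l0, l0), n_features, hidden_dim)
    l1 <- sqrt(6 / (hidden_dim + n_classes))
    W1 <- matrix(runif(hidden_dim * n_classes, -l1, l1), hidden_dim, n_classes)
    gcn_params(W0, W1)
  })
}

#' Training configuration for the base learner
#'
#' @param learning_rate Adam step size, default 0.01.
#' @param epochs Number of full-graph optimizer steps, default 200.
#' @param hidden_dim Hidden layer width, default 16.
#' @param optimizer Only `"adam"` is supported.
#' @param rng_seed Integer seed controlling weight initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 200L, hidden_dim = 16L,
                         optimizer = "adam", rng_seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 0, hidden_dim >= 1,
            identical(optimizer, "adam"))
  list(learning_rate = learning_rate, epochs = as.integer(epochs),
       hidden_dim = as.integer(hidden_dim), optimizer = optimizer,
       rng_seed = as.integer(rng_seed))
}

# Internal forward pass keeping intermediates for backprop.
# ax = A_hat %*% X may be precomputed by hot loops.
.gcn_forward <- function(a_hat, ax, params) {
  s1 <- ax %*% params$W0            # pre-activation, n x hidden
  h1 <- pmax(s1, 0)                 # ReLU
  ah1 <- a_hat %*% h1
  logits <- ah1 %*% params$W1
  z <- softmax_rows(logits)
  list(z = z, s1 = s1, h1 = h1, ah1 = ah1)
}

#' GCN forward propagation
#'
#' Computes `Z = softmax(A_hat ReLU(A_hat X W0) W1)`; every row of `Z` is a
#' probability distribution over the classes.
#'
#' @param a_hat Normalized adjacency from [normalize_adjacency()].
#' @param x Feature matrix, `n_nodes x n_features` (identity by convention for
#'   featureless graphs).
#' @param params A `gcn_params` object.
#' @return List with `z` (the prediction matrix), and the hidden intermediates
#'   `s1`, `h1`, `ah1` used by backpropagation.
#' @export
gcn_forward <- function(a_hat, x, params) {
  stopifnot(inherits(params, "gcn_params"))
  if (ncol(a_hat) != nrow(x)) {
    stop(sprintf("shape mismatch: a_hat is %dx%d but x has %d rows",
                 nrow(a_hat), ncol(a_hat), nrow(x)))
  }
  if (ncol(x) != nrow(params$W0)) {
    stop(sprintf("shape mismatch: x has %d columns but W0 has %d rows",
                 ncol(x), nrow(params$W0)))
  }
  .gcn_forward(a_hat, a_hat %*% x, params)
}

#' Cross-entropy loss over labeled nodes
#'
#' Sums `-log z[i, y_i]` over the labeled nodes; with two classes this is the
#' binary cross-entropy `-(y log f + (1 - y) log(1 - f))` of the positive
#' probability `f`. Probabilities are clipped to `[1e-12, 1 - 1e-12]` before
#' the log.
#'
#' @param z Prediction matrix (rows sum to 1).
#' @param labels Named integer vector: names are node indices (as character),
#'   values are class indices in `1..n_classes`.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(z, labels) {
  if (length(labels) == 0) stop("loss undefined for an empty label set")
  idx <- as.integer(names(labels))
  stopifnot(all(idx >= 1), all(idx <= nrow(z)),
            all(labels >= 1), all(labels <= ncol(z)))
  p <- clip_prob(z[cbind(idx, as.integer(labels))])
  -sum(log(p))
}

# Backprop of cross_entropy_loss through softmax, the second convolution,
# ReLU, and the first convolution. ReLU subgradient at 0 is taken as 0.
.gcn_grad <- function(a_hat, ax, params, labels, fw = NULL) {
  if (is.null(fw)) fw <- .gcn_forward(a_hat, ax, params)
  n <- nrow(fw$z); C <- ncol(fw$z)
  idx <- as.integer(names(labels))
  dlogits <- matrix(0, n, C)
  dlogits[cbind(idx, as.integer(labels))] <- -1
  dlogits[idx, ] <- dlogits[idx, , drop = FALSE] + fw$z[idx, , drop = FALSE]
  adl <- a_hat %*% dlogits                       # A_hat^T = A_hat
  gW1 <- crossprod(fw$h1, adl)
  dh1 <- adl %*% t(params$W1)
  dh1[fw$s1 <= 0] <- 0
  gW0 <- crossprod(ax, dh1)
  list(W0 = gW0, W1 = gW1)
}

#' Analytic gradients of the cross-entropy loss
#'
#' Exact backpropagation gradients of [cross_entropy_loss()] with respect to
#' `W0` and `W1`.
#'
#' @inheritParams gcn_forward
#' @param labels As in [cross_entropy_loss()].
#' @return List with matrices `W0`, `W1`, shaped like `params`.
#' @export
gcn_gradients <- function(a_hat, x, params, labels) {
  if (length(labels) == 0) stop("loss undefined for an empty label set")
  .gcn_grad(a_hat, a_hat %*% x, params, labels)
}

# One Adam step; state carries first/second moments and the step counter.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in c("W0", "W1")) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    m_hat <- state$m[[nm]] / (1 - beta1^state$t)
    v_hat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(params = params, state = state)
}

.adam_init <- function(params) {
  zero <- lapply(params[c("W0", "W1")], function(w) array(0, dim(w)))
  list(t = 0L, m = zero, v = zero)
}

#' Train the GCN with Adam
#'
#' Runs `cfg$epochs` full-graph Adam steps (beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8) on the labeled cross-entropy, starting from `init_params`.
#' Deterministic given the inputs; with `epochs = 0` the initial parameters
#' are returned unchanged.
#'
#' @inheritParams gcn_forward
#' @param init_params Starting `gcn_params`.
#' @param labels As in [cross_entropy_loss()]; non-empty.
#' @param cfg A [train_config()].
#' @return Trained `gcn_params`.
#' @export
gcn_train <- function(a_hat, x, init_params, labels, cfg = train_config()) {
  if (length(labels) == 0) stop("cannot train with an empty label set")
  ax <- a_hat %*% x
  params <- init_params
  state <- .adam_init(params)
  for (ep in seq_len(cfg$epochs)) {
    fw <- .gcn_forward(a_hat, ax, params)
    loss <- cross_entropy_loss(fw$z, labels)
    if (!is.finite(loss)) {
      stop(sprintf("non-finite training loss at epoch %d", ep))
    }
    g <- .gcn_grad(a_hat, ax, params, labels, fw)
    upd <- .adam_step(params, g, state, cfg$learning_rate)
    params <- upd$params
    state <- upd$state
  }
  params
}

#' Write / read a GCN parameter checkpoint
#'
#' Flat JSON container with the two weight matrices (full double precision)
#' and an optional config snapshot; round-trips to the values written.
#'
#' @param params A `gcn_params`.
#' @param path Output path.
#' @param config Optional list stored alongside the weights.
#' @return `path` invisibly; `read_gcn_checkpoint()` returns a list with
#'   `params` and `config`.
#' @export
write_gcn_checkpoint <- function(params, path, config = NULL) {
  obj <- list(W0 = params$W0, W1 = params$W1,
              dim0 = dim(params$W0), dim1 = dim(params$W1),
              config = config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gcn_checkpoint
#' @export
read_gcn_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W0 <- matrix(as.double(obj$W0), obj$dim0[1], obj$dim0[2])
  W1 <- matrix(as.double(obj$W1), obj$dim1[1], obj$dim1[2])
  list(params = gcn_params(W0, W1), config = obj$config)
}
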