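# Interaction-graph ingestion, validation, normalization and hop distances.

#' Construct an interaction graph from an edge table
#'
#' The graph is undirected and weighted: `adjacency[i, j]` holds the edge
#' weight between nodes `i` and `j` (0 means no edge), is symmetric, has a
#' zero diagonal, and all weights are finite and non-negative. Node identity
#' is exact string match; no alias or capitalization merging is attempted.
#'
#' @param node_ids Character vector of unique node identifiers. Nodes with no
#'   edges are allowed.
#' @param edges Data frame with columns `node_a`, `node_b`, `weight`, one row
#'   per undirected edge. May be empty.
#' @return An `interaction_graph` object: list with `node_ids`, `adjacency`
#'   (dense symmetric matrix with dimnames), `n_nodes`.
#' @export
interaction_graph <- function(node_ids, edges = NULL) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) {
    stop("duplicate node ids: ", paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "))
  }
  n <- length(node_ids)
  adj <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  if (!is.null(edges) && nrow(edges) > 0) {
    ia <- match(edges$node_a, node_ids)
    ib <- match(edges$node_b, node_ids)
    if (anyNA(ia) || anyNA(ib)) {
      missing <- unique(c(edges$node_a[is.na(ia)], edges$node_b[is.na(ib)]))
      stop("edge endpoints not in node_ids: ", paste(missing, collapse = ", "))
    }
    if (any(ia == ib)) stop("self-loops are not allowed before normalization")
    w <- as.double(edges$weight)
    if (any(!is.finite(w)) || any(w < 0)) stop("edge weights must be finite and >= 0")
    adj[cbind(ia, ib)] <- w
    adj[cbind(ib, ia)] <- w
  }
  structure(list(node_ids = node_ids, adjacency = adj, n_nodes = n),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  m <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat(sprintf("<interaction_graph> %d nodes, %d edges\n", x$n_nodes, m))
  invisible(x)
}

#' Number of undirected edges in an interaction graph
#' @param g An `interaction_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  sum(g$adjacency[upper.tri(g$adjacency)] > 0)
}

#' Load a STRING-style interaction TSV
#'
#' Expects tab-separated columns `node_a`, `node_b`, `score`. A header line is
#' detected (non-numeric third column) and skipped; lines starting with `#`
#' are comments. Duplicate `(a, b)` / `(b, a)` rows are collapsed keeping the
#' maximum score; rows with `score < score_threshold` (on the input scale,
#' before any rescaling) are dropped. When any input score exceeds 1 the
#' scores are taken to follow the STRING 0-1000 convention and all are
#' divided by 1000 to give weights in (0, 1]; otherwise they are used as-is.
#'
#' @param path Path to the TSV file.
#' @param score_threshold Non-negative minimum score, applied on the input
#'   scale. Default 0 keeps every supplied edge.
#' @param node_ids Optional character vector of node ids to include even when
#'   they have no surviving edges (e.g. a full node-list file); ids seen in
#'   edges are appended to it.
#' @return An `interaction_graph`.
#' @export
load_interactions <- function(path, score_threshold = 0, node_ids = NULL) {
  stopifnot(file.exists(path), score_threshold >= 0)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(interaction_graph(node_ids %||% character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0) {
    stop(sprintf("malformed interaction row at line %d: expected 3 tab-separated fields",
                 line_no[bad[1]]))
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  s_raw <- vapply(parts, `[[`, character(1), 3L)
  s <- suppressWarnings(as.numeric(s_raw))
  # header: first row only, non-numeric score field
  if (is.na(s[1]) && length(s) >= 1) {
    a <- a[-1]; b <- b[-1]; s <- s[-1]; line_no <- line_no[-1]
  }
  if (anyNA(s)) {
    stop(sprintf("malformed interaction row at line %d: non-numeric score",
                 line_no[which(is.na(s))[1]]))
  }
  if (any(s < 0)) {
    stop(sprintf("malformed interaction row at line %d: negative score",
                 line_no[which(s < 0)[1]]))
  }
  drop <- s < score_threshold
  a <- a[!drop]; b <- b[!drop]; s <- s[!drop]
  if (any(a == b)) {
    stop(sprintf("malformed interaction row at line %d: self-interaction",
                 line_no[!drop][which(a == b)[1]]))
  }
  # undirected dedup: canonical order, keep max score
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key) > 0) {
    s <- tapply(s, key, max)
    pair <- strsplit(names(s), "\r", fixed = TRUE)
    lo <- vapply(pair, `[[`, character(1), 1L)
    hi <- vapply(pair, `[[`, character(1), 2L)
    s <- as.double(s)
  }
  if (length(s) > 0 && max(s) > 1) s <- s / 1000
  ids <- unique(c(as.character(node_ids %||% character()), lo, hi))
  interaction_graph(ids, data.frame(node_a = lo, node_b = hi, weight = s,
                                    stringsAsFactors = FALSE))
}

#' Write an interaction graph as a TSV mirroring the reader
#'
#' Writes header `node_a<TAB>node_b<TAB>score`, one row per undirected edge in
#' canonical (lexicographic) order, so `load_interactions()` round-trips the
#' graph exactly.
#'
#' @param g An `interaction_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(g, path) {
  stopifnot(inherits(g, "interaction_graph"))
  ut <- which(upper.tri(g$adjacency) & g$adjacency > 0, arr.ind = TRUE)
  a <- g$node_ids[ut[, 1]]
  b <- g$node_ids[ut[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  w <- g$adjacency[ut]
  ord <- order(lo, hi)
  df <- data.frame(node_a = lo[ord], node_b = hi[ord],
                   score = format(w[ord], digits = 17, scientific = FALSE, trim = TRUE))
  writeLines(c("node_a\tnode_b\tscore",
               paste(df$node_a, df$node_b, df$score, sep = "\t")), path)
  invisible(path)
}

#' Read a node-list TSV
#'
#' One id per line; the first tab-separated column is used. `#` comments and
#' blank lines are skipped; a `node_id`/`id`/`name` header is dropped.
#'
#' @param path Path to the file.
#' @return Character vector of node ids.
#' @export
load_node_list <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (length(ids) > 0 && tolower(ids[1]) %in% c("node_id", "id", "name", "cytokine")) {
    ids <- ids[-1]
  }
  ids
}

#' Symmetric degree-normalized adjacency with self-loops
#'
#' Returns `D^(-1/2) (A + I) D^(-1/2)` where `D` is the diagonal degree matrix
#' of `A + I`. This is the propagation operator of the graph convolution:
#' every node aggregates its neighbours (and itself) with weights scaled by
#' both endpoint degrees. Isolated nodes keep only their self-loop and map to
#' a diagonal entry of 1. All eigenvalues of the result lie in `[-1, 1]`.
#'
#' @param g An `interaction_graph`.
#' @return Dense symmetric matrix of size `n_nodes x n_nodes`.
#' @export
normalize_adjacency <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  a_tilde <- g$adjacency
  diag(a_tilde) <- diag(a_tilde) + 1
  d <- rowSums(a_tilde)
  inv_sqrt <- 1 / sqrt(d)
  a_hat <- a_tilde * tcrossprod(inv_sqrt)
  dimnames(a_hat) <- dimnames(g$adjacency)
  a_hat
}

#' Minimum hop distance from each node to a source set
#'
#' Unweighted shortest-path hop counts on the graph topology (edge weights are
#' ignored; any positive weight is an edge). Sources map to 0; nodes with no
#' path to any source map to `Inf`, which orders them as farther than every
#' reachable node.
#'
#' @param g An `interaction_graph`.
#' @param sources Character vector of source node ids (non-empty, all in the
#'   graph).
#' @return Named numeric vector over all nodes: hop counts, `Inf` if
#'   unreachable.
#' @export
hop_distances <- function(g, sources) {
  stopifnot(inherits(g, "interaction_graph"))
  sources <- unique(as.character(sources))
  if (length(sources) == 0) stop("sources must be non-empty")
  missing <- setdiff(sources, g$node_ids)
  if (length(missing) > 0) {
    stop("unknown source ids: ", paste(missing, collapse = ", "))
  }
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency > 0, mode = "undirected")
  d <- igraph::distances(ig, v = sources, to = igraph::V(ig))
  res <- apply(d, 2L, min)
  names(res) <- g$node_ids
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
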