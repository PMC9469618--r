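# Synthetic planted-community interaction graphs and overlapping pathway
# collections. The generator emulates the structure the analysis assumes: a
# sparse weighted PPI-style graph containing one densely interconnected
# "positive" community from which a handful of seed positives are revealed,
# plus a pathway collection whose sets overlap the community so enrichment
# and crosstalk structure exist downstream.

#' Specification of a planted-community graph
#'
#' Planted-partition (stochastic block) model: background pairs are connected
#' independently with probability `p_out`, pairs inside the planted community
#' with probability `p_in > p_out`. Edge weights mimic rescaled
#' medium-to-high-confidence interaction scores (uniform on
#' `[weight_min, weight_max]` by default).
#'
#' @param n_nodes Total nodes.
#' @param community_size Planted community size.
#' @param n_seed_positives Number of community members revealed as positives.
#' @param p_in,p_out Within-community / background edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param weight_min,weight_max Edge-weight range, default `[0.4, 1]`.
#' @param rng_seed Integer seed.
#' @return A `planted_graph_spec` list.
#' @export
planted_graph_spec <- function(n_nodes, community_size, n_seed_positives,
                               p_in, p_out, weight_min = 0.4, weight_max = 1.0,
                               rng_seed = 1L) {
  stopifnot(n_seed_positives <= community_size, community_size <= n_nodes,
            p_out >= 0, p_out < p_in, p_in <= 1,
            weight_min > 0, weight_min <= weight_max, weight_max <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 community_size = as.integer(community_size),
                 n_seed_positives = as.integer(n_seed_positives),
                 p_in = p_in, p_out = p_out,
                 weight_min = weight_min, weight_max = weight_max,
                 rng_seed = as.integer(rng_seed)),
            class = "planted_graph_spec")
}

#' Desk-scale fixture specification
#'
#' The default test-bench conditions: 400 nodes, a 40-node planted community,
#' 10 revealed seed positives, `p_in = 0.3`, `p_out = 0.01`.
#'
#' @param rng_seed Integer seed.
#' @return A `planted_graph_spec`.
#' @export
desk_scale_spec <- function(rng_seed = 1L) {
  planted_graph_spec(n_nodes = 400L, community_size = 40L,
                     n_seed_positives = 10L, p_in = 0.3, p_out = 0.01,
                     rng_seed = rng_seed)
}

#' Study-scale specification
#'
#' Emulates the published cytokine network: 1615 nodes, a 128-node positive
#' community, 20 revealed seeds, and `p_out` solved in closed form so the
#' expected total edge count equals 62,576 given `p_in = 0.25` in the
#' planted block:
#' `E[m] = C(n,2) p_out + C(c,2) (p_in - p_out)`.
#'
#' @param rng_seed Integer seed.
#' @return A `planted_graph_spec` with `n_nodes = 1615`,
#'   `community_size = 128`, `n_seed_positives = 20`.
#' @export
study_scale_spec <- function(rng_seed = 1L) {
  n <- 1615L; cs <- 128L; m_target <- 62576
  p_in <- 0.25
  pairs_all <- choose(n, 2)
  pairs_in <- choose(cs, 2)
  p_out <- (m_target - pairs_in * p_in) / (pairs_all - pairs_in)
  planted_graph_spec(n_nodes = n, community_size = cs, n_seed_positives = 20L,
                     p_in = p_in, p_out = p_out, rng_seed = rng_seed)
}

#' Expected edge count of a planted-community specification
#' @param spec A `planted_graph_spec`.
#' @return Expected number of undirected edges under the block model.
#' @export
expected_edges <- function(spec) {
  pairs_all <- choose(spec$n_nodes, 2)
  pairs_in <- choose(spec$community_size, 2)
  pairs_all * spec$p_out + pairs_in * (spec$p_in - spec$p_out)
}

#' Generate a planted-community interaction graph
#'
#' Samples the block model of `spec`: community members are drawn uniformly,
#' every node pair is connected independently (probability `p_in` inside the
#' community, `p_out` otherwise), and each edge gets a weight uniform on
#' `[weight_min, weight_max]`. Fully deterministic given `spec$rng_seed`.
#'
#' @param spec A `planted_graph_spec`.
#' @return List with `graph` (an `interaction_graph`) and `truth` (list with
#'   `community_members`, `revealed_positives`).
#' @export
generate_graph <- function(spec) {
  stopifnot(inherits(spec, "planted_graph_spec"))
  n <- spec$n_nodes
  width <- max(4L, nchar(as.character(n)))
  node_ids <- sprintf(paste0("C%0", width, "d"), seq_len(n))
  with_seed(spec$rng_seed, {
    community <- sort(sample(node_ids, spec$community_size))
    revealed <- sort(sample(community, spec$n_seed_positives))
    in_comm <- node_ids %in% community
    adj <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
    ut <- which(upper.tri(adj))
    ri <- ((ut - 1L) %% n) + 1L
    ci <- ((ut - 1L) %/% n) + 1L
    p_pair <- ifelse(in_comm[ri] & in_comm[ci], spec$p_in, spec$p_out)
    hit <- ut[stats::runif(length(ut)) < p_pair]
    w <- stats::runif(length(hit), spec$weight_min, spec$weight_max)
    adj[hit] <- w
    adj <- adj + t(adj)
    g <- structure(list(node_ids = node_ids, adjacency = adj, n_nodes = n),
                   class = "interaction_graph")
    list(graph = g,
         truth = list(community_members = community,
                      revealed_positives = revealed))
  })
}

#' Generate a pathway collection overlapping the planted community
#'
#' Builds a GMT-style collection in which half the pathways draw genes from
#' the planted community (so they enrich for community candidates) and half
#' are background-only. Among the community pathways, three pairs are
#' constructed with controlled shared-gene counts so the crosstalk filter
#' cascade has known positives and negatives by design:
#'
#' * a "pass" pair sharing `overlap_profile$pass_shared` community genes with
#'   a high Jaccard/overlap score,
#' * a "fail-shared" pair sharing `overlap_profile$fail_shared` (< 4) genes,
#' * a "fail-score" pair sharing exactly 4 genes but diluted over large sets
#'   so the mean of Jaccard and overlap coefficients stays at or below 0.3.
#'
#' Community pathways also receive a few background genes so set membership
#' and enriched overlap differ.
#'
#' @param truth Truth list from [generate_graph()] (`community_members`).
#' @param universe Character vector of all node ids in the graph.
#' @param n_pathways Total number of pathways (>= 8).
#' @param overlap_profile List with `pass_shared` (default 6) and
#'   `fail_shared` (default 3).
#' @param rng_seed Integer seed.
#' @return List with `gsc` (a `geneset_collection`) and `design` (list naming
#'   the engineered pairs: `pass_pair`, `fail_shared_pair`,
#'   `fail_score_pair`).
#' @export
generate_genesets <- function(truth, universe, n_pathways = 10L,
                              overlap_profile = list(pass_shared = 6L,
                                                     fail_shared = 3L),
                              rng_seed = 1L) {
  stopifnot(n_pathways >= 8)
  comm <- sort(truth$community_members)
  bg <- sort(setdiff(universe, comm))
  pass_shared <- overlap_profile$pass_shared %||% 6L
  fail_shared <- overlap_profile$fail_shared %||% 3L
  if (pass_shared < 4L) stop("infeasible overlap_profile: pass_shared must be >= 4")
  if (fail_shared >= 4L) stop("infeasible overlap_profile: fail_shared must be < 4")
  # engineered pairs use disjoint stretches of the community member list
  need <- (pass_shared + 4L) + (12L - fail_shared) + 20L
  if (length(comm) < need) {
    stop(sprintf("infeasible overlap_profile: community of %d too small (need %d)",
                 length(comm), need))
  }
  take <- function(pool, from, len) pool[seq(from, length.out = len)]
  i <- 1L
  # pass pair: |A| = pass_shared + 2, |B| = pass_shared + 2, shared = pass_shared
  a1 <- take(comm, i, pass_shared + 2L)
  b1 <- take(comm, i + 2L, pass_shared + 2L)
  i <- i + pass_shared + 4L
  # fail-shared pair: two 6-gene sets sharing fail_shared genes
  a2 <- take(comm, i, 6L)
  b2 <- take(comm, i + 6L - fail_shared, 6L)
  i <- i + 12L - fail_shared
  # fail-score pair: two 12-gene sets sharing exactly 4 genes;
  # jc = 4/20, oc = 4/12 -> score ~ 0.267 <= 0.3
  a3 <- take(comm, i, 12L)
  b3 <- take(comm, i + 8L, 12L)
  i <- i + 20L
  with_seed(rng_seed, {
    sets <- list(PW_PASS_A = a1, PW_PASS_B = b1,
                 PW_FAILSH_A = a2, PW_FAILSH_B = b2,
                 PW_FAILSC_A = a3, PW_FAILSC_B = b3)
    # pad community pathways with background genes (not candidates downstream)
    sets <- lapply(sets, function(s) c(s, sample(bg, 3L)))
    n_extra <- n_pathways - length(sets)
    n_comm_extra <- max(0L, n_extra %/% 2L - 1L)
    extra <- list()
    for (j in seq_len(n_extra)) {
      id <- sprintf("PW_BG%02d", j)
      if (j <= n_comm_extra && length(comm) >= i + 7L) {
        extra[[id]] <- c(take(comm, i, 7L), sample(bg, 5L))
        i <- i + 7L
      } else {
        extra[[id]] <- sample(bg, 12L)
      }
    }
    gsc <- geneset_collection(c(sets, extra))
    list(gsc = gsc,
         design = list(pass_pair = c("PW_PASS_A", "PW_PASS_B"),
                       fail_shared_pair = c("PW_FAILSH_A", "PW_FAILSH_B"),
                       fail_score_pair = c("PW_FAILSC_A", "PW_FAILSC_B")))
  })
}

#' Write synthetic stand-ins for the study's supplementary inputs
#'
#' Generates a study-scale planted-community graph and writes the three input
#' files the pipeline ingests, in the study's printed shapes: an interaction
#' TSV (~62,576 rows at the default spec), a node-list TSV padded with
#' interaction-less records up to `n_records` (1,769 by default, matching the
#' 154 collected-but-unconnected cytokines), and a positives list (the
#' revealed seed ids). These are synthetic stand-ins: the real supplementary
#' tables are not redistributable, so ingestion is exercised on generated
#' files of the same shape and scale.
#'
#' @param dir Output directory (created if needed).
#' @param spec A `planted_graph_spec`; default [study_scale_spec()].
#' @param n_records Total node-list records including interaction-less ones.
#' @return List with the written paths (`interactions`, `nodes`, `positives`)
#'   and the generated `graph`/`truth`.
#' @export
write_synthetic_supplementary <- function(dir, spec = study_scale_spec(),
                                          n_records = 1769L) {
  stopifnot(n_records >= spec$n_nodes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_graph(spec)
  n_pad <- n_records - spec$n_nodes
  pad_ids <- if (n_pad > 0) sprintf("X%04d", seq_len(n_pad)) else character()
  paths <- list(interactions = file.path(dir, "synthetic_interactions.tsv"),
                nodes = file.path(dir, "synthetic_cytokines.tsv"),
                positives = file.path(dir, "synthetic_positives.txt"))
  write_interactions(gen$graph, paths$interactions)
  writeLines(c("node_id", gen$graph$node_ids, pad_ids), paths$nodes)
  writeLines(gen$truth$revealed_positives, paths$positives)
  c(paths, gen)
}
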