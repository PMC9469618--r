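# End-to-end orchestration: validated flat-key configuration, deterministic
# seed propagation, and the prioritize -> enrich -> crosstalk run.

.config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "results",
    graph.score_threshold = 0,
    graph.binarize = FALSE,
    gcn.hidden_dim = 16L,
    gcn.learning_rate = 0.01,
    gcn.epochs = 200L,
    meta.n_tasks = 8L,
    meta.support_per_class = 5L,
    meta.inner_lr = 0.1,
    meta.outer_lr = 0.01,
    meta.inner_steps = 1L,
    meta.meta_epochs = 50L,
    pu.k_negatives = 100L,
    pu.n_restarts = 1000L,
    pu.threshold = 0.95,
    pu.max_refine_iters = 20L,
    pu.negative_seeding = "random",
    enrich.fdr_max = 0.05,
    enrich.min_set_genes = 5L,
    enrich.min_shared = 4L,
    enrich.min_score = 0.3
  )
}

.config_checks <- function() {
  list(
    seed = function(v) is.finite(v),
    graph.score_threshold = function(v) is.finite(v) && v >= 0,
    graph.binarize = function(v) is.logical(v),
    gcn.hidden_dim = function(v) v >= 1,
    gcn.learning_rate = function(v) v > 0,
    gcn.epochs = function(v) v >= 0,
    meta.n_tasks = function(v) v >= 1,
    meta.support_per_class = function(v) v >= 1,
    meta.inner_lr = function(v) v > 0,
    meta.outer_lr = function(v) v > 0,
    meta.inner_steps = function(v) v >= 1,
    meta.meta_epochs = function(v) v >= 0,
    pu.k_negatives = function(v) v >= 1,
    pu.n_restarts = function(v) v >= 1,
    pu.threshold = function(v) v > 0 && v < 1,
    pu.max_refine_iters = function(v) v >= 1,
    pu.negative_seeding = function(v) v %in% c("random", "farthest"),
    enrich.fdr_max = function(v) v > 0 && v <= 1,
    enrich.min_set_genes = function(v) v >= 0,
    enrich.min_shared = function(v) v >= 0,
    enrich.min_score = function(v) v >= 0 && v < 1
  )
}

# Parse "key = value" lines; '#' comments and blank lines skipped.
.read_flat_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key = value'): ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- val
  }
  out
}

.coerce_config_value <- function(key, val, default) {
  if (!is.character(val)) return(val)
  if (is.logical(default)) return(toupper(val) %in% c("TRUE", "T", "1", "YES"))
  if (is.numeric(default)) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop(sprintf("config key %s: '%s' is not numeric", key, val))
    return(if (is.integer(default)) as.integer(num) else num)
  }
  val
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list of overrides or a path to a flat `key = value` text
#' file (sections use dotted keys, e.g. `pu.threshold = 0.95`). Unset keys
#' receive the study defaults (k = 100 negatives, R = 1000 restarts,
#' threshold 0.95, FDR 0.05, minimum 5 enriched genes, minimum 4 shared
#' genes, minimum score 0.3). Unknown keys are rejected with a nearest-key
#' suggestion; all range violations are reported together.
#'
#' @param config Named list or file path; `NULL` gives the full defaults.
#' @return Normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  defaults <- .config_defaults()
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1) {
    config <- .read_flat_config(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    msgs <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(defaults))
      near <- names(defaults)[which.min(d)]
      sprintf("unknown config key '%s' (did you mean '%s'?)", k, near)
    }, character(1))
    stop(paste(msgs, collapse = "; "))
  }
  cfg <- defaults
  for (k in names(config)) {
    cfg[[k]] <- .coerce_config_value(k, config[[k]], defaults[[k]])
  }
  checks <- .config_checks()
  bad <- character(0)
  for (k in names(checks)) {
    ok <- tryCatch(isTRUE(checks[[k]](cfg[[k]])), error = function(e) FALSE)
    if (!ok) bad <- c(bad, sprintf("%s = %s out of range", k, format(cfg[[k]])))
  }
  if (length(bad) > 0) stop(paste(bad, collapse = "; "))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Assemble per-module configuration objects from the flat config.
.module_configs <- function(cfg) {
  list(
    meta = meta_config(n_tasks = cfg$meta.n_tasks,
                       support_per_class = cfg$meta.support_per_class,
                       inner_lr = cfg$meta.inner_lr, outer_lr = cfg$meta.outer_lr,
                       inner_steps = cfg$meta.inner_steps,
                       meta_epochs = cfg$meta.meta_epochs,
                       hidden_dim = cfg$gcn.hidden_dim,
                       rng_seed = mix_seed(cfg$seed, 1L)),
    train = train_config(learning_rate = cfg$gcn.learning_rate,
                         epochs = cfg$gcn.epochs, hidden_dim = cfg$gcn.hidden_dim,
                         rng_seed = mix_seed(cfg$seed, 2L)),
    pu = pu_config(k_negatives = cfg$pu.k_negatives,
                   n_restarts = cfg$pu.n_restarts, threshold = cfg$pu.threshold,
                   max_refine_iters = cfg$pu.max_refine_iters,
                   negative_seeding = cfg$pu.negative_seeding,
                   rng_seed = mix_seed(cfg$seed, 3L))
  )
}

#' Run the full prioritization and crosstalk pipeline
#'
#' Executes prioritize (PU ensemble) -> candidate selection -> gene-set
#' enrichment -> pathway crosstalk -> gene frequency, and writes five
#' artifacts to `cfg$out_dir`: `candidates.tsv` (ranked scores with a
#' selected flag), `enrichment.tsv`, `crosstalk_pairs.tsv`,
#' `pair_frequency.tsv`, and `run_log.txt` recording every resolved
#' parameter and derived seed. Identical configuration and inputs give
#' byte-identical outputs (the log carries no timestamps). Partial outputs
#' are removed if any stage fails.
#'
#' @param config Anything [validate_config()] accepts.
#' @param graph An `interaction_graph`.
#' @param positives Character vector of positive node ids.
#' @param gsc A `geneset_collection` for enrichment/crosstalk.
#' @return List with `manifest` (named file paths), `candidates`,
#'   `enrichment`, `crosstalk`, `frequency`, `ensemble`.
#' @export
run_full <- function(config, graph, positives, gsc) {
  cfg <- validate_config(config)
  stopifnot(inherits(graph, "interaction_graph"),
            inherits(gsc, "geneset_collection"))
  missing <- setdiff(positives, graph$node_ids)
  if (length(missing) > 0) {
    stop("positives not in graph: ", paste(missing, collapse = ", "))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  mods <- .module_configs(cfg)
  manifest <- c(candidates = file.path(cfg$out_dir, "candidates.tsv"),
                enrichment = file.path(cfg$out_dir, "enrichment.tsv"),
                crosstalk = file.path(cfg$out_dir, "crosstalk_pairs.tsv"),
                frequency = file.path(cfg$out_dir, "pair_frequency.tsv"),
                log = file.path(cfg$out_dir, "run_log.txt"))
  on_fail <- function() unlink(manifest[file.exists(manifest)])
  tryCatch({
    if (isTRUE(cfg$graph.binarize)) {
      graph$adjacency <- (graph$adjacency > 0) * 1
    }
    ens <- pu_run_ensemble(graph, positives, mods$meta, mods$train, mods$pu)
    cand <- threshold_candidates(ens, cfg$pu.threshold)
    write_score_table(ens, manifest[["candidates"]], cfg$pu.threshold)
    enr <- enrich(cand$node_id, gsc, universe = graph$node_ids)
    utils::write.table(.format_num_df(enr), manifest[["enrichment"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ct <- crosstalk(enr, fdr_max = cfg$enrich.fdr_max,
                    min_set_genes = cfg$enrich.min_set_genes,
                    min_shared = cfg$enrich.min_shared,
                    min_score = cfg$enrich.min_score)
    utils::write.table(.format_num_df(ct), manifest[["crosstalk"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    freq <- pair_frequency(ct, enr)
    utils::write.table(freq, manifest[["frequency"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c("crsnet run log",
                   sprintf("n_nodes\t%d", graph$n_nodes),
                   sprintf("n_edges\t%d", n_edges(graph)),
                   sprintf("n_positives\t%d", length(positives)),
                   sprintf("n_genesets\t%d", length(gsc$sets)),
                   vapply(sort(setdiff(names(cfg), "out_dir")), function(k)
                     sprintf("config\t%s\t%s", k, format(cfg[[k]])), character(1)),
                   sprintf("derived_seed\tmeta\t%d", mods$meta$rng_seed),
                   sprintf("derived_seed\ttrain\t%d", mods$train$rng_seed),
                   sprintf("derived_seed\tpu\t%d", mods$pu$rng_seed),
                   sprintf("converged_runs\t%d/%d", sum(ens$converged), ens$n_runs),
                   sprintf("n_candidates\t%d", nrow(cand)),
                   sprintf("n_crosstalk_pairs\t%d", nrow(ct)))
    writeLines(log_lines, manifest[["log"]])
    list(manifest = manifest, candidates = cand, enrichment = enr,
         crosstalk = ct, frequency = freq, ensemble = ens)
  }, error = function(e) {
    on_fail()
    stop(e)
  })
}

# Stable full-precision numeric formatting for TSV output (keeps reruns
# byte-identical across platforms' default digit settings).
.format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- format(df[[nm]], digits = 15, scientific = TRUE, trim = TRUE)
    }
  }
  df
}
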