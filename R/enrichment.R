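# Gene-set enrichment (hypergeometric test, BH FDR) and pathway-crosstalk
# pair analysis with the filter cascade.

#' Construct a gene-set collection
#'
#' @param sets Named list: pathway id -> character vector of member gene ids
#'   (duplicates collapsed; empty sets rejected).
#' @param names_ Optional named character vector of human-readable set names;
#'   defaults to the ids.
#' @return A `geneset_collection` object.
#' @export
geneset_collection <- function(sets, names_ = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set needs a non-empty id")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set ids: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed")
  if (is.null(names_)) names_ <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, set_names = names_), class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d sets, sizes %s\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set id, description, then one field per member gene.
#' Duplicate genes within a set are collapsed; a duplicated set id is an
#' error.
#'
#' @param path Path to the GMT file.
#' @return A `geneset_collection`.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(structure(list(sets = stats::setNames(list(), character()),
                          set_names = character()),
                     class = "geneset_collection"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0) {
    stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields",
                 line_no[bad[1]]))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  descs <- vapply(parts, `[[`, character(1), 2L)
  if (anyDuplicated(ids)) {
    stop("duplicate set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  geneset_collection(sets, stats::setNames(descs, ids))
}

#' Write a gene-set collection as GMT
#' @param gsc A `geneset_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$set_names[[id]], gsc$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment with BH FDR
#'
#' For each set, tests over-representation of the candidate genes with the
#' one-sided hypergeometric upper tail (equivalently Fisher's one-sided exact
#' test): given a universe of size `N`, a set covering `K` universe genes,
#' and `n` candidates, the p-value of an overlap `k` is
#' `P(X >= k), X ~ Hypergeometric(N, K, n)`. Benjamini-Hochberg FDR is
#' computed across all tested sets. Candidates outside the universe are
#' dropped with a message; sets with no universe genes are skipped.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param gsc A `geneset_collection`.
#' @param universe Character vector: the gene universe.
#' @return Data frame sorted by p-value: `pathway_id`, `name`, `k_overlap`,
#'   `set_size`, `p_value`, `fdr`, `overlap_genes` (comma-joined).
#' @export
enrich <- function(candidates, gsc, universe) {
  universe <- unique(as.character(universe))
  candidates <- unique(as.character(candidates))
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(candidates, universe)
  if (length(outside) > 0) {
    message(sprintf("dropping %d candidate(s) outside the universe", length(outside)))
    candidates <- intersect(candidates, universe)
  }
  if (length(candidates) == 0) stop("no candidates inside the universe")
  N <- length(universe)
  n <- length(candidates)
  rows <- lapply(names(gsc$sets), function(id) {
    set_u <- intersect(gsc$sets[[id]], universe)
    K <- length(set_u)
    if (K == 0) return(NULL)
    ov <- intersect(set_u, candidates)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, name = unname(gsc$set_names[[id]]),
               k_overlap = k, set_size = K, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0) {
    stop("no testable sets: every set is disjoint from the universe")
  }
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$pathway_id), ]
  rownames(res) <- NULL
  res[, c("pathway_id", "name", "k_overlap", "set_size", "p_value", "fdr",
          "overlap_genes")]
}

#' Jaccard coefficient of two gene sets
#'
#' `|A intersect B| / |A union B|`; both sets must be non-empty.
#'
#' @param a,b Character vectors of gene ids.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) stop("jaccard() requires non-empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap (Szymkiewicz-Simpson) coefficient of two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`; both sets must be non-empty.
#'
#' @param a,b Character vectors of gene ids.
#' @return Value in `[0, 1]`.
#' @export
overlap_coef <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) stop("overlap_coef() requires non-empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pathway-crosstalk pairs from enrichment results
#'
#' Applies the filter cascade: (1) eligible pathways have `fdr < fdr_max` and
#' strictly more than `min_set_genes` enriched genes; (2) for every unordered
#' eligible pair, the shared enriched-gene count is computed and pairs
#' sharing fewer than `min_shared` genes are removed; (3) the Jaccard and
#' overlap coefficients of the two ENRICHED gene sets are averaged into
#' `score = (jc + oc) / 2`; (4) pairs with `score <= min_score` are removed.
#' Pairs are returned sorted by descending score.
#'
#' @param records Enrichment data frame from [enrich()] (needs
#'   `pathway_id`, `k_overlap`, `fdr`, `overlap_genes`).
#' @param fdr_max FDR cutoff, default 0.05 (strict).
#' @param min_set_genes Minimum enriched-gene count, default 5 (strictly
#'   more than this survive).
#' @param min_shared Minimum shared enriched genes per pair, default 4
#'   (pairs with fewer are removed; equality survives).
#' @param min_score Score cutoff, default 0.3 (strictly above survives).
#' @return Data frame: `pathway_a`, `pathway_b`, `shared`, `jc`, `oc`,
#'   `score`, sorted by descending score then pathway ids.
#' @export
crosstalk <- function(records, fdr_max = 0.05, min_set_genes = 5L,
                      min_shared = 4L, min_score = 0.3) {
  stopifnot(all(c("pathway_id", "k_overlap", "fdr", "overlap_genes") %in%
                  names(records)))
  elig <- records[records$fdr < fdr_max & records$k_overlap > min_set_genes, ]
  empty <- data.frame(pathway_a = character(), pathway_b = character(),
                      shared = integer(), jc = numeric(), oc = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(elig) < 2) return(empty)
  genes <- lapply(strsplit(elig$overlap_genes, ",", fixed = TRUE), unique)
  names(genes) <- elig$pathway_id
  ids <- sort(elig$pathway_id)
  pairs <- utils::combn(ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    shared <- length(intersect(genes[[a]], genes[[b]]))
    if (shared < min_shared) return(NULL)
    jc <- jaccard(genes[[a]], genes[[b]])
    oc <- overlap_coef(genes[[a]], genes[[b]])
    score <- (jc + oc) / 2
    if (score <= min_score) return(NULL)
    data.frame(pathway_a = a, pathway_b = b, shared = shared, jc = jc,
               oc = oc, score = score, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$pathway_a, res$pathway_b), ]
  rownames(res) <- NULL
  res
}

#' Gene frequency across retained crosstalk pathways
#'
#' Counts, for every gene, how many of the pathways retained in the
#' crosstalk table contain it among their enriched genes. Useful for the
#' "most frequent cytokines" summary of a crosstalk map.
#'
#' @param pairs Crosstalk data frame from [crosstalk()].
#' @param records The enrichment data frame the pairs were derived from.
#' @param top_n Optional: keep only the `top_n` most frequent genes (ties
#'   broken lexicographically).
#' @return Data frame `gene`, `n_pathways`, sorted by descending count then
#'   gene id.
#' @export
pair_frequency <- function(pairs, records, top_n = NULL) {
  empty <- data.frame(gene = character(), n_pathways = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  retained <- sort(unique(c(pairs$pathway_a, pairs$pathway_b)))
  genes <- lapply(strsplit(records$overlap_genes[match(retained, records$pathway_id)],
                           ",", fixed = TRUE), unique)
  tab <- table(unlist(genes))
  res <- data.frame(gene = names(tab), n_pathways = as.integer(tab),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n_pathways, res$gene), ]
  rownames(res) <- NULL
  if (!is.null(top_n)) res <- utils::head(res, top_n)
  res
}
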