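#!/usr/bin/env Rscript
# Build the study inputs: a desk-scale planted-community interaction graph
# (the recovery benchmark), study-scale synthetic supplementary stand-ins,
# and the engineered pathway collection. Everything downstream (02, 03)
# reads the files written here.

suppressPackageStartupMessages(library(crsnet))

seed <- 20260924L
out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## Desk-scale benchmark graph: 400 nodes, 40-node planted community,
## 10 revealed seed positives.
spec <- desk_scale_spec(rng_seed = seed)
gen <- generate_graph(spec)
write_interactions(gen$graph, file.path(out_dir, "desk_graph.tsv"))
writeLines(gen$graph$node_ids, file.path(out_dir, "desk_nodes.tsv"))
writeLines(gen$truth$revealed_positives, file.path(out_dir, "desk_positives.txt"))
writeLines(gen$truth$community_members, file.path(out_dir, "desk_truth_community.txt"))
cat(sprintf("desk graph: %d nodes, %d edges (expected %.0f)\n",
            gen$graph$n_nodes, n_edges(gen$graph), expected_edges(spec)))
cat(sprintf("planted community: %d members, %d revealed as positives\n",
            length(gen$truth$community_members),
            length(gen$truth$revealed_positives)))

## Engineered pathway collection over the same community, with designed
## crosstalk passes/failures.
gs <- generate_genesets(gen$truth, universe = gen$graph$node_ids,
                        n_pathways = 10L, rng_seed = seed)
write_gmt(gs$gsc, file.path(out_dir, "desk_pathways.gmt"))
cat(sprintf("pathways: %d sets; designed pass pair %s, designed failures %s / %s\n",
            length(gs$gsc$sets),
            paste(gs$design$pass_pair, collapse = "-"),
            paste(gs$design$fail_shared_pair, collapse = "-"),
            paste(gs$design$fail_score_pair, collapse = "-")))

## Study-scale synthetic supplementary stand-ins (1,769 records, 1,615
## network nodes, ~62,576 interactions) to exercise ingestion at scale.
supp <- write_synthetic_supplementary(file.path(out_dir, "synthetic_supplementary"),
                                      study_scale_spec(rng_seed = seed))
g_study <- load_interactions(supp$interactions)
cat(sprintf("study-scale stand-in: %d node records, %d network nodes, %d interactions\n",
            length(load_node_list(supp$nodes)), g_study$n_nodes, n_edges(g_study)))
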