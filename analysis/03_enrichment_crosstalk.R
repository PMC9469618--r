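#!/usr/bin/env Rscript
# Gene-set enrichment of the prioritized candidates and the pathway
# crosstalk cascade, on the artifacts written by 01 and 02: hypergeometric
# test with BH FDR, then pair filtering (FDR < 0.05, > 5 enriched genes,
# >= 4 shared genes, mean of Jaccard and overlap coefficients > 0.3).

suppressPackageStartupMessages(library(crsnet))

out_dir <- "results"
graph_nodes <- readLines(file.path(out_dir, "desk_nodes.tsv"))
candidates <- load_node_list(file.path(out_dir, "desk_candidates.txt"))
gsc <- read_gmt(file.path(out_dir, "desk_pathways.gmt"))

rec <- enrich(candidates, gsc, universe = graph_nodes)
write.table(rec, file.path(out_dir, "desk_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d pathways tested; %d significant at FDR < 0.05\n",
            nrow(rec), sum(rec$fdr < 0.05)))

ct <- crosstalk(rec, fdr_max = 0.05, min_set_genes = 5L, min_shared = 4L,
                min_score = 0.3)
write.table(ct, file.path(out_dir, "desk_crosstalk_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d crosstalk pair(s) retained by the cascade\n", nrow(ct)))
if (nrow(ct) > 0) {
  print(ct, row.names = FALSE)
}

freq <- pair_frequency(ct, rec, top_n = 20)
write.table(freq, file.path(out_dir, "desk_pair_frequency.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("top recurring genes across retained pathways: %s\n",
            paste(head(freq$gene, 5), collapse = ", ")))
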