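# crsnet

Network prioritization of cytokines associated with cytokine release
syndrome (CRS), the main systemic toxicity of CAR-T therapy. Starting from
a handful of literature-confirmed CRS cytokines and a protein–protein
interaction (PPI) network, `crsnet` scores every cytokine in the network
for CRS association, then characterizes the resulting candidate set by
gene-set enrichment and pathway-crosstalk analysis.

## Who this is for

Computational biologists who want a reproducible, fully tested
implementation of PU-learning-based gene prioritization on interaction
networks — either to run on their own interaction/pathway exports or to
study the method itself on synthetic benchmarks with known ground truth.

## The method

**Classifier.** A two-layer graph convolutional network over the symmetric
normalized adjacency $\hat A = \tilde D^{-1/2}(A+I)\tilde D^{-1/2}$:

$$Z = \mathrm{softmax}\big(\hat A\,\mathrm{ReLU}(\hat A X W^{(0)})\,W^{(1)}\big)$$

with identity node features, binary cross-entropy loss over labeled nodes,
exact backpropagation, and Adam. Initial parameters are meta-learned in the
first-order MAML style over episodic support/query tasks sampled from the
labeled nodes.

**Positive-unlabeled protocol.** Only positives are known. Each run seeds
$k = 100$ provisional negatives (random, or topologically farthest from
the positives), trains, rescores all nodes, and relabels the negatives as
the $k$ lowest-scoring non-positive nodes, iterating until the negative
set is stable (capped at 20 iterations). The run is restarted $R$ times
($R = 1000$ at full scale) with fresh random seeds; the per-node **median**
score over restarts is the final result, and nodes with median score
> 0.95 are the CRS-candidate set.

**Downstream.** Candidates are tested per pathway with the one-sided
hypergeometric (Fisher) test and Benjamini–Hochberg FDR; enriched pathways
(FDR < 0.05, > 5 enriched genes) are screened pairwise for crosstalk with
the Jaccard coefficient $|A\cap B|/|A\cup B|$ and overlap coefficient
$|A\cap B|/\min(|A|,|B|)$, retaining pairs that share ≥ 4 enriched genes
and have mean coefficient > 0.3.

A planted-community (stochastic block model) generator plus an engineered
pathway collection make the entire pipeline testable without any network
downloads; `vignettes/methods.Rmd` documents the model, every tunable
parameter, and the design decisions.

## Worked example

The numbered scripts under `analysis/` run the study end to end on the
desk-scale benchmark (400 nodes, 40-node planted community, 10 revealed
seed positives, 50 restarts):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prioritize.R          # ~3 minutes on one core
Rscript analysis/03_enrichment_crosstalk.R
```

which prints (seed 20260924):

```
desk graph: 400 nodes, 1033 edges (expected 1024)
planted community: 40 members, 10 revealed as positives
...
converged runs: 50/50; median-score AUC vs planted community: 0.983
36 candidates above 0.95, of which 29 are planted community members
...
10 pathways tested; 4 significant at FDR < 0.05
2 crosstalk pair(s) retained by the cascade
```

Reading: every restart's negative-relabeling loop reached a stable
negative set; ranking all 400 nodes by ensemble-median score separates the
hidden 40-node community from background with AUC 0.983; the strict 0.95
cutoff recovers 29 of the 40 planted members (the remaining candidates are
background nodes embedded in the community's neighbourhood); and the
crosstalk cascade retains the pathway pair engineered to pass, plus one
borderline pair whose overlap coefficient rises once enrichment is
restricted to recovered candidates.

The same functions run on real exports: `load_interactions()` reads
STRING-style TSV (scores 0–1000 are rescaled to (0,1]), `read_gmt()` reads
pathway collections, `crs_seed_cytokines()` returns the packaged 20-entry
CRS seed list, and `run_full()` executes the whole pipeline from one
validated flat-key config.

```r
library(crsnet)
g   <- load_interactions("string_export.tsv")
ens <- pu_run_ensemble(g, crs_seed_cytokines(),
                       pu_cfg = pu_config(n_restarts = 1000, rng_seed = 1))
head(threshold_candidates(ens, 0.95))
```

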