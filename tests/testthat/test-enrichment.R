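# GMT parsing, hypergeometric enrichment, JC/OC, crosstalk cascade.

test_that("GMT files parse, collapse duplicates, and reject bad input", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tfirst set\tg1\tg2\tg3",
               "S2\tsecond set\tg1\tg4\tg5\tg6\tg7"), path)
  gsc <- read_gmt(path)
  expect_length(gsc$sets, 2)
  expect_equal(lengths(gsc$sets), c(S1 = 3L, S2 = 5L))
  expect_equal(unname(gsc$set_names["S2"]), "second set")

  # duplicate genes within a set collapse
  writeLines("S1\td\tg1\tg1\tg2", path)
  expect_equal(read_gmt(path)$sets$S1, c("g1", "g2"))

  # empty file: empty collection
  writeLines(character(), path)
  expect_length(read_gmt(path)$sets, 0)

  writeLines(c("S1\td\tg1", "S1\td\tg2"), path)
  expect_error(read_gmt(path), "duplicate set ids")
  writeLines(c("S1\td\tg1", "ONLYTWO\tfields"), path)
  expect_error(read_gmt(path), "line 2")
})

test_that("GMT writer round-trips through the reader", {
  gsc <- geneset_collection(list(A = c("g1", "g2"), B = c("g2", "g3", "g4")),
                            names_ = c(A = "alpha", B = "beta"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, path)
  back <- read_gmt(path)
  expect_equal(back$sets, gsc$sets)
  expect_equal(unname(back$set_names), unname(gsc$set_names))
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  # full containment: universe 20, candidates 5, set of 5, overlap 5
  gsc <- geneset_collection(list(S = sprintf("g%02d", 1:5)))
  uni <- sprintf("g%02d", 1:20)
  rec <- enrich(sprintf("g%02d", 1:5), gsc, uni)
  expect_equal(rec$p_value, 1 / choose(20, 5))
  expect_equal(rec$k_overlap, 5)

  # random configurations vs the enumeration oracle
  set.seed(55)
  for (rep in 1:25) {
    N <- sample(8:20, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    set <- sample(uni, K)
    cand <- sample(uni, n)
    rec <- enrich(cand, geneset_collection(list(S = set)), uni)
    k <- length(intersect(set, cand))
    expect_equal(rec$p_value, oracle_hyper_upper(k, K, N, n), tolerance = 1e-12)
    # cross-check against Fisher's one-sided exact test
    ft <- fisher.test(matrix(c(k, K - k, n - k, N - K - (n - k)), 2, 2),
                      alternative = "greater")
    expect_equal(rec$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment and degenerate sets behave as documented", {
  gsc <- geneset_collection(list(A = c("g1", "g2"), B = c("g3", "g4"),
                                 OUT = c("x1", "x2")))
  uni <- sprintf("g%d", 1:10)
  # set entirely outside the universe is skipped
  rec <- enrich(c("g1", "g2", "g3"), gsc, uni)
  expect_setequal(rec$pathway_id, c("A", "B"))
  expect_equal(rec$fdr, p.adjust(rec$p_value, "BH"))
  # BH is monotone nondecreasing in sorted-p order
  expect_true(all(diff(rec$fdr[order(rec$p_value)]) >= 0))
  # worked BH case: {0.01, 0.02, 0.03} -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  expect_error(enrich(character(), gsc, uni), "candidates")
  expect_error(enrich(c("g1"), gsc, character()), "universe")
  expect_message(enrich(c("g1", "nope"), gsc, uni), "outside the universe")
})

test_that("JC and OC match brute-force set algebra exhaustively", {
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard("x", "z"), 0)
  expect_equal(jaccard(c("x", "y"), c("y", "z")), 1 / 3)
  expect_equal(overlap_coef(c("x", "y"), c("x", "y", "z")), 1)  # subset
  expect_equal(overlap_coef("x", "z"), 0)
  expect_equal(overlap_coef(c("x", "y"), c("y", "z")), 1 / 2)
  expect_error(jaccard(character(), "a"), "non-empty")
  expect_error(overlap_coef("a", character()), "non-empty")

  # all nonempty subset pairs of a 6-gene universe vs brute-force counting
  genes <- letters[1:6]
  subsets <- lapply(1:63, function(mask) genes[bitwAnd(mask, 2^(0:5)) > 0])
  for (a in subsets) {
    for (b in subsets) {
      inter <- sum(genes %in% a & genes %in% b)
      uni <- sum(genes %in% a | genes %in% b)
      expect_identical(jaccard(a, b), inter / uni)
      expect_identical(overlap_coef(a, b), inter / min(length(a), length(b)))
      expect_lte(jaccard(a, b), overlap_coef(a, b))
    }
  }
})

make_records <- function(sets, fdr) {
  data.frame(pathway_id = names(sets),
             k_overlap = lengths(sets),
             fdr = fdr,
             overlap_genes = vapply(sets, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

test_that("the crosstalk filter cascade applies every rule", {
  g <- function(i) sprintf("g%02d", i)
  sets <- list(P1 = g(1:6), P2 = g(1:6),          # identical: jc = oc = 1
               P3 = g(10:15), P4 = g(13:18),      # shared 3: removed
               P5 = g(1:6), P6 = g(3:8),          # shared 4: jc 4/8, oc 4/6
               SMALL = g(1:5),                    # only 5 enriched genes
               BADFDR = g(1:6))
  rec <- make_records(sets, fdr = c(rep(0.001, 7), 0.2))
  ct <- crosstalk(rec)
  # SMALL (k = 5 not > 5) and BADFDR never enter; P3-P4 dropped on shared < 4
  expect_false(any(c("SMALL", "BADFDR") %in% c(ct$pathway_a, ct$pathway_b)))
  expect_false(any(ct$pathway_a == "P3" & ct$pathway_b == "P4"))

  ident <- ct[ct$pathway_a == "P1" & ct$pathway_b == "P2", ]
  expect_equal(ident$shared, 6)
  expect_equal(ident$jc, 1); expect_equal(ident$oc, 1); expect_equal(ident$score, 1)

  mixed <- ct[ct$pathway_a == "P5" & ct$pathway_b == "P6", ]
  expect_equal(mixed$shared, 4)
  expect_equal(mixed$score, (4 / 8 + 4 / 6) / 2, tolerance = 1e-12)

  # sorted by descending score
  expect_true(all(diff(ct$score) <= 0))

  # boundary: score exactly at the cutoff is dropped (strictly above retained)
  sets2 <- list(A = g(1:12), B = g(9:20))  # shared 4, jc 0.2, oc 1/3
  rec2 <- make_records(sets2, fdr = c(0.001, 0.001))
  expect_equal(nrow(crosstalk(rec2)), 0)
  expect_equal(nrow(crosstalk(rec2, min_score = 0.25)), 1)
})

test_that("crosstalk is symmetric under relabeling the pair members", {
  g <- function(i) sprintf("g%02d", i)
  sets <- list(X = g(1:8), Y = g(3:10), Z = g(5:12))
  rec <- make_records(sets, fdr = rep(0.01, 3))
  ct1 <- crosstalk(rec)
  sets_sw <- list(Y = g(1:8), X = g(3:10), Z = g(5:12))  # swap X and Y labels
  ct2 <- crosstalk(make_records(sets_sw, fdr = rep(0.01, 3)))
  expect_setequal(ct1$score, ct2$score)
  expect_setequal(ct1$shared, ct2$shared)
})

test_that("pair frequency counts genes over retained pathways", {
  g <- function(i) sprintf("g%02d", i)
  # one retained pair; g04 sits in both enriched sets
  sets <- list(A = c(g(1:3), "g04", g(20:22)), B = c("g04", g(5:7), g(30:32)))
  rec <- make_records(sets, fdr = c(0.01, 0.01))
  ct <- crosstalk(rec, min_shared = 1, min_score = 0.01)
  expect_equal(nrow(ct), 1)
  freq <- pair_frequency(ct, rec)
  expect_equal(freq$n_pathways[freq$gene == "g04"], 2L)
  expect_true(all(freq$n_pathways[freq$gene != "g04"] == 1L))

  # top-N with lexicographic tie-break
  top <- pair_frequency(ct, rec, top_n = 3)
  expect_equal(top$gene[1], "g04")
  expect_equal(nrow(top), 3)

  # empty input, and invariance to pair ordering
  expect_equal(nrow(pair_frequency(ct[0, ], rec)), 0)
})
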