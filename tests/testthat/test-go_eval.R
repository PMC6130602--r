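test_that("OBO parsing keeps the requested namespace and drops obsolete terms", {
  dag <- toy_dag()
  expect_s3_class(dag, "go_dag")
  expect_false("GO:0000007" %in% dag$ids)  # obsolete
  expect_false("GO:0000010" %in% dag$ids)  # other namespace
  expect_identical(length(dag$ids), 7L)

  # minimal 5-term file: 5 terms, 4 is_a edges
  p5 <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T1", "namespace: biological_process", "",
               "[Term]", "id: T2", "is_a: T1", "namespace: biological_process", "",
               "[Term]", "id: T3", "is_a: T1", "namespace: biological_process", "",
               "[Term]", "id: T4", "is_a: T2", "namespace: biological_process", "",
               "[Term]", "id: T5", "is_a: T2", "namespace: biological_process"),
             p5)
  dag5 <- parse_obo(p5)
  expect_identical(length(dag5$ids), 5L)
  expect_identical(sum(lengths(lapply(dag5$parents, `[[`, "parent"))), 4L)

  # cycles are rejected
  pc <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: C1", "is_a: C2", "namespace: biological_process", "",
               "[Term]", "id: C2", "is_a: C1", "namespace: biological_process"),
             pc)
  expect_error(parse_obo(pc), "cycle")
})

test_that("ancestor closure equals brute-force transitive closure", {
  dag <- toy_dag()
  # brute force: repeated joins over the parent relation
  closure <- function(term) {
    out <- term
    repeat {
      more <- unique(unlist(lapply(out, function(t) dag$parents[[t]]$parent)))
      if (all(more %in% out)) return(sort(out))
      out <- union(out, more)
    }
  }
  for (t in dag$ids) expect_setequal(ancestors(dag, t), closure(t))
})

test_that("Wang similarity matches the hand oracle on the toy DAG", {
  dag <- toy_dag()
  a <- "GO:0000003"; b <- "GO:0000004"; cc <- "GO:0000006"
  # S_a = {a: 1, p: 0.8, root: 0.64}, SV = 2.44; shared(a,b) = {p, root}
  expect_equal(term_similarity(dag, a, b), 2.88 / 4.88, tolerance = 1e-9)
  # terms sharing only the root: 2 * S(root) / (SV + SV)
  expect_equal(term_similarity(dag, a, cc), (0.64 + 0.64) / 4.88,
               tolerance = 1e-9)
  # part_of edge carries weight 0.6
  s <- "GO:0000008"  # S_s = {s: 1, p: 0.6, root: 0.48}, SV = 2.08
  expect_equal(term_similarity(dag, s, a),
               (0.6 + 0.8 + 0.48 + 0.64) / (2.08 + 2.44), tolerance = 1e-9)
  # identity and symmetry over all terms
  for (t in dag$ids) expect_equal(term_similarity(dag, t, t), 1)
  for (u in dag$ids) {
    expect_equal(term_similarity(dag, u, a), term_similarity(dag, a, u))
    expect_gte(term_similarity(dag, u, a), 0)
    expect_lte(term_similarity(dag, u, a), 1)
  }
  expect_error(term_similarity(dag, "GO:9999999", a), "unknown term")
})

test_that("gene similarity is the best-match average of term similarities", {
  dag <- toy_dag()
  annot <- list(g1 = c("GO:0000003", "GO:0000004"),
                g2 = "GO:0000003",
                g3 = "GO:0000003",
                g4 = "GO:0000006")
  expect_equal(gene_similarity(dag, annot, "g2", "g3"), 1)
  expect_equal(gene_similarity(dag, annot, "g2", "g4"),
               term_similarity(dag, "GO:0000003", "GO:0000006"))
  sim_ba <- term_similarity(dag, "GO:0000004", "GO:0000003")
  expect_equal(gene_similarity(dag, annot, "g1", "g2"), (1 + sim_ba + 1) / 3,
               tolerance = 1e-9)
  expect_equal(gene_similarity(dag, annot, "g1", "g2"),
               gene_similarity(dag, annot, "g2", "g1"))
  expect_error(gene_similarity(dag, annot, "g1", "nope"), "annotated")
})

test_that("clustering score weights per-cluster scores by annotated size", {
  dag <- toy_dag()
  annot <- list(g1 = "GO:0000003", g2 = "GO:0000003",
                g3 = "GO:0000004", g4 = "GO:0000004",
                g5 = "GO:0000003", g6 = "GO:0000006",
                g7 = "GO:0000003")
  # identically annotated pairs score 1
  cl_pairs <- c(g1 = 1, g2 = 1, g3 = 2, g4 = 2)
  expect_equal(clustering_score(dag, annot, cl_pairs)$overall, 1)
  # weighting rule: cluster of 2 and cluster of 4
  cl <- c(g1 = 1, g2 = 1, g3 = 2, g4 = 2, g5 = 2, g6 = 2)
  sc <- clustering_score(dag, annot, cl)
  s2 <- sc$per_cluster[["1"]]; s4 <- sc$per_cluster[["2"]]
  expect_equal(sc$overall, (2 * s2 + 4 * s4) / 6, tolerance = 1e-12)
  # singletons and clusters without 2 annotated genes are excluded, reported
  cl_s <- c(cl, g7 = 3)
  sc_s <- clustering_score(dag, annot, cl_s)
  expect_identical(sc_s$unscored, "3")
  expect_equal(sc_s$overall, sc$overall)
})

test_that("random gene relabelling lowers the score of structured clusters", {
  dag <- toy_dag()
  # two functionally tight clusters
  annot <- c(setNames(rep(list("GO:0000003"), 4), paste0("a", 1:4)),
             setNames(rep(list("GO:0000006"), 4), paste0("b", 1:4)))
  cl <- setNames(rep(1:2, each = 4), c(paste0("a", 1:4), paste0("b", 1:4)))
  obs <- clustering_score(dag, annot, cl)$overall
  expect_equal(obs, 1)
  null <- relabel_null(dag, annot, cl, n_sets = 100, seed = 42)
  expect_identical(length(null), 100L)
  expect_lt(mean(null), obs)
  # deterministic given seed
  expect_identical(relabel_null(dag, annot, cl, n_sets = 5, seed = 7),
                   relabel_null(dag, annot, cl, n_sets = 5, seed = 7))
  # degenerate: identical annotation everywhere keeps every null score at 1
  annot1 <- setNames(rep(list("GO:0000003"), 8), names(cl))
  expect_equal(relabel_null(dag, annot1, cl, n_sets = 5, seed = 1),
               rep(1, 5))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  p <- c(0.003, 0.04, 0.7, 0.012)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # invariant to input order up to reordering
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
})

test_that("exact binomial overrepresentation tail matches the closed-form sum", {
  # k = 8, n = 10, p0 = 0.2: sum_{i=8}^{10} C(10,i) 0.2^i 0.8^(10-i)
  exact <- choose(10, 8) * 0.2^8 * 0.8^2 + choose(10, 9) * 0.2^9 * 0.8 + 0.2^10
  genes <- paste0("g", 1:50)
  flagged <- paste0("g", 1:10)       # global fraction 0.2
  cl <- setNames(c(rep(1, 10), rep(2, 40)), genes)
  # cluster 1: 8 of its 10 genes flagged
  cl[c("g9", "g10")] <- 2
  cl[c("g49", "g50")] <- 1
  res <- binomial_overrepresentation(cl, flagged)
  expect_equal(res$p[res$cluster == "1"], exact, tolerance = 1e-12)
  expect_equal(res$p[res$cluster == "1"], 7.79264e-5, tolerance = 1e-10)
  # k = 0 gives p = 1; clusters exactly at the global fraction are
  # unremarkable (both have flagged fraction = global 0.2)
  cl0 <- setNames(c(rep(1, 10), rep(2, 40)), genes)
  res0 <- binomial_overrepresentation(cl0, c("g1", "g2", paste0("g", 11:18)))
  expect_gte(res0$p[res0$cluster == "1"], 0.5)
  expect_gte(res0$p[res0$cluster == "2"], 0.5)
  resk0 <- binomial_overrepresentation(cl0, paste0("g", 11:20))
  expect_equal(resk0$p[resk0$cluster == "1"], 1)
})

test_that("enrichment chi-squared and resampling p behave on the toy instance", {
  # 3 clusters of sizes 4/4/2; term T on 5 genes, all in cluster 1 -> X2 = 7.5
  genes <- paste0("g", 1:10)
  cl <- setNames(c(rep(1, 4), rep(2, 4), rep(3, 2)), genes)
  annot <- setNames(rep(list("U"), 10), genes)
  annot[paste0("g", c(1:4, 5))] <- list(c("T", "U"))
  dagless_freq <- sum(vapply(annot, function(t) "T" %in% t, logical(1)))
  expect_identical(dagless_freq, 5L)
  res <- enrichment_test(cl, annot, n_resamples = 20000, min_freq = 5, seed = 3)
  # hand value: O = (4,1,0) vs E = (2,2,1): (4-2)^2/2 + (1-2)^2/2 + (0-1)^2/1
  expect_equal(res$chi2[res$term == "T"], 3.5, tolerance = 1e-9)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$p_adj >= res$p))
  # frequency filter: a term on 4 genes is excluded at min_freq = 5
  annot2 <- annot
  annot2[paste0("g", 7:10)] <- lapply(annot2[paste0("g", 7:10)], c, "R")
  res2 <- enrichment_test(cl, annot2, n_resamples = 100, min_freq = 5, seed = 1)
  expect_false("R" %in% res2$term)
  # counts proportional to cluster sizes: X2 = 0, p = 1
  annot3 <- setNames(rep(list("U"), 10), genes)
  annot3[c("g1", "g2", "g5", "g6", "g9")] <- list(c("V", "U"))
  res3 <- enrichment_test(cl, annot3, n_resamples = 200, min_freq = 5, seed = 1)
  expect_equal(res3$chi2[res3$term == "V"], 0, tolerance = 1e-12)
  expect_equal(res3$p[res3$term == "V"], 1)
  # resampling is bit-identical given the seed
  expect_identical(enrichment_test(cl, annot, n_resamples = 50, seed = 9),
                   enrichment_test(cl, annot, n_resamples = 50, seed = 9))
})
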