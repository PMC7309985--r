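test_that("gene containment follows the full-overlap rule", {
  genes <- data.frame(contig = "c", start = c(10, 90, 150),
                      end = c(20, 110, 160),
                      gene_id = c("gIn", "gStraddle", "gOut"),
                      stringsAsFactors = FALSE)
  svs <- data.frame(contig = "c", start = 0, end = 100,
                    consensus_id = "sv1", stringsAsFactors = FALSE)
  hits <- genes_fully_inside(genes, svs)
  expect_equal(hits$gene_id, "gIn")
})

test_that("containment matches a brute-force per-pair scan", {
  set.seed(19)
  genes <- data.frame(contig = sample(c("a", "b"), 60, replace = TRUE),
                      start = sample.int(5000, 60), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(400, 60)
  genes$gene_id <- sprintf("g%02d", 1:60)
  svs <- data.frame(contig = sample(c("a", "b"), 15, replace = TRUE),
                    start = sample.int(4000, 15), stringsAsFactors = FALSE)
  svs$end <- svs$start + sample.int(1500, 15)
  svs$consensus_id <- sprintf("sv%02d", 1:15)
  hits <- genes_fully_inside(genes, svs)
  manual <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(svs))) {
    if (genes$contig[i] == svs$contig[j] &&
        genes$start[i] >= svs$start[j] && genes$end[i] <= svs$end[j])
      manual[[length(manual) + 1]] <- paste(genes$gene_id[i],
                                            svs$consensus_id[j])
  }
  expect_setequal(paste(hits$gene_id, hits$consensus_id),
                  unlist(manual))
})

flat_dag <- function(n_leaves = 5, genes_per_leaf = 20) {
  leaves <- sprintf("T%d", seq_len(n_leaves))
  edges <- data.frame(child = leaves, parent = "ROOT",
                      stringsAsFactors = FALSE)
  g2t <- do.call(rbind, lapply(seq_len(n_leaves), function(i)
    data.frame(gene = sprintf("g%d_%02d", i, seq_len(genes_per_leaf)),
               term = leaves[i], stringsAsFactors = FALSE)))
  go_dag(edges, g2t)
}

test_that("DAG propagation: ancestors annotate all descendant genes", {
  edges <- data.frame(child = c("B", "C", "C"), parent = c("A", "B", "A"))
  g2t <- data.frame(gene = c("g1", "g2"), term = c("C", "B"))
  dag <- go_dag(edges, g2t)
  expect_setequal(dag$genes[["A"]], c("g1", "g2"))
  expect_setequal(dag$genes[["B"]], c("g1", "g2"))
  expect_equal(dag$genes[["C"]], "g1")
  expect_equal(dag$depth[["A"]], 0)
  expect_equal(dag$depth[["C"]], 2)  # longest path C -> B -> A
  for (t in dag$terms) {
    for (a in dag$ancestors[[t]])
      expect_true(all(dag$genes[[t]] %in% dag$genes[[a]]))
  }
  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"))
  expect_error(go_dag(cyc, g2t), "cycle")
})

test_that("worked hypergeometric example matches tail summation exactly", {
  universe <- sprintf("u%03d", 1:100)
  edges <- data.frame(child = "T1", parent = "ROOT")
  g2t <- data.frame(gene = universe[1:20], term = "T1")
  dag <- go_dag(edges, g2t)
  study <- c(universe[1:6], universe[90:93])  # 6 of 10 hit the term
  res <- go_enrichment_elim(study, universe, dag, node_size = 5)
  row <- res[res$term == "T1", ]
  expect_equal(row$annotated, 20L)
  expect_equal(row$significant, 6L)
  expect_equal(row$expected, 2.0)
  expect_equal(row$p_elim, oracle_hyper_tail(6, 20, 100, 10),
               tolerance = 1e-12)
})

test_that("elim equals classic Fisher on flat DAGs and with cutoff 0", {
  set.seed(44)
  dag <- flat_dag()
  universe <- unique(unlist(dag$genes))
  study <- sample(universe, 25)
  res <- go_enrichment_elim(study, universe, dag, elim_cutoff = 0.01)
  for (i in seq_len(nrow(res))) {
    t <- res$term[i]
    if (t == "ROOT") next  # root is downstream of eliminations
    K <- length(dag$genes[[t]])
    k <- length(intersect(dag$genes[[t]], study))
    classic <- stats::fisher.test(
      matrix(c(k, K - k, length(study) - k,
               length(universe) - K - length(study) + k), 2),
      alternative = "greater")$p.value
    expect_equal(res$p_elim[i], classic, tolerance = 1e-10)
  }

  # deep DAG with cutoff 0: elim never triggers, equals classic everywhere
  edges <- data.frame(child = c("M1", "M2", "L1", "L2", "L3"),
                      parent = c("R", "R", "M1", "M1", "M2"))
  g2t <- data.frame(gene = sprintf("g%02d", 1:40),
                    term = sample(c("L1", "L2", "L3"), 40, replace = TRUE))
  dag2 <- go_dag(edges, g2t)
  universe2 <- sprintf("g%02d", 1:40)
  study2 <- sample(universe2, 12)
  res0 <- go_enrichment_elim(study2, universe2, dag2, elim_cutoff = 0)
  for (i in seq_len(nrow(res0))) {
    t <- res0$term[i]
    K <- length(intersect(dag2$genes[[t]], universe2))
    k <- length(intersect(dag2$genes[[t]], study2))
    expect_equal(res0$p_elim[i],
                 oracle_hyper_tail(k, K, 40, 12), tolerance = 1e-10)
  }
})

test_that("a significant child decorrelates its parent", {
  # 3-term chain: leaf L shares all its study genes with parent M
  edges <- data.frame(child = c("M", "L"), parent = c("R", "M"))
  universe <- sprintf("g%03d", 1:200)
  leaf_genes <- universe[1:10]
  mid_extra <- universe[11:40]
  g2t <- rbind(data.frame(gene = leaf_genes, term = "L"),
               data.frame(gene = mid_extra, term = "M"))
  dag <- go_dag(edges, g2t)
  study <- c(leaf_genes[1:8], universe[150:161])  # leaf strongly enriched
  res <- go_enrichment_elim(study, universe, dag, elim_cutoff = 0.01)
  p_leaf <- res$p_elim[res$term == "L"]
  expect_lt(p_leaf, 0.01)
  # classic parent p (with leaf genes included)
  K <- 40; k <- length(intersect(dag$genes[["M"]], study))
  classic_parent <- oracle_hyper_tail(k, K, 200, length(study))
  # elim parent p: leaf genes removed before testing
  K2 <- 30; k2 <- length(intersect(mid_extra, study))
  elim_parent <- oracle_hyper_tail(k2, K2, 200, length(study))
  got <- res$p_elim[res$term == "M"]
  expect_equal(got, elim_parent, tolerance = 1e-10)
  expect_gt(got, classic_parent)

  expect_error(go_enrichment_elim(c("nope", study), universe, dag),
               "absent from the universe")
})

test_that("reported expected value always equals annotated*|study|/|universe|", {
  set.seed(66)
  dag <- flat_dag(4, 15)
  universe <- unique(unlist(dag$genes))
  study <- sample(universe, 10)
  res <- go_enrichment_elim(study, universe, dag)
  expect_equal(res$expected,
               res$annotated * length(study) / length(universe))
  expect_true(all(res$significant <= res$annotated))
})
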