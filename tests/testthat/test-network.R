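test_that("edge canonicalisation dedupes, orders and drops self-loops", {
  e <- data.frame(gene_a = c("B", "A", "C", "C"),
                  gene_b = c("A", "B", "C", "D"),
                  combined_score = c(0.9, 0.8, 0.5, 0.7))
  ce <- canonical_edges(e)
  expect_equal(nrow(ce), 2)                      # self-loop gone, dup collapsed
  expect_equal(ce$combined_score[ce$gene_a == "A"], 0.9)  # max kept
  expect_true(all(ce$gene_a < ce$gene_b))
  expect_error(canonical_edges(data.frame(gene_a = "A", gene_b = "B",
                                          combined_score = 1.4)),
               "\\[0, 1\\]")
})

test_that("node scores count distinct retained interactors above a strict threshold", {
  e <- data.frame(gene_a = c("KCNV2", "KCNV2", "X", "X"),
                  gene_b = c("P1", "P2", "Y", "KCNV2"),
                  combined_score = c(0.926, 0.4, 0.41, 0.39))
  ns <- node_scores(e, members = c("KCNV2", "P1", "P2", "X", "Y"))
  row <- ns[ns$gene == "KCNV2", ]
  # only the 0.926 edge survives: 0.4 is not strictly above the threshold
  # and 0.39 is below it
  expect_equal(row$n_nodes, 1)
  expect_equal(row$total_score, 0.926)
  expect_equal(row$mean_score, 0.926)
  expect_false("P2" %in% ns$gene)
  # non-member endpoints exclude the edge entirely
  ns2 <- node_scores(e, members = c("KCNV2", "P1"))
  expect_equal(nrow(ns2), 2)
})

test_that("node scores agree with igraph on random networks", {
  set.seed(707)
  genes <- sprintf("G%02d", 1:25)
  pairs <- t(combn(genes, 2))
  pick <- runif(nrow(pairs)) < 0.2
  e <- data.frame(gene_a = pairs[pick, 1], gene_b = pairs[pick, 2],
                  combined_score = round(runif(sum(pick)), 3))
  members <- sample(genes, 18)
  ns <- node_scores(e, members, threshold = 0.4)
  kept <- e[e$combined_score > 0.4 & e$gene_a %in% members &
              e$gene_b %in% members, ]
  g <- igraph::graph_from_data_frame(kept, directed = FALSE)
  deg <- igraph::degree(g)
  str <- igraph::strength(g, weights = kept$combined_score)
  for (i in seq_len(nrow(ns))) {
    expect_equal(ns$n_nodes[i], unname(deg[ns$gene[i]]))
    expect_equal(ns$total_score[i], unname(str[ns$gene[i]]), tolerance = 1e-9)
  }
})

test_that("group combination halves single-group genes and averages shared ones", {
  g1 <- data.frame(gene = c("RYR2", "KCNV2"), n_nodes = c(37, 1),
                   total_score = c(23.226, 0.926),
                   mean_score = c(0.628, 0.926))
  g2 <- data.frame(gene = "RYR2", n_nodes = 10, total_score = 6.533,
                   mean_score = 0.653)
  cr <- combine_groups(g1, g2)
  expect_equal(cr$combined_total[cr$gene == "RYR2"], (23.226 + 6.533) / 2)
  expect_equal(cr$combined_nodes[cr$gene == "RYR2"], 23.5)
  expect_equal(cr$combined_total[cr$gene == "KCNV2"], 0.926 / 2)
  expect_equal(cr$combined_nodes[cr$gene == "KCNV2"], 0.5)
  expect_true(is.na(cr$total_score_2[cr$gene == "KCNV2"]))
  # identical groups collapse to the single-group totals
  same <- combine_groups(g1, g1)
  expect_equal(same$combined_total, same$total_score_1)
})

test_that("combination reproduces every published two-group row", {
  tab <- avnrt_study_table("ppi_group_scores")
  g1 <- na.omit(tab[, c("gene", "n_nodes_1", "total_score_1", "mean_score_1")])
  names(g1) <- c("gene", "n_nodes", "total_score", "mean_score")
  g2 <- na.omit(tab[, c("gene", "n_nodes_2", "total_score_2", "mean_score_2")])
  names(g2) <- c("gene", "n_nodes", "total_score", "mean_score")
  cr <- combine_groups(g1, g2)
  m <- match(tab$gene, cr$gene)
  expect_equal(round(cr$combined_total[m], 3), round(tab$combined_total, 3),
               tolerance = 1e-3)
  expect_equal(cr$combined_nodes[m], tab$combined_nodes, tolerance = 1e-9)
  # published per-group means are consistent with total/nodes up to the
  # rounding of the printed mean (half an ulp of 3 d.p. per node)
  with_nodes <- !is.na(tab$n_nodes_1)
  expect_true(all(abs(tab$mean_score_1[with_nodes] * tab$n_nodes_1[with_nodes] -
                        tab$total_score_1[with_nodes]) <=
                    tab$n_nodes_1[with_nodes] * 5e-4 + 1e-9))
})

test_that("ranking is a deterministic total order with tie-breaks", {
  g1 <- data.frame(gene = c("B", "A", "C"), n_nodes = c(2, 2, 1),
                   total_score = c(1.0, 1.0, 1.0),
                   mean_score = c(0.5, 0.5, 1.0))
  g2 <- g1[0, ]
  cr <- combine_groups(g1, g2)
  expect_equal(cr$gene, c("A", "B", "C"))   # nodes desc, then symbol
  expect_equal(cr$rank, 1:3)
})

test_that("prioritisation returns the published top-10 ordering", {
  tab <- avnrt_study_table("ppi_group_scores")
  g1 <- na.omit(tab[, c("gene", "n_nodes_1", "total_score_1", "mean_score_1")])
  names(g1) <- c("gene", "n_nodes", "total_score", "mean_score")
  g2 <- na.omit(tab[, c("gene", "n_nodes_2", "total_score_2", "mean_score_2")])
  names(g2) <- c("gene", "n_nodes", "total_score", "mean_score")
  cr <- combine_groups(g1, g2)
  counts <- avnrt_study_table("burden_counts")
  ft <- fisher_exact(counts$carrier_cases_maf001,
                     82 - counts$carrier_cases_maf001,
                     counts$carrier_controls_maf001,
                     100 - counts$carrier_controls_maf001,
                     alternative = "greater")
  burden <- data.frame(gene = counts$gene, stratum = "MAF<0.001",
                       p_value = ft$p_value)
  top <- prioritize(cr, burden, k = 10,
                    reference_genes = avnrt_study_table("reference_gene_tally")$gene)
  expect_equal(top$gene, c("RYR2", "NOS1", "SCN1A", "CFTR", "EPHB4",
                           "PRKAG2", "ROBO1", "ASPH", "MMP2", "ABCC8"))
  expect_true(top$in_reference_panel[top$gene == "RYR2"])
  expect_false(top$in_reference_panel[top$gene == "CFTR"])
  # k beyond the list length returns everything; empty ranking stays empty
  expect_equal(nrow(prioritize(cr, burden, k = 100)), nrow(cr))
  expect_equal(nrow(prioritize(cr[0, ], burden)), 0)
})
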