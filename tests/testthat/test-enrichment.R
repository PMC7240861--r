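toy_sets <- function() {
  list(sets = list(P1 = sprintf("G%02d", 1:10),
                   P2 = sprintf("G%02d", 5:30),
                   P3 = sprintf("G%02d", 25:40)),
       description = c(P1 = "one", P2 = "two", P3 = "three"))
}

test_that("hypergeometric enrichment matches the direct-summation oracle", {
  # fixed example: population 1000, pathway 50, draws 100, overlap 10
  pop <- c(sprintf("X%04d", 1:1000))
  gs <- list(sets = list(BIG = pop[1:50]), description = c(BIG = "big"))
  input <- c(pop[1:10], pop[101:190])   # 10 in pathway, 90 outside
  res <- hypergeom_enrich(input, gs, background = pop)
  expect_equal(res$p_value, oracle_hypergeom_upper(10, 50, 1000, 100),
               tolerance = 1e-12)
  expect_equal(res$input_number, 10)
  expect_equal(res$background_number, 50)
  expect_equal(res$rich_factor, 10 / 50)
})

test_that("enrichment edge cases: no overlap and saturated overlap", {
  gs <- toy_sets()
  bg <- sprintf("G%02d", 1:40)
  res <- hypergeom_enrich(sprintf("G%02d", 31:40), gs, background = bg)
  expect_equal(res$p_value[res$set_id == "P1"], 1)     # k = 0
  full <- hypergeom_enrich(bg, list(sets = list(ALL = bg),
                                    description = c(ALL = "all")),
                           background = bg)
  expect_equal(full$p_value, 1)   # point mass: draws = population
  expect_equal(full$rich_factor, 1)
})

test_that("enrichment matches oracle over random draws", {
  set.seed(505)
  for (i in 1:25) {
    N <- sample(50:2000, 1)
    bg <- sprintf("B%05d", seq_len(N))
    K <- sample(5:min(200, N), 1)
    n_draw <- sample(5:min(300, N), 1)
    gs <- list(sets = list(S = sample(bg, K)), description = c(S = "s"))
    input <- sample(bg, n_draw)
    res <- hypergeom_enrich(input, gs, background = bg)
    k <- length(intersect(input, gs$sets$S))
    expect_equal(res$p_value, oracle_hypergeom_upper(k, K, N, n_draw),
                 tolerance = 1e-9)
  }
})

test_that("input genes outside the background are dropped with a message", {
  gs <- toy_sets()
  expect_message(
    res <- hypergeom_enrich(c("G01", "NOT_A_GENE"), gs),
    "outside the background")
  expect_equal(res$input_number[res$set_id == "P1"], 1)
  expect_error(hypergeom_enrich("G01", list(sets = list(), description = NULL)),
               "empty background")
})

test_that("BH correction matches hand computation and is permutation invariant", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(0.04, 5)), rep(0.04, 5))
  set.seed(606)
  p <- runif(30)
  expect_equal(adjust_pvalues(p), oracle_bh(p), tolerance = 1e-12)
  perm <- sample(30)
  expect_equal(adjust_pvalues(p[perm]), adjust_pvalues(p)[perm])
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("top pathways are ranked by corrected then raw p then id", {
  res <- data.frame(set_id = sprintf("S%02d", 1:40), name = "x",
                    input_number = 1, background_number = 10,
                    p_value = seq(0.001, 0.04, length.out = 40),
                    corrected_p = rep(c(0.02, 0.04), each = 20),
                    rich_factor = 0.1, overlap_genes = "g")
  top <- top_pathways(res, k = 30)
  expect_equal(nrow(top), 30)
  expect_true(all(diff(top$corrected_p) >= 0))
  tied <- data.frame(set_id = c("B", "A"), name = "x", input_number = 1,
                     background_number = 10, p_value = c(0.01, 0.005),
                     corrected_p = 0.03, rich_factor = 0.1,
                     overlap_genes = "g")
  expect_equal(top_pathways(tied)$set_id, c("A", "B"))
})

test_that("a planted overlap-heavy pathway ranks first", {
  bg <- sprintf("G%03d", 1:200)
  gs <- list(sets = list(PLANT = bg[1:20], R1 = bg[50:90], R2 = bg[100:160]),
             description = c(PLANT = "p", R1 = "r", R2 = "r"))
  input <- bg[1:15]   # 15/15 inside the planted set
  res <- hypergeom_enrich(input, gs, background = bg)
  expect_equal(top_pathways(res)$set_id[1], "PLANT")
})

test_that("candidate selection unions tagged overlap gene lists", {
  tabs <- rbind(avnrt_study_table("pathway_enrichment_maf01"),
                avnrt_study_table("pathway_enrichment_maf001"))
  genes <- select_candidates(tabs, tabs$set_id)
  # union of the published overlap lists: 35 unique symbols
  expect_length(genes, 35)
  expect_true(all(c("ABCC8", "CFTR", "NOS1", "SCN1A") %in% genes))
  expect_identical(genes, sort(unique(genes)))
  expect_length(select_candidates(tabs, character(0)), 0)
  # a tag listed twice does not duplicate genes
  expect_identical(select_candidates(tabs, rep("R-HSA-5576891", 2)),
                   select_candidates(tabs, "R-HSA-5576891"))
  expect_warning(select_candidates(tabs, "R-HSA-0000000"), "skipped")
})
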