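test_that("identical config and seed reproduce the bundle exactly", {
  cfg <- tiny_config(seed = 5, planted_or = c(GENE02 = 4))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # a different seed changes the data
  expect_false(identical(simulate_cohort(cfg),
                         simulate_cohort(tiny_config(seed = 6,
                                                     planted_or = c(GENE02 = 4)))))
})

test_that("bundle satisfies its structural invariants", {
  b <- simulate_cohort(tiny_config(seed = 3))
  expect_true(all(colnames(b$genotypes$dosage) %in% b$variants$key))
  expect_setequal(b$truth$gene, default_gene_panel(6)$gene)
  expect_true(all(b$genotypes$dosage %in% c(0L, 1L, 2L, NA)))
  afs <- c(b$variants$af_exac, b$variants$af_kg)
  expect_true(all(afs >= 0 & afs <= 1, na.rm = TRUE))
  expect_true(all(b$variants$functional_class %in% variant_classes()))
  expect_gt(mean(is.na(b$genotypes$dosage)), 0)   # missingness applied
  expect_true(all(b$external_table$gene %in% b$variants$gene))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_cases = 0), "positive")
  expect_error(simulation_config(planted_or = c(G1 = -2)), "> 0")
  expect_error(simulation_config(planted_or = 2), "named")
  expect_error(simulation_config(genes = default_gene_panel(0)), "non-empty")
})

test_that("case carrier rates follow the odds-scale tilt of the planted effect", {
  cfg <- simulation_config(
    n_cases = 4000, n_controls = 4000,
    genes = data.frame(gene = "G1", n_sites = 1),
    carrier_p0 = c(G1 = 0.1), planted_or = c(G1 = 3),
    n_common_variants = 0, missing_af_rate = 1, seed = 21)
  b <- simulate_cohort(cfg)
  carrier <- rowSums(b$genotypes$dosage >= 1) > 0
  p_case <- mean(carrier[b$genotypes$status == "case"])
  p_ctrl <- mean(carrier[b$genotypes$status == "control"])
  expect_equal(p_ctrl, 0.1, tolerance = 0.15)
  p1 <- (3 * 0.1 / 0.9) / (1 + 3 * 0.1 / 0.9)   # 0.25
  expect_equal(p_case, p1, tolerance = 0.1)
  expect_equal(b$truth$p_carrier_cases[b$truth$gene == "G1"], p1)
})

test_that("empirical burden power matches the exact binomial-carrier oracle", {
  # one gene, control carrier rate 0.05, planted carrier OR 5, n = 82/100
  expected <- oracle_burden_power(82, 100, 0.05, 5)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(
      n_cases = 82, n_controls = 100,
      genes = data.frame(gene = "G1", n_sites = 1),
      carrier_p0 = c(G1 = 0.05), planted_or = c(G1 = 5),
      n_common_variants = 0, missing_af_rate = 1, seed = 7000 + r)
    b <- simulate_cohort(cfg)
    qs <- build_qualifying_sets(b$variants)
    res <- gene_burden(qs[["MAF<0.01"]], b$genotypes)
    p <- if (nrow(res) == 0) 1 else res$p_value[1]
    if (p < 0.05) hits <- hits + 1
  }
  expect_lt(abs(hits / n_rep - expected), 0.05)
})

test_that("null burden p-values are valid (conservative, never anti-conservative)", {
  # With all odds ratios at 1 the exact test's p-value distribution is
  # discrete and stochastically larger than uniform: P(p <= t) <= t up to
  # Monte Carlo noise.  (Exact uniformity is impossible for a discrete
  # exact test, so a KS test against the uniform is not applicable.)
  cfg <- simulation_config(
    genes = data.frame(gene = sprintf("G%03d", 1:300),
                       n_sites = rep(c(2, 4, 6), 100)),
    n_common_variants = 0, missing_af_rate = 1, seed = 77)
  b <- simulate_cohort(cfg)
  qs <- build_qualifying_sets(b$variants)
  res <- gene_burden(qs[["MAF<0.01"]], b$genotypes)
  expect_gt(nrow(res), 150)
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    mc_slack <- 3 * sqrt(t * (1 - t) / nrow(res))
    expect_lte(mean(res$p_value <= t), t + mc_slack)
  }
})

test_that("written bundle files round-trip through the readers", {
  b <- simulate_cohort(tiny_config(seed = 11))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  keys <- sort(b$variants$key)
  expect_identical(b$genotypes$dosage[, keys], b2$genotypes$dosage[, keys])
  expect_identical(b$genotypes$status, b2$genotypes$status)
  cols <- c("key", "gene", "functional_class", "hgvs_c", "hgvs_p",
            "af_exac", "af_kg")
  v1 <- b$variants[order(b$variants$key), cols]
  v2 <- b2$variants[order(b2$variants$key), cols]
  rownames(v1) <- rownames(v2) <- NULL
  expect_equal(v1, v2)
  expect_identical(lapply(b$gene_sets$sets, sort),
                   lapply(b2$gene_sets$sets, sort))
  expect_identical(b$gene_sets$description, b2$gene_sets$description)
  expect_equal(b$ppi_edges, b2$ppi_edges)
  expect_equal(b$external_table$gene, b2$external_table$gene)
  expect_equal(b$external_table$hgvs_c, b2$external_table$hgvs_c)
})

test_that("VCF records are written in coordinate order", {
  b <- simulate_cohort(tiny_config(seed = 2))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  lines <- readLines(file.path(dir, "cohort.vcf"))
  body <- lines[!startsWith(lines, "#")]
  fields <- do.call(rbind, strsplit(body, "\t"))[, 1:2]
  chrom <- as.numeric(fields[, 1])
  pos <- as.numeric(fields[, 2])
  # oracle comparator: lexicographic (chrom, pos) must already be sorted
  expect_identical(order(chrom, pos), seq_along(chrom))
})

test_that("empty external table writes a header-only TSV", {
  b <- simulate_cohort(tiny_config(seed = 4, external_fraction = 0))
  expect_equal(nrow(b$external_table), 0)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  lines <- readLines(file.path(dir, "external_variants.tsv"))
  expect_length(lines, 1)
  expect_match(lines, "^gene\t")
})
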