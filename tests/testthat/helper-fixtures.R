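# Small shared simulation configs.

tiny_config <- function(seed = 1, ...) {
  simulation_config(
    n_cases = 30, n_controls = 40,
    genes = default_gene_panel(6),
    n_common_variants = 10,
    pathway_config = list(n_sets = 4, min_size = 3, max_size = 10,
                          background_size = 30,
                          planted_genes = character(0)),
    missing_genotype_rate = 0.02,
    seed = seed, ...)
}

# Genotype list built directly from a dosage matrix.
make_genotypes <- function(dosage, n_cases) {
  n <- nrow(dosage)
  list(sample_ids = rownames(dosage),
       status = factor(rep(c("case", "control"), c(n_cases, n - n_cases)),
                       levels = c("case", "control")),
       dosage = dosage)
}

# Dosage matrix realising given per-gene carrier counts: one variant per
# gene, carriers are the first samples of each group.
carrier_dosage <- function(carrier_cases, carrier_controls, n_cases,
                           n_controls, keys) {
  n <- n_cases + n_controls
  dosage <- matrix(0L, n, length(keys),
                   dimnames = list(sprintf("S%03d", 1:n), keys))
  for (j in seq_along(keys)) {
    if (carrier_cases[j] > 0) dosage[seq_len(carrier_cases[j]), j] <- 1L
    if (carrier_controls[j] > 0) {
      dosage[n_cases + seq_len(carrier_controls[j]), j] <- 1L
    }
  }
  dosage
}
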