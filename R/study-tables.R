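#' Bundled AVNRT discovery-study summary tables
#'
#' The package ships the published summary tables of the AVNRT case-control
#' exome study (82 cases / 100 controls) as plain-text data, so the
#' pipeline's statistics can be recomputed from the printed counts and
#' scores without access to individual-level data:
#' \describe{
#'   \item{`burden_counts`}{per-gene carrier counts at the two MAF strata
#'     (the inputs of the collapsing test).}
#'   \item{`ppi_group_scores`}{per-gene node counts, total and mean edge
#'     scores in the two PPI network constructions, plus the published
#'     combined values.}
#'   \item{`gwas_snps`}{single-variant hits with tested-allele frequencies
#'     in cases/controls.}
#'   \item{`pathway_enrichment_maf01`, `pathway_enrichment_maf001`}{pathway
#'     over-representation rows with overlap gene lists.}
#'   \item{`internal_candidate_variants`}{the study's RYR2/SCN1A rare
#'     variants (HGVS notation).}
#'   \item{`external_danish_variants`}{the Danish replication cohort's
#'     variants for the same genes.}
#'   \item{`reference_gene_tally`}{rare-variant counts over the reference
#'     gene panel (MAF < 0.001).}
#' }
#'
#' @param name one of the table names above.
#' @return data.frame.
#' @export
avnrt_study_table <- function(name = c("burden_counts", "ppi_group_scores",
                                       "gwas_snps",
                                       "pathway_enrichment_maf01",
                                       "pathway_enrichment_maf001",
                                       "internal_candidate_variants",
                                       "external_danish_variants",
                                       "reference_gene_tally")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("avnrt_", name, ".tsv"),
                      package = "avnrtwes", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
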