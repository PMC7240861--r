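#' Gene-based carrier-collapsing burden test
#'
#' Collapses each gene's qualifying variants to a per-sample binary carrier
#' indicator (dosage >= 1 at any qualifying site; missing dosage =
#' non-carrier) and tests carrier status against case/control labels with an
#' exact 2x2 test, separately per MAF stratum.
#'
#' @param qualifying_sets result of [build_qualifying_sets()] (list of
#'   strata), or a single stratum element.
#' @param genotypes cohort genotypes (`dosage` samples x variants matrix,
#'   `status` factor with levels `case`, `control`).
#' @param alternative p-value convention, see [fisher_exact()].
#' @return data.frame with one row per gene per stratum: `gene`, `stratum`,
#'   `carrier_cases`, `noncarrier_cases`, `carrier_controls`,
#'   `noncarrier_controls`, `odds_ratio`, `p_value`; ordered by `p_value`
#'   then `gene` within stratum.  Genes with no qualifying variant in the
#'   cohort, or carried by no sample in either group, are omitted.
#' @export
gene_burden <- function(qualifying_sets, genotypes,
                        alternative = c("two_sided_minlik", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.null(qualifying_sets$per_gene)) {
    qualifying_sets <- list(qualifying_sets)
    names(qualifying_sets) <- qualifying_sets[[1]]$stratum
  }
  dosage <- genotypes$dosage
  status <- genotypes$status
  n_cases <- sum(status == "case")
  n_controls <- sum(status == "control")
  res <- lapply(qualifying_sets, function(q) {
    genes <- names(q$per_gene)
    rows <- lapply(genes, function(g) {
      keys <- intersect(q$per_gene[[g]], colnames(dosage))
      if (length(keys) == 0) return(NULL)
      carrier <- rowSums(dosage[, keys, drop = FALSE] >= 1, na.rm = TRUE) > 0
      a <- sum(carrier & status == "case")
      c_ <- sum(carrier & status == "control")
      if (a == 0 && c_ == 0) return(NULL)
      data.frame(gene = g, stratum = q$stratum,
                 carrier_cases = a, noncarrier_cases = n_cases - a,
                 carrier_controls = c_,
                 noncarrier_controls = n_controls - c_)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0) {
    return(data.frame(gene = character(0), stratum = character(0),
                      carrier_cases = integer(0), noncarrier_cases = integer(0),
                      carrier_controls = integer(0),
                      noncarrier_controls = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0)))
  }
  ft <- fisher_exact(res$carrier_cases, res$noncarrier_cases,
                     res$carrier_controls, res$noncarrier_controls,
                     alternative = alternative)
  res$odds_ratio <- ft$odds_ratio
  res$p_value <- ft$p_value
  res <- res[order(res$stratum, res$p_value, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Significant burden genes per stratum
#'
#' Selects genes with `p_value < alpha` (strict), and also reports the
#' stratum-deduplicated union with the strata each gene was significant in.
#'
#' @param results data.frame from [gene_burden()].
#' @param alpha significance level (default 0.05, strict `<`).
#' @return List with `per_stratum` (named list of gene character vectors) and
#'   `combined` (data.frame `gene`, `strata`, `min_p`, one row per gene,
#'   ordered by `min_p` then symbol).
#' @export
significant_genes <- function(results, alpha = 0.05) {
  hit <- results[!is.na(results$p_value) & results$p_value < alpha, ,
                 drop = FALSE]
  per_stratum <- lapply(split(hit$gene, hit$stratum), unique)
  if (nrow(hit) == 0) {
    combined <- data.frame(gene = character(0), strata = character(0),
                           min_p = numeric(0))
  } else {
    combined <- do.call(rbind, lapply(split(hit, hit$gene), function(d) {
      data.frame(gene = d$gene[1],
                 strata = paste(sort(unique(d$stratum)), collapse = ";"),
                 min_p = min(d$p_value))
    }))
    combined <- combined[order(combined$min_p, combined$gene), , drop = FALSE]
    rownames(combined) <- NULL
  }
  list(per_stratum = per_stratum, combined = combined)
}
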