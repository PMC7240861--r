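#' Marker quality-control filter
#'
#' Removes variants with genotype missingness above `geno_max_missing`,
#' sample-wide minor-allele frequency below `maf_min`, or an exact
#' Hardy-Weinberg p-value below `hwe_min_p`.  HWE is computed on all samples
#' pooled by default (one marker-wide filter), or on controls only.
#'
#' @param genotypes cohort genotypes (`dosage` samples x variants,
#'   `status`).
#' @param geno_max_missing maximum fraction of missing genotypes (default 0.1).
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param hwe_min_p minimum exact HWE p-value (default 1e-4).
#' @param hwe_samples `"pooled"` (default) or `"controls"`.
#' @return List with `keep` (character vector of passing variant keys) and
#'   `counts` (named integer vector of exclusions per filter, applied in the
#'   order missingness, MAF, HWE).
#' @export
qc_filter <- function(genotypes, geno_max_missing = 0.1, maf_min = 0.01,
                      hwe_min_p = 1e-4,
                      hwe_samples = c("pooled", "controls")) {
  hwe_samples <- match.arg(hwe_samples)
  dosage <- genotypes$dosage
  n <- nrow(dosage)
  miss <- colMeans(is.na(dosage))
  fail_miss <- miss > geno_max_missing
  alt <- colSums(dosage, na.rm = TRUE)
  called <- 2 * colSums(!is.na(dosage))
  af <- ifelse(called > 0, alt / called, 0)
  maf <- pmin(af, 1 - af)
  fail_maf <- !fail_miss & maf < maf_min
  hwe_rows <- if (hwe_samples == "controls") {
    genotypes$status == "control"
  } else rep(TRUE, n)
  cand <- which(!fail_miss & !fail_maf)
  fail_hwe <- logical(ncol(dosage))
  for (j in cand) {
    d <- dosage[hwe_rows, j]
    d <- d[!is.na(d)]
    p <- hwe_exact(sum(d == 0), sum(d == 1), sum(d == 2))
    fail_hwe[j] <- p < hwe_min_p
  }
  keep <- colnames(dosage)[!fail_miss & !fail_maf & !fail_hwe]
  list(keep = keep,
       counts = c(missingness = sum(fail_miss), maf = sum(fail_maf),
                  hwe = sum(fail_hwe)))
}

#' Allelic Fisher exact association for one or more variants
#'
#' Builds the 2x2 allele-count table (2 alleles per called sample; missing
#' genotypes reduce the denominator) and applies the exact test.  The odds
#' ratio is `(case_alt * control_ref) / (case_ref * control_alt)`, i.e. the
#' cross-product for the tested (alternate) allele.
#'
#' @param genotypes cohort genotypes.
#' @param keys variant keys to test (default all columns).
#' @param alternative p-value convention, see [fisher_exact()]; the default
#'   two-sided minimum-likelihood convention matches standard GWAS practice.
#' @return data.frame: `key`, `f_a` (tested-allele frequency in cases),
#'   `f_u` (in controls), `case_alt`, `case_ref`, `control_alt`,
#'   `control_ref`, `odds_ratio`, `p_value`.
#' @export
allelic_fisher <- function(genotypes, keys = colnames(genotypes$dosage),
                           alternative = "two_sided_minlik") {
  dosage <- genotypes$dosage[, keys, drop = FALSE]
  cases <- genotypes$status == "case"
  count_group <- function(rows) {
    alt <- colSums(dosage[rows, , drop = FALSE], na.rm = TRUE)
    tot <- 2 * colSums(!is.na(dosage[rows, , drop = FALSE]))
    cbind(alt = alt, ref = tot - alt, tot = tot)
  }
  ca <- count_group(cases)
  co <- count_group(!cases)
  if (any(ca[, "tot"] == 0) || any(co[, "tot"] == 0)) {
    stop("variant with zero called alleles in one group")
  }
  ft <- fisher_exact(ca[, "alt"], ca[, "ref"], co[, "alt"], co[, "ref"],
                     alternative = alternative)
  data.frame(key = keys,
             f_a = ca[, "alt"] / ca[, "tot"],
             f_u = co[, "alt"] / co[, "tot"],
             case_alt = ca[, "alt"], case_ref = ca[, "ref"],
             control_alt = co[, "alt"], control_ref = co[, "ref"],
             odds_ratio = ft$odds_ratio, p_value = ft$p_value,
             row.names = NULL)
}

#' Genomic inflation factor (lambda)
#'
#' Median-based definition: the observed p-values are converted to 1-df
#' chi-square quantiles and the median is divided by the null median
#' (`qchisq(0.5, 1)` = 0.4549).
#'
#' @param p numeric vector of p-values.
#' @return Positive scalar, or `NA` for empty input.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  stats::qchisq(stats::median(p), df = 1, lower.tail = FALSE) /
    stats::qchisq(0.5, df = 1)
}

#' Single-variant genome scan with QQ diagnostics
#'
#' Runs [allelic_fisher()] over the QC-passing variants and summarises the
#' p-value distribution: genomic-inflation lambda, QQ table of expected vs
#' observed -log10 p, the genome-wide significant hits, and the genes
#' carrying any suggestive variant (for downstream pathway enrichment).
#'
#' @param genotypes cohort genotypes.
#' @param variants variant annotation data.frame (`key`, `gene`).
#' @param keep character vector of QC-passing keys (from [qc_filter()]).
#' @param significance genome-wide threshold (default 1e-6).
#' @param suggestive threshold feeding the enrichment gene list (default 0.01).
#' @param alternative p-value convention for the allelic test.
#' @return List: `results` (per-variant data.frame with `gene` attached),
#'   `summary` (list `lambda_gc`, `qq_points`, `n_pass_filters`),
#'   `significant` (rows with `p_value < significance`),
#'   `suggestive_genes` (sorted unique gene symbols with any
#'   `p_value < suggestive`).
#' @export
genome_scan <- function(genotypes, variants, keep,
                        significance = 1e-6, suggestive = 0.01,
                        alternative = "two_sided_minlik") {
  if (length(keep) == 0) {
    return(list(results = NULL,
                summary = list(lambda_gc = NA_real_, qq_points = NULL,
                               n_pass_filters = 0L),
                significant = NULL, suggestive_genes = character(0)))
  }
  res <- allelic_fisher(genotypes, keep, alternative = alternative)
  res$gene <- variants$gene[match(res$key, variants$key)]
  obs <- sort(res$p_value)
  m <- length(obs)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(obs))
  qq <- qq[order(qq$expected), , drop = FALSE]
  list(results = res,
       summary = list(lambda_gc = lambda_gc(res$p_value),
                      qq_points = qq, n_pass_filters = m),
       significant = res[res$p_value < significance, , drop = FALSE],
       suggestive_genes = sort(unique(stats::na.omit(
         res$gene[res$p_value < suggestive]))))
}
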