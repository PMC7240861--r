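#' @keywords internal
"_PACKAGE"

# Controlled functional-class vocabulary.
VARIANT_CLASSES <- c("nonsense", "missense", "splice_site", "frameshift",
                     "inframe_indel", "synonymous", "intron", "utr", "other")

# Classes that qualify a variant as deleterious for collapsing:
# nonsense, missense, splice-site and indel (frameshift + in-frame) changes.
DELETERIOUS_CLASSES <- c("nonsense", "missense", "splice_site",
                         "frameshift", "inframe_indel")

#' Deleterious functional classes
#'
#' The controlled vocabulary of variant functional classes, and the subset
#' counted as deleterious for carrier collapsing (nonsense, missense,
#' splice-site, frameshift and in-frame indel changes).
#'
#' @return Character vector of class labels.
#' @export
deleterious_classes <- function() DELETERIOUS_CLASSES

#' @rdname deleterious_classes
#' @export
variant_classes <- function() VARIANT_CLASSES

#' Flag deleterious variants
#'
#' Pure function of the functional class: `TRUE` iff the class is one of
#' nonsense, missense, splice_site, frameshift or inframe_indel.
#'
#' @param functional_class character vector drawn from [variant_classes()].
#' @return Logical vector.
#' @export
classify_deleterious <- function(functional_class) {
  bad <- setdiff(unique(functional_class), VARIANT_CLASSES)
  if (length(bad) > 0) {
    stop("unknown functional class value(s): ", paste(bad, collapse = ", "))
  }
  functional_class %in% DELETERIOUS_CLASSES
}

#' Assign variants to MAF rarity strata
#'
#' A variant belongs to a stratum when every reference-panel allele frequency
#' that is reported for it lies strictly below the stratum threshold; a
#' variant with no reported panel frequency counts as rare (AF 0).  With the
#' default thresholds this yields the nested strata MAF<0.001 and MAF<0.01.
#'
#' @param panel_afs numeric matrix or data.frame, one row per variant, one
#'   column per reference panel; `NA` = panel does not report the variant.
#' @param thresholds named numeric vector of stratum upper bounds.
#' @return Logical matrix, variants x strata.
#' @export
stratify_by_maf <- function(panel_afs,
                            thresholds = c("MAF<0.001" = 0.001,
                                           "MAF<0.01"  = 0.01)) {
  afs <- as.matrix(panel_afs)
  if (any(afs < 0 | afs > 1, na.rm = TRUE)) {
    stop("panel allele frequencies must lie in [0, 1]")
  }
  # max available AF per variant; all-missing rows behave as AF 0
  max_af <- suppressWarnings(apply(afs, 1, max, na.rm = TRUE))
  max_af[!is.finite(max_af)] <- 0
  out <- vapply(thresholds, function(thr) max_af < thr,
                logical(nrow(afs)))
  out <- matrix(out, nrow = nrow(afs),
                dimnames = list(rownames(afs), names(thresholds)))
  out
}

#' Build per-gene qualifying variant sets at each MAF stratum
#'
#' A qualifying variant is deleterious-class and below the stratum's panel-AF
#' threshold.  Variants with an empty or missing gene label are excluded (a
#' warning reports how many).
#'
#' @param variants data.frame with columns `key`, `gene`, `functional_class`,
#'   and one `af_*` column per reference panel (e.g. `af_exac`, `af_kg`).
#' @param thresholds as in [stratify_by_maf()].
#' @return Named list, one element per stratum, each a list with `stratum`,
#'   `variant_keys` (character) and `per_gene` (named list of key vectors).
#' @export
build_qualifying_sets <- function(variants,
                                  thresholds = c("MAF<0.001" = 0.001,
                                                 "MAF<0.01"  = 0.01)) {
  stopifnot(all(c("key", "gene", "functional_class") %in% names(variants)))
  af_cols <- grep("^af_", names(variants), value = TRUE)
  if (length(af_cols) == 0) stop("no af_* panel columns in variant table")
  if (nrow(variants) == 0) {
    return(lapply(stats::setNames(names(thresholds), names(thresholds)),
                  function(s) list(stratum = s,
                                   variant_keys = character(0),
                                   per_gene = list())))
  }
  no_gene <- is.na(variants$gene) | variants$gene == ""
  if (any(no_gene)) {
    warning(sum(no_gene), " variant(s) without a gene label excluded")
    variants <- variants[!no_gene, , drop = FALSE]
  }
  deleterious <- classify_deleterious(variants$functional_class)
  strata <- stratify_by_maf(variants[, af_cols, drop = FALSE], thresholds)
  out <- lapply(names(thresholds), function(s) {
    keep <- deleterious & strata[, s]
    keys <- variants$key[keep]
    per_gene <- split(keys, variants$gene[keep])
    per_gene <- per_gene[order(names(per_gene))]
    list(stratum = s, variant_keys = keys, per_gene = per_gene)
  })
  names(out) <- names(thresholds)
  out
}

#' Tabulate qualifying variants and case carriers over a reference gene panel
#'
#' For each panel gene: the number of qualifying variants and the number of
#' case samples carrying at least one of them (carrier = dosage >= 1;
#' missing dosage counts as non-carrier).
#'
#' @param qualifying one stratum element from [build_qualifying_sets()].
#' @param genotypes cohort genotypes as returned by [simulate_cohort()] or
#'   [read_cohort()]: list with `dosage` (samples x variants matrix),
#'   `status` (factor `case`/`control`).
#' @param panel_genes character vector of panel gene symbols.
#' @return data.frame with columns `gene`, `n_variants`, `n_case_carriers`.
#' @export
panel_summary <- function(qualifying, genotypes, panel_genes) {
  dosage <- genotypes$dosage
  cases <- genotypes$status == "case"
  rows <- lapply(panel_genes, function(g) {
    keys <- intersect(qualifying$per_gene[[g]], colnames(dosage))
    if (length(keys) == 0) {
      return(data.frame(gene = g, n_variants = 0L, n_case_carriers = 0L))
    }
    sub <- dosage[cases, keys, drop = FALSE]
    carrier <- rowSums(sub >= 1, na.rm = TRUE) > 0
    data.frame(gene = g,
               n_variants = length(qualifying$per_gene[[g]]),
               n_case_carriers = sum(carrier))
  })
  do.call(rbind, rows)
}
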