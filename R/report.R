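#' Normalise HGVS notation strings
#'
#' Canonicalises transcript- (c.) and protein- (p.) level variant notation
#' for cross-cohort string matching: strips all whitespace (including around
#' ">"), maps unicode minus/dash variants to ASCII "-", and treats lone "."
#' or empty strings as missing (`NA`).  Idempotent.
#'
#' @param x character vector of HGVS strings.
#' @return Character vector with `NA` for missing entries.
#' @export
normalize_hgvs <- function(x) {
  out <- gsub("\\s+", "", as.character(x))
  out <- gsub("[−‐‑‒–—]", "-", out)
  out[out %in% c("", ".", "NA") | is.na(out)] <- NA_character_
  out
}

#' Cross-cohort variant overlap validation
#'
#' Compares internal candidate variants against an external cohort's variant
#' table, matching within gene at the strongest level available per pair:
#' `protein_exact` (identical normalised p. strings), `cdna_exact`
#' (identical normalised c. strings), else `gene_only`.  External records
#' whose gene is missing or that carry neither a c. nor a p. string are
#' skipped with a warning.
#'
#' @param internal data.frame with `gene`, `hgvs_c`, `hgvs_p` and a variant
#'   identifier column `key` (or `hgvs_c` reused as key).
#' @param external data.frame with `gene`, `hgvs_c`, `hgvs_p`,
#'   `cohort_label`.
#' @return data.frame: `gene`, `match_level`, `internal_key`,
#'   `internal_hgvs_c`, `internal_hgvs_p`, `external_hgvs_c`,
#'   `external_hgvs_p`, `cohort_label`; exact matches first.
#' @export
overlap_validation <- function(internal, external) {
  if (!"key" %in% names(internal)) internal$key <- internal$hgvs_c
  int_c <- normalize_hgvs(internal$hgvs_c)
  int_p <- normalize_hgvs(internal$hgvs_p)
  ext_c <- normalize_hgvs(external$hgvs_c)
  ext_p <- normalize_hgvs(external$hgvs_p)
  malformed <- (is.na(external$gene) | external$gene == "") |
    (is.na(ext_c) & is.na(ext_p))
  if (any(malformed)) {
    warning(sum(malformed), " malformed external record(s) skipped")
  }
  out <- list()
  for (j in which(!malformed)) {
    same_gene <- which(internal$gene == external$gene[j])
    if (length(same_gene) == 0) next
    for (i in same_gene) {
      level <- if (!is.na(int_p[i]) && !is.na(ext_p[j]) &&
                   int_p[i] == ext_p[j]) {
        "protein_exact"
      } else if (!is.na(int_c[i]) && !is.na(ext_c[j]) &&
                 int_c[i] == ext_c[j]) {
        "cdna_exact"
      } else {
        "gene_only"
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = external$gene[j], match_level = level,
        internal_key = internal$key[i],
        internal_hgvs_c = int_c[i], internal_hgvs_p = int_p[i],
        external_hgvs_c = ext_c[j], external_hgvs_p = ext_p[j],
        cohort_label = if ("cohort_label" %in% names(external))
          external$cohort_label[j] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), match_level = character(0),
                      internal_key = character(0),
                      internal_hgvs_c = character(0),
                      internal_hgvs_p = character(0),
                      external_hgvs_c = character(0),
                      external_hgvs_p = character(0),
                      cohort_label = character(0)))
  }
  res <- do.call(rbind, out)
  lvl <- factor(res$match_level,
                levels = c("protein_exact", "cdna_exact", "gene_only"))
  res <- res[order(lvl, res$gene, res$internal_key), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cohort summary statistics
#'
#' Counts per case/control group; female:male ratio (2 d.p., `NA` with a
#' flag when a cohort has no males); mean +/- SD for numeric clinical
#' columns, or median (IQR) for columns named in `median_cols`.
#'
#' @param status factor of `case`/`control` labels.
#' @param sex optional character/factor of `female`/`male` (cases only or
#'   full cohort; summarised as given).
#' @param clinical optional data.frame of numeric clinical columns.
#' @param median_cols character vector of clinical columns to summarise as
#'   median (IQR).
#' @return List: `n_cases`, `n_controls`, `female_male_ratio`,
#'   `ratio_defined`, `clinical` (data.frame of formatted summaries).
#' @export
cohort_summary <- function(status, sex = NULL, clinical = NULL,
                           median_cols = character(0)) {
  out <- list(n_cases = sum(status == "case"),
              n_controls = sum(status == "control"))
  if (!is.null(sex)) {
    n_f <- sum(sex == "female")
    n_m <- sum(sex == "male")
    out$ratio_defined <- n_m > 0
    out$female_male_ratio <- if (n_m > 0) round(n_f / n_m, 2) else NA_real_
  }
  if (!is.null(clinical)) {
    rows <- lapply(names(clinical), function(v) {
      x <- clinical[[v]]
      if (!is.numeric(x)) return(NULL)
      if (v %in% median_cols) {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
        data.frame(variable = v,
                   summary = sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3]))
      } else {
        data.frame(variable = v,
                   summary = sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE),
                                     stats::sd(x, na.rm = TRUE)))
      }
    })
    out$clinical <- do.call(rbind, rows)
  }
  out
}

#' Consolidated run report
#'
#' Assembles whichever stage outputs are available into one structured,
#' deterministic report: QC counts, burden table, top pathways, PPI ranking,
#' overlap matches, and a final per-gene evidence trail (burden p and
#' stratum, pathway tags, combined PPI score, external match count).
#' Sections for absent stages are omitted; no timestamps are embedded, so
#' identical inputs give identical reports.
#'
#' @param cohort optional output of [cohort_summary()].
#' @param qc optional output of [qc_filter()].
#' @param burden optional data.frame from [gene_burden()].
#' @param pathways optional data.frame from [top_pathways()].
#' @param candidate_genes optional character vector from
#'   [select_candidates()].
#' @param ppi optional data.frame from [prioritize()] or [combine_groups()].
#' @param overlaps optional data.frame from [overlap_validation()].
#' @param parameters optional named list of run parameters (seed included),
#'   stored verbatim.
#' @return List of class `avnrt_report` with an `evidence` data.frame when
#'   enough stages are present.
#' @export
build_report <- function(cohort = NULL, qc = NULL, burden = NULL,
                         pathways = NULL, candidate_genes = NULL,
                         ppi = NULL, overlaps = NULL, parameters = NULL) {
  report <- list()
  for (nm in c("parameters", "cohort", "qc", "burden", "pathways",
               "candidate_genes", "ppi", "overlaps")) {
    val <- get(nm)
    if (!is.null(val)) report[[nm]] <- val
  }
  genes <- unique(c(if (!is.null(burden)) burden$gene,
                    if (!is.null(ppi)) ppi$gene))
  if (length(genes) > 0) {
    ev <- data.frame(gene = sort(genes), stringsAsFactors = FALSE)
    if (!is.null(burden)) {
      best <- vapply(ev$gene, function(g) {
        p <- burden$p_value[burden$gene == g]
        if (length(p) == 0) NA_real_ else min(p, na.rm = TRUE)
      }, numeric(1))
      ev$burden_p <- best
    }
    if (!is.null(candidate_genes)) {
      ev$pathway_candidate <- ev$gene %in% candidate_genes
    }
    if (!is.null(ppi)) {
      ev$combined_score <- ppi$combined_total[match(ev$gene, ppi$gene)]
    }
    if (!is.null(overlaps)) {
      exact <- overlaps[overlaps$match_level != "gene_only", , drop = FALSE]
      ev$external_exact_matches <-
        vapply(ev$gene, function(g) sum(exact$gene == g), integer(1))
    }
    ord <- if (!is.null(ev$combined_score)) {
      order(-ifelse(is.na(ev$combined_score), -Inf, ev$combined_score),
            ev$gene)
    } else if (!is.null(ev$burden_p)) {
      order(ev$burden_p, ev$gene)
    } else {
      order(ev$gene)
    }
    ev <- ev[ord, , drop = FALSE]
    rownames(ev) <- NULL
    report$evidence <- ev
  }
  structure(report, class = "avnrt_report")
}

#' Write a report as JSON plus a plain-text summary
#'
#' @param report an `avnrt_report`.
#' @param json_path,text_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, text_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE,
                         force = TRUE)
  }
  if (!is.null(text_path)) {
    lines <- c("AVNRT rare-variant prioritization report", "")
    if (!is.null(report$cohort)) {
      lines <- c(lines, sprintf("Cohort: %d cases / %d controls",
                                report$cohort$n_cases,
                                report$cohort$n_controls))
    }
    if (!is.null(report$qc)) {
      lines <- c(lines, sprintf("QC exclusions: %s",
                                paste(names(report$qc$counts),
                                      report$qc$counts, sep = "=",
                                      collapse = ", ")))
    }
    if (!is.null(report$burden)) {
      lines <- c(lines, sprintf("Burden results: %d gene-stratum rows",
                                nrow(report$burden)))
    }
    if (!is.null(report$evidence)) {
      lines <- c(lines, "", "Top genes by evidence:",
                 utils::capture.output(print(utils::head(report$evidence, 10))))
    }
    writeLines(lines, text_path)
  }
  invisible(report)
}
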