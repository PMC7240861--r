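#' Hypergeometric pathway over-representation
#'
#' For each gene set, tests whether the input gene list hits the set more
#' often than expected under sampling without replacement from the
#' background: upper-tail p = P(X >= k) with population |background|,
#' successes |set ∩ background|, draws |input ∩ background|, observed
#' k = |input ∩ set ∩ background|.  The rich factor is
#' k / |set ∩ background|.
#'
#' @param input_genes character vector of gene symbols; symbols outside the
#'   background are dropped (a message reports how many).
#' @param gene_sets gene-set collection as returned by [read_gmt()]: list
#'   with `sets` (named list of symbol vectors) and `description` (named
#'   character).
#' @param background background universe; default is the union of all genes
#'   in the collection.
#' @param method multiplicity-correction method passed to
#'   [adjust_pvalues()] (default `"BH"`); recorded in the result's
#'   `correction` attribute.
#' @return data.frame: `set_id`, `name`, `input_number`,
#'   `background_number`, `p_value`, `corrected_p`, `rich_factor`,
#'   `overlap_genes` (semicolon-joined, alphabetical).
#' @export
hypergeom_enrich <- function(input_genes, gene_sets, background = NULL,
                             method = "BH") {
  sets <- gene_sets$sets
  if (is.null(background)) background <- sort(unique(unlist(sets)))
  if (length(background) == 0) stop("empty background universe")
  input_genes <- unique(input_genes)
  outside <- setdiff(input_genes, background)
  if (length(outside) > 0) {
    message(length(outside), " input gene(s) outside the background dropped")
  }
  input <- intersect(input_genes, background)
  N <- length(background)
  n_draw <- length(input)
  rows <- lapply(names(sets), function(id) {
    in_bg <- intersect(sets[[id]], background)
    K <- length(in_bg)
    overlap <- sort(intersect(input, in_bg))
    k <- length(overlap)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(set_id = id,
               name = unname(gene_sets$description[id]),
               input_number = k, background_number = K,
               p_value = p,
               rich_factor = if (K > 0) k / K else NA_real_,
               overlap_genes = paste(overlap, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out$corrected_p <- adjust_pvalues(out$p_value, method = method)
  out <- out[, c("set_id", "name", "input_number", "background_number",
                 "p_value", "corrected_p", "rich_factor", "overlap_genes")]
  attr(out, "correction") <- method
  out
}

#' Multiple-testing correction
#'
#' Thin validated wrapper over [stats::p.adjust()]; default
#' Benjamini-Hochberg step-up.  Output order matches input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method correction method (see [stats::p.adjust.methods]).
#' @return Numeric vector of corrected p-values.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}

#' Top enriched pathways
#'
#' Ranks by corrected p ascending, breaking ties by raw p then set id, and
#' keeps at most `k` rows.  The returned table carries the bubble-chart
#' columns (rich factor, input number, corrected p).
#'
#' @param results data.frame from [hypergeom_enrich()].
#' @param k maximum number of pathways to keep (default 30).
#' @return Ranked data.frame (at most `k` rows).
#' @export
top_pathways <- function(results, k = 30) {
  ord <- order(results$corrected_p, results$p_value, results$set_id)
  out <- results[ord, , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Candidate genes from domain-tagged pathways
#'
#' Unions the overlap gene lists of the tagged pathways (the tags encode the
#' domain judgment of which enriched pathways are disease-relevant), and
#' returns the deduplicated, alphabetically sorted symbols.  Tags absent
#' from the results are skipped with a warning.
#'
#' @param results data.frame from [hypergeom_enrich()] (or any table with
#'   `set_id` and `overlap_genes` columns).
#' @param relevance_tags character vector of set ids.
#' @return Character vector of gene symbols.
#' @export
select_candidates <- function(results, relevance_tags) {
  if (!"overlap_genes" %in% names(results) && "genes" %in% names(results)) {
    results$overlap_genes <- results$genes
  }
  missing_tags <- setdiff(relevance_tags, results$set_id)
  if (length(missing_tags) > 0) {
    warning("tag(s) not present in results, skipped: ",
            paste(missing_tags, collapse = ", "))
  }
  rows <- results[results$set_id %in% relevance_tags, , drop = FALSE]
  genes <- unlist(strsplit(rows$overlap_genes, ";", fixed = TRUE))
  sort(unique(genes[genes != ""]))
}
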