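#' Canonicalise an undirected weighted PPI edge list
#'
#' Orders each pair lexicographically, drops self-loops, and collapses
#' duplicate pairs (keeping the maximum score).  Scores must lie in \[0, 1\].
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`,
#'   `combined_score`.
#' @return Canonical edge data.frame.
#' @export
canonical_edges <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  if (any(edges$combined_score < 0 | edges$combined_score > 1)) {
    stop("combined_score must lie in [0, 1]")
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- a != b
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    combined_score = edges$combined_score[keep])
  out <- out[order(out$gene_a, out$gene_b, -out$combined_score), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene node scores in a thresholded PPI network
#'
#' Induces the subnetwork on `members`, keeps edges with confidence score
#' strictly above `threshold` (0.4 = medium confidence), and scores each
#' member gene by its number of distinct retained interactors and the sum of
#' retained edge scores.  Genes retaining no edge are omitted.
#'
#' @param edges PPI edge data.frame (canonicalised internally).
#' @param members character vector of genes defining the network.
#' @param threshold minimum confidence, strict (default 0.4).
#' @return data.frame: `gene`, `n_nodes`, `total_score`, `mean_score`.
#' @export
node_scores <- function(edges, members, threshold = 0.4) {
  e <- canonical_edges(edges)
  e <- e[e$gene_a %in% members & e$gene_b %in% members &
           e$combined_score > threshold, , drop = FALSE]
  long <- rbind(data.frame(gene = e$gene_a, partner = e$gene_b,
                           score = e$combined_score),
                data.frame(gene = e$gene_b, partner = e$gene_a,
                           score = e$combined_score))
  if (nrow(long) == 0) {
    return(data.frame(gene = character(0), n_nodes = integer(0),
                      total_score = numeric(0), mean_score = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(long, long$gene), function(d) {
    data.frame(gene = d$gene[1],
               n_nodes = length(unique(d$partner)),
               total_score = sum(d$score))
  }))
  out$mean_score <- out$total_score / out$n_nodes
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine two network constructions into one ranking
#'
#' Averages each gene's total score and node count across the two network
#' constructions; a gene absent from one construction contributes zero for
#' that construction but the average still divides by two (so a
#' single-construction gene scores half its single total).  Ranked by
#' combined total descending, ties by combined nodes then symbol.
#'
#' @param g1,g2 data.frames from [node_scores()] for the two constructions.
#' @return data.frame: `gene`, `n_nodes_1`, `total_score_1`, `mean_score_1`,
#'   `n_nodes_2`, `total_score_2`, `mean_score_2` (NA where absent),
#'   `combined_total`, `combined_nodes`, `rank`.
#' @export
combine_groups <- function(g1, g2) {
  genes <- sort(union(g1$gene, g2$gene))
  i1 <- match(genes, g1$gene)
  i2 <- match(genes, g2$gene)
  t1 <- ifelse(is.na(i1), 0, g1$total_score[i1])
  t2 <- ifelse(is.na(i2), 0, g2$total_score[i2])
  n1 <- ifelse(is.na(i1), 0, g1$n_nodes[i1])
  n2 <- ifelse(is.na(i2), 0, g2$n_nodes[i2])
  out <- data.frame(
    gene = genes,
    n_nodes_1 = g1$n_nodes[i1], total_score_1 = g1$total_score[i1],
    mean_score_1 = g1$mean_score[i1],
    n_nodes_2 = g2$n_nodes[i2], total_score_2 = g2$total_score[i2],
    mean_score_2 = g2$mean_score[i2],
    combined_total = (t1 + t2) / 2,
    combined_nodes = (n1 + n2) / 2)
  out <- out[order(-out$combined_total, -out$combined_nodes, out$gene), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top-ranked candidate genes with burden evidence attached
#'
#' Takes the top `k` genes of a combined PPI ranking and attaches each
#' gene's best burden-test evidence (minimum p across strata) plus a flag
#' for membership in the reference gene panel (reference genes can enter the
#' ranking through the network even when their burden p is not significant).
#'
#' @param ranked data.frame from [combine_groups()].
#' @param burden_results data.frame from [gene_burden()] (optional).
#' @param k number of genes to report (default 10).
#' @param reference_genes character vector of reference-panel symbols
#'   (optional).
#' @return data.frame: ranking columns plus `burden_p`, `burden_stratum`,
#'   `in_reference_panel`.
#' @export
prioritize <- function(ranked, burden_results = NULL, k = 10,
                       reference_genes = character(0)) {
  top <- utils::head(ranked, k)
  if (nrow(top) == 0) return(top)
  top$burden_p <- NA_real_
  top$burden_stratum <- NA_character_
  if (!is.null(burden_results) && nrow(burden_results) > 0) {
    for (i in seq_len(nrow(top))) {
      rows <- burden_results[burden_results$gene == top$gene[i], ,
                             drop = FALSE]
      if (nrow(rows) > 0) {
        best <- which.min(rows$p_value)
        top$burden_p[i] <- rows$p_value[best]
        top$burden_stratum[i] <- rows$stratum[best]
      }
    }
  }
  top$in_reference_panel <- top$gene %in% reference_genes
  top
}
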