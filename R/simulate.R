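#' Configuration for the synthetic WES cohort generator
#'
#' Defines the statistical structure of a simulated case-control exome
#' cohort: sample sizes, a gene panel with per-gene rare-site counts, a
#' reference-panel allele-frequency spectrum, planted per-gene carrier odds
#' ratios, pathway membership, and PPI edge structure.  The defaults emulate
#' the study design the pipeline targets: 82 cases vs 100 controls over a
#' rare-variant candidate panel of 40 genes whose sites are drawn from a
#' rare-skewed AF spectrum on \[0, 0.05\].
#'
#' @param n_cases,n_controls positive sample counts (defaults 82 / 100).
#' @param genes data.frame with columns `gene`, `n_sites`; default 40 genes
#'   with 2-8 rare sites each.
#' @param maf_spectrum function(n) returning n allele frequencies in
#'   \[0, 0.05\]; default `0.05 * rbeta(n, 0.3, 12)` (rare-skewed, median
#'   cohort carrier probability around 1 percent).
#' @param deleterious_fraction proportion of sites drawn from the
#'   deleterious functional classes (default 0.8; the first site of every
#'   gene is always deleterious so each gene is collapsible).
#' @param planted_or named numeric vector, gene -> carrier odds ratio
#'   (1 = null; must be > 0).
#' @param carrier_p0 optional named numeric vector, gene -> control-group
#'   carrier probability, overriding the value implied by the gene's site
#'   frequencies; used for calibration and power studies where the carrier
#'   rate must be held exactly.
#' @param n_common_variants common biallelic markers simulated under the
#'   null for the single-variant scan (default 2000).
#' @param common_af_range AF range for common markers (default 0.05-0.5).
#' @param pathway_config list: `n_sets`, `min_size`, `max_size`,
#'   `background_size` (filler symbols beyond the cohort genes),
#'   `planted_genes` (genes forced together into the first set).
#' @param ppi_config list: `edge_density` in (0,1\], `score_fn` function(n)
#'   returning scores in \[0, 1\].
#' @param missing_genotype_rate fraction of genotype calls set missing
#'   (default 0).
#' @param missing_af_rate fraction of panel AF entries set missing, to
#'   exercise the absent-in-panel rarity rule (default 0.1).
#' @param external_fraction fraction of case-carried deleterious variants
#'   echoed into the external validation table (default 0.3).
#' @param seed integer seed; all stochastic draws flow from it.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_cases = 82, n_controls = 100,
                              genes = default_gene_panel(),
                              maf_spectrum = function(n) 0.05 * stats::rbeta(n, 0.3, 12),
                              deleterious_fraction = 0.8,
                              planted_or = numeric(0),
                              carrier_p0 = numeric(0),
                              n_common_variants = 2000,
                              common_af_range = c(0.05, 0.5),
                              pathway_config = list(n_sets = 15, min_size = 5,
                                                    max_size = 40,
                                                    background_size = 300,
                                                    planted_genes = character(0)),
                              ppi_config = list(edge_density = 0.08,
                                                score_fn = stats::runif),
                              missing_genotype_rate = 0,
                              missing_af_rate = 0.1,
                              external_fraction = 0.3,
                              seed = 1) {
  stopifnot(is.data.frame(genes), all(c("gene", "n_sites") %in% names(genes)))
  if (n_cases <= 0 || n_controls <= 0) stop("sample counts must be positive")
  if (nrow(genes) == 0) stop("gene panel must be non-empty")
  if (any(planted_or <= 0)) stop("planted odds ratios must be > 0")
  if (length(planted_or) > 0 && is.null(names(planted_or))) {
    stop("planted_or must be a named vector (gene -> odds ratio)")
  }
  if (length(carrier_p0) > 0 &&
      (is.null(names(carrier_p0)) || any(carrier_p0 <= 0 | carrier_p0 >= 1))) {
    stop("carrier_p0 must be a named vector with values in (0, 1)")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 genes = genes, maf_spectrum = maf_spectrum,
                 deleterious_fraction = deleterious_fraction,
                 planted_or = planted_or, carrier_p0 = carrier_p0,
                 n_common_variants = as.integer(n_common_variants),
                 common_af_range = common_af_range,
                 pathway_config = pathway_config,
                 ppi_config = ppi_config,
                 missing_genotype_rate = missing_genotype_rate,
                 missing_af_rate = missing_af_rate,
                 external_fraction = external_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default synthetic gene panel
#'
#' 40 genes (`GENE01` ... `GENE40`) with 2-8 rare sites each, the scale of a
#' curated arrhythmia candidate panel.
#'
#' @param n_genes number of genes.
#' @return data.frame with `gene`, `n_sites`.
#' @export
default_gene_panel <- function(n_genes = 40) {
  data.frame(gene = sprintf("GENE%02d", seq_len(n_genes)),
             n_sites = rep(2:8, length.out = n_genes))
}

# Tilt a control-group carrier probability to the case group on the
# carrier/non-carrier odds scale.
tilt_carrier_prob <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Simulate a synthetic case-control WES cohort bundle
#'
#' Generates annotated rare variants over the configured gene panel, common
#' null markers, per-sample genotypes with case carrier probabilities tilted
#' to the planted odds ratios, pathway gene sets, PPI edges, an external
#' validation variant table, and a truth ledger of the planted effects.
#'
#' The carrier model is gene-level: a control sample carries a qualifying
#' allele in gene *g* with probability
#' \eqn{p_0 = 1 - \prod_s (1 - f_s)^2} over the gene's deleterious site
#' frequencies \eqn{f_s}; the case probability is the odds-scale tilt of
#' \eqn{p_0} by the planted odds ratio.  A carrier is assigned one
#' heterozygous deleterious site (AF-weighted); non-deleterious and common
#' sites receive Hardy-Weinberg genotypes independent of status.
#'
#' @param config a [simulation_config()].
#' @return List of class `synthetic_bundle`: `variants` (annotation
#'   data.frame), `genotypes` (list `sample_ids`, `status`, `dosage`),
#'   `gene_sets`, `ppi_edges`, `external_table`, `truth`, `config_seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  status <- factor(rep(c("case", "control"),
                       c(config$n_cases, config$n_controls)),
                   levels = c("case", "control"))
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## ---- rare panel variants -------------------------------------------
  genes <- config$genes
  gene_of_site <- rep(genes$gene, genes$n_sites)
  n_rare <- length(gene_of_site)
  chrom <- as.character(((match(gene_of_site, genes$gene) - 1) %% 22) + 1)
  pos <- integer(n_rare)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(5e7, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_rare, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  first_site <- !duplicated(gene_of_site)
  deleterious <- first_site |
    stats::runif(n_rare) < config$deleterious_fraction
  functional_class <- ifelse(
    deleterious,
    sample(c("missense", "nonsense", "splice_site", "frameshift",
             "inframe_indel"), n_rare, replace = TRUE,
           prob = c(0.7, 0.08, 0.08, 0.08, 0.06)),
    sample(c("synonymous", "intron", "utr"), n_rare, replace = TRUE,
           prob = c(0.4, 0.5, 0.1)))
  cohort_af <- pmin(pmax(config$maf_spectrum(n_rare), 1e-4), 0.05)
  # reference-panel AFs drawn independently of the cohort AFs
  af_exac <- round(pmin(pmax(config$maf_spectrum(n_rare), 0), 0.05), 6)
  af_kg <- round(pmin(pmax(config$maf_spectrum(n_rare), 0), 0.05), 6)
  af_exac[stats::runif(n_rare) < config$missing_af_rate] <- NA
  af_kg[stats::runif(n_rare) < config$missing_af_rate] <- NA
  aa3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
           "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
           "Tyr", "Val")
  cpos <- sample.int(9000, n_rare, replace = TRUE)
  hgvs_c <- sprintf("c.%d%s>%s", cpos, ref, alt)
  hgvs_p <- rep("", n_rare)
  prot <- functional_class %in% c("missense", "nonsense")
  hgvs_p[prot] <- sprintf("p.%s%d%s", sample(aa3, sum(prot), replace = TRUE),
                          ceiling(cpos[prot] / 3),
                          ifelse(functional_class[prot] == "nonsense", "Ter",
                                 sample(aa3, sum(prot), replace = TRUE)))
  hgvs_p[functional_class == "frameshift"] <-
    sprintf("p.%s%dfs", sample(aa3, sum(functional_class == "frameshift"),
                               replace = TRUE),
            ceiling(cpos[functional_class == "frameshift"] / 3))
  key <- paste(chrom, pos, ref, alt, sep = ":")
  rare_variants <- data.frame(
    key = key, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene_of_site, functional_class = functional_class,
    hgvs_c = hgvs_c, hgvs_p = hgvs_p,
    af_exac = af_exac, af_kg = af_kg, stringsAsFactors = FALSE)

  ## ---- genotypes for rare variants -----------------------------------
  dosage <- matrix(0L, nrow = n, ncol = n_rare,
                   dimnames = list(sample_ids, key))
  truth_rows <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene[gi]
    sites <- which(gene_of_site == g)
    del_sites <- sites[deleterious[sites]]
    afd <- cohort_af[del_sites]
    p0 <- if (g %in% names(config$carrier_p0)) {
      config$carrier_p0[[g]]
    } else {
      min(max(1 - prod((1 - afd)^2), 1e-4), 0.95)
    }
    or <- if (g %in% names(config$planted_or)) config$planted_or[[g]] else 1
    p1 <- tilt_carrier_prob(p0, or)
    p_carrier <- ifelse(status == "case", p1, p0)
    carrier <- stats::runif(n) < p_carrier
    if (any(carrier)) {
      assigned <- if (length(del_sites) == 1) {
        rep(del_sites, sum(carrier))
      } else {
        sample(del_sites, sum(carrier), replace = TRUE, prob = afd)
      }
      dosage[cbind(which(carrier), assigned)] <- 1L
    }
    # non-deleterious sites: HWE genotypes independent of status
    for (s in sites[!deleterious[sites]]) {
      dosage[, s] <- stats::rbinom(n, 2, cohort_af[s])
    }
    truth_rows[[g]] <- data.frame(
      gene = g, planted_or = or, p_carrier_controls = p0,
      p_carrier_cases = p1, n_sites = length(sites),
      n_deleterious_sites = length(del_sites))
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  ## ---- common null markers for the single-variant scan ---------------
  if (config$n_common_variants > 0) {
    m <- config$n_common_variants
    c_chrom <- as.character(sample.int(22, m, replace = TRUE))
    c_pos <- integer(m)
    for (ch in unique(c_chrom)) {
      idx <- which(c_chrom == ch)
      c_pos[idx] <- sort(sample(5e7:9e7, length(idx)))
    }
    c_ref <- sample(bases, m, replace = TRUE)
    c_alt <- vapply(c_ref, function(r) sample(setdiff(bases, r), 1),
                    character(1))
    c_af <- stats::runif(m, config$common_af_range[1],
                         config$common_af_range[2])
    c_key <- paste(c_chrom, c_pos, c_ref, c_alt, sep = ":")
    # common markers are annotated to filler background genes
    bg_genes <- sprintf("BG%04d", seq_len(config$pathway_config$background_size))
    c_gene <- bg_genes[((seq_len(m) - 1) %% length(bg_genes)) + 1]
    c_cpos <- sample.int(9000, m, replace = TRUE)
    common_variants <- data.frame(
      key = c_key, chrom = c_chrom, pos = c_pos, ref = c_ref, alt = c_alt,
      gene = c_gene, functional_class = "intron",
      hgvs_c = sprintf("c.%d+%d%s>%s", c_cpos,
                       sample.int(500, m, replace = TRUE), c_ref, c_alt),
      hgvs_p = "", af_exac = round(c_af, 4), af_kg = round(c_af, 4),
      stringsAsFactors = FALSE)
    c_dosage <- matrix(stats::rbinom(n * m, 2, rep(c_af, each = n)),
                       nrow = n, dimnames = list(sample_ids, c_key))
    variants <- rbind(rare_variants, common_variants)
    dosage <- cbind(dosage, c_dosage)
  } else {
    variants <- rare_variants
  }

  if (config$missing_genotype_rate > 0) {
    drop <- stats::runif(length(dosage)) < config$missing_genotype_rate
    dosage[drop] <- NA_integer_
  }

  ## ---- pathway gene sets ---------------------------------------------
  pc <- config$pathway_config
  universe <- c(genes$gene,
                sprintf("BG%04d", seq_len(pc$background_size)))
  sets <- list()
  for (si in seq_len(pc$n_sets)) {
    size <- sample(pc$min_size:pc$max_size, 1)
    members <- sample(universe, size)
    if (si == 1 && length(pc$planted_genes) > 0) {
      members <- unique(c(pc$planted_genes, members))[seq_len(max(size, length(pc$planted_genes)))]
    }
    sets[[sprintf("SET%03d", si)]] <- sort(unique(members))
  }
  gene_sets <- list(sets = sets,
                    description = stats::setNames(
                      sprintf("synthetic pathway %d", seq_len(pc$n_sets)),
                      names(sets)))

  ## ---- PPI edges ------------------------------------------------------
  ppic <- config$ppi_config
  pairs <- utils::combn(universe[seq_len(min(length(universe), 120))], 2)
  pick <- stats::runif(ncol(pairs)) < ppic$edge_density
  ppi_edges <- data.frame(gene_a = pairs[1, pick], gene_b = pairs[2, pick],
                          combined_score = round(ppic$score_fn(sum(pick)), 3),
                          stringsAsFactors = FALSE)
  ppi_edges <- canonical_edges(ppi_edges)

  ## ---- external validation table -------------------------------------
  case_rows <- which(status == "case")
  carried <- colSums(dosage[case_rows, seq_len(n_rare), drop = FALSE] >= 1,
                     na.rm = TRUE) > 0
  cand <- which(carried & deleterious)
  n_ext <- round(length(cand) * config$external_fraction)
  ext_idx <- if (n_ext > 0) sort(sample(cand, n_ext)) else integer(0)
  external_table <- data.frame(
    gene = rare_variants$gene[ext_idx],
    hgvs_c = rare_variants$hgvs_c[ext_idx],
    hgvs_p = rare_variants$hgvs_p[ext_idx],
    cohort_label = rep("replication_cohort", length(ext_idx)),
    mac = colSums(dosage[, ext_idx, drop = FALSE] > 0, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(external_table) <- NULL

  structure(list(variants = variants,
                 genotypes = list(sample_ids = sample_ids, status = status,
                                  dosage = dosage),
                 gene_sets = gene_sets, ppi_edges = ppi_edges,
                 external_table = external_table, truth = truth,
                 config_seed = config$seed),
            class = "synthetic_bundle")
}
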