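#' Write a synthetic bundle to a directory of standard files
#'
#' Emits `cohort.vcf` (minimal VCF 4.2 with GT genotypes),
#' `annotations.tsv`, `phenotypes.tsv`, `gene_sets.gmt`, `ppi_edges.tsv`,
#' `external_variants.tsv` and `truth.tsv`, all of which round-trip through
#' [read_bundle()].
#'
#' @param bundle a `synthetic_bundle` from [simulate_cohort()].
#' @param directory output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- c(vcf = file.path(directory, "cohort.vcf"),
             annotations = file.path(directory, "annotations.tsv"),
             phenotypes = file.path(directory, "phenotypes.tsv"),
             gmt = file.path(directory, "gene_sets.gmt"),
             ppi = file.path(directory, "ppi_edges.tsv"),
             external = file.path(directory, "external_variants.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_minimal_vcf(bundle$variants, bundle$genotypes, paths["vcf"])
  ann <- bundle$variants[, c("key", "gene", "functional_class", "hgvs_c",
                             "hgvs_p", "af_exac", "af_kg")]
  for (col in c("af_exac", "af_kg")) {
    ann[[col]] <- ifelse(is.na(ann[[col]]), ".", as.character(ann[[col]]))
  }
  utils::write.table(ann, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = bundle$genotypes$sample_ids,
               status = as.character(bundle$genotypes$status)),
    paths["phenotypes"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(bundle$gene_sets, paths["gmt"])
  utils::write.table(bundle$ppi_edges, paths["ppi"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$external_table, paths["external"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Minimal VCF 4.2 writer: one row per alternate allele, GT-only FORMAT,
# records in coordinate order (numeric chromosome sort where possible).
write_minimal_vcf <- function(variants, genotypes, path) {
  ord <- order(suppressWarnings(as.numeric(variants$chrom)), variants$chrom,
               variants$pos, variants$ref, variants$alt, na.last = TRUE)
  v <- variants[ord, , drop = FALSE]
  dos <- genotypes$dosage[, v$key, drop = FALSE]
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow = nrow(dos))
  gt[is.na(dos)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$sample_ids),
                    collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$key, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

#' Read a cohort from VCF + annotation + phenotype files
#'
#' Parses a (minimal, GT-only) VCF 4.2 file, splitting multi-allelic records
#' into one variant per alternate allele with per-allele dosages, joins the
#' annotation table by variant key (`chrom:pos:ref:alt`), and attaches
#' case/control labels from the phenotype table.
#'
#' @param vcf_path VCF file.
#' @param annotation_path annotation TSV (`key`, `gene`, `functional_class`,
#'   `hgvs_c`, `hgvs_p`, `af_*` panel columns; "." = missing AF).
#' @param phenotype_path phenotype TSV (`sample_id`, `status`).
#' @return List with `variants` (annotation data.frame incl. coordinates)
#'   and `genotypes` (`sample_ids`, `status`, `dosage`).
#' @export
read_cohort <- function(vcf_path, annotation_path, phenotype_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  sample_ids <- colnames(gt_raw)[-1]
  gt_idx <- vapply(strsplit(gt_raw[, "FORMAT"], ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (any(is.na(gt_idx))) stop("VCF record without GT field")
  rows <- list()
  dos_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    raw <- gt_raw[i, -1]
    gts <- rep(NA_character_, length(raw))
    ok <- !is.na(raw)
    gts[ok] <- vapply(strsplit(raw[ok], ":", fixed = TRUE),
                      function(x) x[gt_idx[i]], character(1))
    gts[gts %in% c(".", "./.", ".|.")] <- NA    # missing call
    alleles <- strsplit(gts, "[/|]")
    bad <- !is.na(gts) & lengths(alleles) != 2
    if (any(bad)) stop("malformed genotype in VCF record ", fix$ID[i])
    alleles[is.na(gts)] <- list(c(".", "."))
    for (k in seq_along(alts)) {
      dose <- vapply(alleles, function(al) {
        if (any(al == ".")) return(NA_integer_)
        sum(al == as.character(k))
      }, integer(1))
      key <- paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[k], sep = ":")
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], stringsAsFactors = FALSE)
      dos_rows[[length(dos_rows) + 1L]] <- dose
    }
  }
  coords <- do.call(rbind, rows)
  if (anyDuplicated(coords$key)) {
    stop("duplicate variant key(s) in VCF: ",
         paste(utils::head(coords$key[duplicated(coords$key)], 3),
               collapse = ", "))
  }
  dosage <- do.call(cbind, dos_rows)
  dimnames(dosage) <- list(sample_ids, coords$key)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  af_cols <- grep("^af_", names(ann), value = TRUE)
  for (col in af_cols) {
    ann[[col]] <- suppressWarnings(
      as.numeric(ifelse(ann[[col]] %in% c(".", ""), NA, ann[[col]])))
  }
  variants <- merge(coords, ann, by = "key", sort = FALSE)
  variants <- variants[match(coords$key, variants$key), , drop = FALSE]
  rownames(variants) <- NULL
  phen <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  if (!setequal(phen$sample_id, sample_ids)) {
    stop("phenotype samples do not match VCF sample columns")
  }
  status <- factor(phen$status[match(sample_ids, phen$sample_id)],
                   levels = c("case", "control"))
  list(variants = variants,
       genotypes = list(sample_ids = sample_ids, status = status,
                        dosage = dosage))
}

#' Read a GMT gene-set file
#'
#' Sets are parsed with [fgsea::gmtPathways()]; the description column
#' (field 2) is recovered separately so it survives a round trip.
#'
#' @param path GMT file.
#' @return List with `sets` (named list of symbol vectors) and
#'   `description` (named character vector).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lines <- readLines(path)
  desc <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 2)
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  list(sets = sets, description = stats::setNames(desc, ids)[names(sets)])
}

#' Write a GMT gene-set file
#'
#' @param gene_sets list with `sets` and `description` as in [read_gmt()].
#' @param path output file.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets$sets), function(id) {
    paste(c(id, unname(gene_sets$description[id]), gene_sets$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a weighted PPI edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `combined_score`.
#' @return Canonicalised edge data.frame (see [canonical_edges()]).
#' @export
read_ppi_edges <- function(path) {
  canonical_edges(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read an external validation variant table
#'
#' @param path TSV with at least `gene`, `hgvs_c`, `hgvs_p`,
#'   `cohort_label`; other columns pass through.
#' @return data.frame.
#' @export
read_external_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file.
#' @return Character vector (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[x != ""]
}

#' Read a previously written bundle back from disk
#'
#' Inverse of [write_bundle()] for every field the pipeline consumes.
#'
#' @param directory directory written by [write_bundle()].
#' @return List with the same components as a `synthetic_bundle`.
#' @export
read_bundle <- function(directory) {
  cohort <- read_cohort(file.path(directory, "cohort.vcf"),
                        file.path(directory, "annotations.tsv"),
                        file.path(directory, "phenotypes.tsv"))
  truth <- utils::read.delim(file.path(directory, "truth.tsv"),
                             stringsAsFactors = FALSE)
  structure(list(variants = cohort$variants,
                 genotypes = cohort$genotypes,
                 gene_sets = read_gmt(file.path(directory, "gene_sets.gmt")),
                 ppi_edges = read_ppi_edges(file.path(directory,
                                                      "ppi_edges.tsv")),
                 external_table = read_external_table(
                   file.path(directory, "external_variants.tsv")),
                 truth = truth),
            class = "synthetic_bundle")
}
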