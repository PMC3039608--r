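# Plain-text interchange: study-record TSV, association-summary TSV,
# genotype VCF (with sample-map and SNP-info sidecars) and dense dosage TSV.
# Positions are 0-based internally and converted to 1-based VCF coordinates
# on write (and back on read).

#' Write / read study records as TSV
#'
#' Columns: `record_id`, `gene`, `disease`, `outcome` (Y/N),
#' `ancestry_label`, `sample_size`, `year`, `marker_id`.
#'
#' @param records Study-record data frame.
#' @param path File path.
#' @return `read_study_records` returns the records data frame;
#'   `write_study_records` returns `path` invisibly.
#' @export
write_study_records <- function(records, path) {
  cols <- c("record_id", "gene", "disease", "outcome", "ancestry_label",
            "sample_size", "year", "marker_id")
  stopifnot(all(cols %in% names(records)))
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_records
#' @export
read_study_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(record_id = "character",
                                   gene = "character",
                                   disease = "character",
                                   outcome = "character",
                                   ancestry_label = "character",
                                   marker_id = "character"))
}

#' Write / read association summaries as TSV
#'
#' Round-trip safe for the Global- and Continental-Set summary frames
#' (numeric columns are written at full precision).
#'
#' @param summaries Association-summary data frame.
#' @param path File path.
#' @export
write_association_summaries <- function(summaries, path) {
  utils::write.table(format(summaries, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_summaries
#' @export
read_association_summaries <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene = "character", disease = "character"))
}

#' Write a genotype table as VCF plus sidecar TSVs
#'
#' Emits a minimal VCF 4.2 (GT-only, one sample column per individual;
#' REF = ancestral allele, ALT = derived allele, 1-based positions), a
#' two-column sample map (`sample_id`, `population`) and a SNP-info sidecar
#' (`snp_id`, `gene`, `pos`, `annotation`, `anc_allele`, `der_allele`,
#' `outgroup1`, `outgroup2`) carrying what VCF INFO fields would in a
#' production pipeline.
#'
#' @param gt A [genotype_table()].
#' @param vcf_path,sample_map_path,snp_info_path Output file paths.
#' @return `vcf_path`, invisibly.
#' @export
write_genotypes_vcf <- function(gt, vcf_path, sample_map_path, snp_info_path) {
  stopifnot(inherits(gt, "genotype_table"))
  gt_codes <- c("0/0", "0/1", "1/1")
  gm <- matrix("./.", nrow(gt$dosage), ncol(gt$dosage))
  known <- !is.na(gt$dosage)
  gm[known] <- gt_codes[gt$dosage[known] + 1L]
  body <- paste(
    "1", gt$snps$pos + 1L, gt$snps$snp_id,
    gt$snps$anc_allele, gt$snps$der_allele, ".", "PASS", ".", "GT",
    apply(gm, 1L, paste, collapse = "\t"),
    sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gt$samples$sample_id), collapse = "\t"))
  writeLines(c(header, body), vcf_path)
  utils::write.table(gt$samples, sample_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  info_cols <- intersect(c("snp_id", "gene", "pos", "annotation",
                           "anc_allele", "der_allele", "outgroup1",
                           "outgroup2"), names(gt$snps))
  utils::write.table(gt$snps[, info_cols], snp_info_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Read a genotype table from VCF plus sidecar TSVs
#'
#' Only biallelic SNP records are used; multiallelic records are skipped
#' with a warning. Dosages count ALT (derived) alleles in the GT field;
#' positions are converted to the internal 0-based convention.
#'
#' @param vcf_path VCF file (plain text) as written by
#'   [write_genotypes_vcf()] or any GT-bearing biallelic SNP VCF.
#' @param sample_map_path Two-column TSV `sample_id`, `population`.
#' @param snp_info_path Optional SNP-info sidecar TSV; when absent, gene and
#'   annotation columns are filled from the VCF only (`gene = NA`).
#' @return A [genotype_table()].
#' @export
read_genotypes_vcf <- function(vcf_path, sample_map_path,
                               snp_info_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    warning("skipping ", sum(multi), " non-biallelic-SNP records")
  }
  gtm <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(al) {
             sum(al == "1")
           }, integer(1)))
  }
  dosage <- apply(gtm, 2L, count_alt)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = nrow(fix))

  samples <- utils::read.delim(sample_map_path, stringsAsFactors = FALSE)
  stopifnot(all(colnames(gtm) == samples$sample_id))
  snps <- data.frame(snp_id = fix$ID, gene = NA_character_,
                     pos = as.integer(fix$POS) - 1L,
                     anc_allele = fix$REF, der_allele = fix$ALT,
                     stringsAsFactors = FALSE)
  if (!is.null(snp_info_path)) {
    info <- utils::read.delim(snp_info_path, stringsAsFactors = FALSE)
    m <- match(snps$snp_id, info$snp_id)
    for (col in setdiff(names(info), c("snp_id", "pos"))) {
      snps[[col]] <- info[[col]][m]
    }
  }
  genotype_table(dosage, samples, snps)
}

#' Write / read a dense dosage matrix as TSV
#'
#' First column `snp_id`, then one column per sample; missing calls written
#' as `NA`. The sample map travels in the same sidecar format as for VCF.
#'
#' @param gt A [genotype_table()].
#' @param path Dosage TSV path.
#' @param sample_map_path,snp_info_path Sidecar paths (as in
#'   [write_genotypes_vcf()]).
#' @export
write_dosage_tsv <- function(gt, path, sample_map_path, snp_info_path) {
  stopifnot(inherits(gt, "genotype_table"))
  df <- cbind(data.frame(snp_id = gt$snps$snp_id, stringsAsFactors = FALSE),
              as.data.frame(gt$dosage))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gt$samples, sample_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  info_cols <- intersect(c("snp_id", "gene", "pos", "annotation",
                           "anc_allele", "der_allele", "outgroup1",
                           "outgroup2"), names(gt$snps))
  utils::write.table(gt$snps[, info_cols], snp_info_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path, sample_map_path, snp_info_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- utils::read.delim(sample_map_path, stringsAsFactors = FALSE)
  info <- utils::read.delim(snp_info_path, stringsAsFactors = FALSE)
  dosage <- as.matrix(df[, samples$sample_id, drop = FALSE])
  m <- match(df$snp_id, info$snp_id)
  genotype_table(dosage, samples, info[m, , drop = FALSE])
}
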