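#' Genotype table container
#'
#' Bundles a SNP-by-sample diploid dosage matrix with its sample-to-population
#' map and per-SNP metadata (gene, position, annotation class, ancestral and
#' derived alleles, outgroup alleles from two species). Dosages count copies
#' of the derived allele (0, 1, 2) with `NA` for missing calls. Positions are
#' 0-based internally; VCF input/output converts at the boundary.
#'
#' @param dosage Integer matrix, SNPs in rows, samples in columns; entries in
#'   `{0, 1, 2, NA}`. Row names are SNP IDs, column names sample IDs.
#' @param samples Data frame with columns `sample_id`, `population`; one row
#'   per dosage column, in column order.
#' @param snps Data frame with one row per dosage row, containing at least
#'   `snp_id`, `gene`, `pos`; optionally `annotation`, `anc_allele`,
#'   `der_allele`, `outgroup1`, `outgroup2`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(dosage, samples, snps) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(
    is.data.frame(samples), all(c("sample_id", "population") %in% names(samples)),
    is.data.frame(snps), all(c("snp_id", "gene", "pos") %in% names(snps)),
    nrow(samples) == ncol(dosage),
    nrow(snps) == nrow(dosage)
  )
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample IDs")
  if (anyDuplicated(snps$snp_id)) stop("duplicated SNP IDs")
  rownames(dosage) <- snps$snp_id
  colnames(dosage) <- samples$sample_id
  structure(list(dosage = dosage, samples = samples, snps = snps),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  tab <- table(x$samples$population)
  cat("Genotype table:", nrow(x$dosage), "SNPs x", ncol(x$dosage),
      "samples in", length(tab), "populations\n")
  cat("  populations:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  cat("  genes:", length(unique(x$snps$gene)),
      " missing calls:", sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "\n")
  invisible(x)
}

#' Subset a genotype table
#'
#' @param gt A [genotype_table()].
#' @param snp_ids Optional character vector of SNP IDs to keep.
#' @param populations Optional character vector of population labels to keep.
#' @return A `genotype_table` restricted to the requested SNPs/populations.
#' @export
subset_genotypes <- function(gt, snp_ids = NULL, populations = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  ri <- if (is.null(snp_ids)) seq_len(nrow(gt$dosage)) else {
    m <- match(snp_ids, gt$snps$snp_id)
    if (anyNA(m)) stop("unknown SNP IDs: ", paste(snp_ids[is.na(m)], collapse = ", "))
    m
  }
  ci <- if (is.null(populations)) seq_len(ncol(gt$dosage)) else {
    which(gt$samples$population %in% populations)
  }
  genotype_table(gt$dosage[ri, ci, drop = FALSE],
                 gt$samples[ci, , drop = FALSE],
                 gt$snps[ri, , drop = FALSE])
}
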