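# Population-differentiation statistics: per-SNP allele frequencies,
# the Weir-Cockerham variance-components FST estimator on allele counts,
# gene-level aggregation, the extreme-frequency statistic, and ancestral /
# derived classification of the major allele by outgroup parsimony.

#' Per-population derived-allele frequencies and allele counts
#'
#' @param gt A [genotype_table()].
#' @param populations Optional subset of population labels.
#' @return A list with two SNP-by-population matrices: `freq` (derived-allele
#'   frequency, `NaN` where a population has no non-missing call) and `n`
#'   (number of sampled alleles, i.e. 2 x non-missing diploids).
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 2, n_associations = 1,
#'                                   snps_per_gene = c(3, 3)))
#' af <- allele_frequencies(ds$genotypes)
#' head(af$freq)
#' @export
allele_frequencies <- function(gt, populations = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  pops <- if (is.null(populations)) unique(gt$samples$population) else populations
  freq <- n <- matrix(NA_real_, nrow(gt$dosage), length(pops),
                      dimnames = list(gt$snps$snp_id, pops))
  for (j in seq_along(pops)) {
    block <- gt$dosage[, gt$samples$population == pops[j], drop = FALSE]
    if (ncol(block) == 0L) stop("population not present: ", pops[j])
    n[, j] <- 2 * rowSums(!is.na(block))
    freq[, j] <- rowSums(block, na.rm = TRUE) / n[, j]
  }
  list(freq = freq, n = n)
}

#' Weir--Cockerham FST estimator (allele-count form)
#'
#' Method-of-moments variance-components estimator of FST (theta) for one or
#' more biallelic SNPs typed in `r >= 2` populations, computed from sampled
#' allele counts `n_i` and derived-allele frequencies `p_i`. With
#' `nbar = sum(n_i)/r`, `nc = (sum(n_i) - sum(n_i^2)/sum(n_i))/(r-1)`,
#' `pbar = sum(n_i p_i)/sum(n_i)` and
#' `s2 = sum(n_i (p_i - pbar)^2)/((r-1) nbar)`, the among- and
#' within-population components are
#' `a = (nbar/nc) * (s2 - (pbar(1-pbar) - s2 (r-1)/r) / (nbar-1))` and
#' `b = (nbar/(nbar-1)) * (pbar(1-pbar) - s2 (r-1)/r)`, and
#' `theta = a / (a + b)`. Negative estimates are retained, not clamped:
#' clamping would bias gene-level means upward. SNPs monomorphic in the
#' pooled sample have no defined theta and return `NA`.
#'
#' @param p Numeric vector (one SNP) or SNP-by-population matrix of
#'   derived-allele frequencies.
#' @param n Matching vector/matrix of sampled allele counts per population.
#' @return Numeric vector of theta estimates (length 1 for vector input),
#'   `NA` where undefined.
#' @examples
#' fst_wc(c(1, 0), c(120, 120))   # fixed difference: exactly 1
#' fst_wc(c(0.5, 0.5), c(120, 120)) # identical frequencies: <= 0
#' @export
fst_wc <- function(p, n) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (is.null(dim(n))) n <- matrix(n, nrow = 1)
  stopifnot(all(dim(p) == dim(n)))
  if (ncol(p) < 2L) stop("at least two populations are required")
  if (any(n[!is.na(n)] < 0)) stop("allele counts must be non-negative")

  valid <- !is.na(p) & !is.na(n) & n > 0
  n <- ifelse(valid, n, 0)
  p <- ifelse(valid, p, 0)
  r <- rowSums(valid)

  sumn <- rowSums(n)
  nbar <- sumn / r
  nc <- (sumn - rowSums(n^2) / sumn) / (r - 1)
  pbar <- rowSums(n * p) / sumn
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  h <- pbar * (1 - pbar) - s2 * (r - 1) / r
  a <- (nbar / nc) * (s2 - h / (nbar - 1))
  b <- (nbar / (nbar - 1)) * h
  theta <- a / (a + b)

  bad <- r < 2 | pbar <= 0 | pbar >= 1 | nbar <= 1 | !is.finite(theta)
  theta[bad] <- NA_real_
  out <- as.numeric(theta)
  names(out) <- rownames(p)
  out
}

#' Per-SNP FST for a set of populations
#'
#' Convenience wrapper: computes allele frequencies in the requested
#' populations and the Weir--Cockerham theta per SNP. Pass two labels for a
#' pairwise FST or all labels for the global (multi-population) value.
#'
#' @param gt A [genotype_table()].
#' @param populations Character vector of population labels (default: all).
#' @return Named numeric vector of per-SNP theta (`NA` where undefined).
#' @export
snp_fst <- function(gt, populations = NULL) {
  af <- allele_frequencies(gt, populations)
  fst_wc(af$freq, af$n)
}

#' Multi-locus Weir--Cockerham estimate (ratio of sums)
#'
#' The classical multi-locus combination `sum(a_l) / sum(a_l + b_l)` over
#' loci, which is nearly unbiased where the arithmetic mean of per-SNP
#' ratios is pulled down by low-information SNPs. Provided for comparison;
#' gene-level aggregation in this package uses the per-SNP mean (see
#' [aggregate_gene_fst()]).
#'
#' @inheritParams fst_wc
#' @return Single numeric theta estimate.
#' @export
fst_wc_multilocus <- function(p, n) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (is.null(dim(n))) n <- matrix(n, nrow = 1)
  valid <- !is.na(p) & !is.na(n) & n > 0
  n <- ifelse(valid, n, 0)
  p <- ifelse(valid, p, 0)
  r <- rowSums(valid)
  sumn <- rowSums(n)
  nbar <- sumn / r
  nc <- (sumn - rowSums(n^2) / sumn) / (r - 1)
  pbar <- rowSums(n * p) / sumn
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  h <- pbar * (1 - pbar) - s2 * (r - 1) / r
  a <- (nbar / nc) * (s2 - h / (nbar - 1))
  b <- (nbar / (nbar - 1)) * h
  keep <- r >= 2 & pbar > 0 & pbar < 1 & nbar > 1 & is.finite(a) & is.finite(b)
  sum(a[keep]) / sum(a[keep] + b[keep])
}

#' Aggregate per-SNP FST values to a gene-level statistic
#'
#' Three pooling modes: `mean` (arithmetic mean over SNPs with a defined
#' theta), `max` (maximum defined theta), and `tag_mean` (mean over the
#' gene's tagSNPs only). Undefined (`NA`) thetas -- SNPs monomorphic in the
#' pooled sample -- are excluded throughout.
#'
#' @param thetas Named numeric vector of per-SNP theta values for one gene.
#' @param mode One of `"mean"`, `"max"`, `"tag_mean"`.
#' @param tags Character vector of tag SNP IDs (names of `thetas`) or a
#'   logical/integer index; required for `tag_mean`.
#' @return Single numeric value, `NA` if no defined theta qualifies.
#' @examples
#' aggregate_gene_fst(c(a = 0.0, b = 0.2, c = 0.4), "mean") # 0.2
#' aggregate_gene_fst(c(a = 0.0, b = 0.2, c = 0.4), "max")  # 0.4
#' @export
aggregate_gene_fst <- function(thetas, mode = c("mean", "max", "tag_mean"),
                               tags = NULL) {
  mode <- match.arg(mode)
  if (mode == "tag_mean") {
    if (is.null(tags)) stop("tag_mean requires a tag set")
    thetas <- if (is.character(tags)) thetas[names(thetas) %in% tags]
              else thetas[tags]
  }
  thetas <- thetas[!is.na(thetas)]
  if (!length(thetas)) return(NA_real_)
  if (mode == "max") max(thetas) else mean(thetas)
}

#' Percentage of extreme-frequency SNPs in a gene
#'
#' For a population pair, the percentage of a gene's SNPs that are rare
#' (MAF < `rare_max`) in exactly one population while common
#' (MAF > `common_min`) in the other; such SNPs index loss of statistical
#' power when an association is re-tested on another continent. The
#' denominator counts SNPs with a defined MAF in both populations.
#'
#' @param gt A [genotype_table()].
#' @param pair Length-2 character vector of population labels.
#' @param rare_max MAF bound below which an allele is "rare" (default 0.1).
#' @param common_min MAF bound above which it is "common" (default 0.2).
#' @return Data frame with one row per gene: `gene`, `n_informative`,
#'   `extreme_freq_pct` (`NA` where no SNP is informative).
#' @export
extreme_frequency_pct <- function(gt, pair, rare_max = 0.1, common_min = 0.2) {
  stopifnot(length(pair) == 2L)
  af <- allele_frequencies(gt, pair)
  maf <- pmin(af$freq, 1 - af$freq)
  ok <- is.finite(maf[, 1]) & is.finite(maf[, 2])
  extreme <- (maf[, 1] < rare_max & maf[, 2] > common_min) |
    (maf[, 2] < rare_max & maf[, 1] > common_min)
  genes <- unique(gt$snps$gene)
  res <- data.frame(gene = genes,
                    n_informative = NA_integer_,
                    extreme_freq_pct = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    snp_i <- gt$snps$gene == genes[i]
    den <- sum(ok & snp_i)
    res$n_informative[i] <- den
    if (den > 0) res$extreme_freq_pct[i] <- 100 * sum(extreme & ok & snp_i) / den
  }
  res
}

#' Classify the major allele of a SNP as ancestral or derived
#'
#' Applies the frequency rule to an inferred derived-allele frequency:
#' `> 0.5` means the derived allele is the major one (`"DER"`), `< 0.5`
#' means the ancestral allele is major (`"ANC"`). At exactly 0.5 neither
#' allele is strictly major; by declared convention the derived allele is
#' reported (`tie = "DER"`), configurable. SNPs without a usable ancestral
#' call (`ancestral_ok = FALSE`) or frequency are `"excluded"`.
#'
#' @param der_freq Numeric vector of derived-allele frequencies in one
#'   population.
#' @param ancestral_ok Logical vector: is the parsimony ancestral call valid
#'   (both outgroups agree and match one human allele)?
#' @param tie `"DER"` (default) or `"ANC"`: status assigned at frequency 0.5.
#' @return Character vector in `{"ANC", "DER", "excluded"}`.
#' @export
classify_major_allele <- function(der_freq, ancestral_ok = TRUE,
                                  tie = c("DER", "ANC")) {
  tie <- match.arg(tie)
  ancestral_ok <- rep_len(ancestral_ok, length(der_freq))
  out <- rep("excluded", length(der_freq))
  usable <- ancestral_ok & is.finite(der_freq)
  out[usable & der_freq > 0.5] <- "DER"
  out[usable & der_freq < 0.5] <- "ANC"
  out[usable & der_freq == 0.5] <- tie
  out
}

#' Ancestral/derived status of the major allele, per SNP and population
#'
#' Infers the ancestral state of each SNP by outgroup parsimony: the call is
#' usable only if both outgroup species carry the same allele and that allele
#' matches one of the two human alleles. If the outgroups agree on the
#' *derived* human allele, polarity is flipped accordingly (the inferred
#' derived-allele frequency becomes `1 - p`), which is exactly how a
#' misleading outgroup state propagates through real parsimony calls.
#'
#' @param gt A [genotype_table()] whose `snps` table carries `anc_allele`,
#'   `der_allele`, `outgroup1`, `outgroup2`.
#' @param populations Optional subset of population labels.
#' @param tie Convention at frequency 0.5, see [classify_major_allele()].
#' @return Character matrix (SNPs x populations) over
#'   `{"ANC", "DER", "excluded"}`.
#' @export
major_allele_status <- function(gt, populations = NULL, tie = "DER") {
  stopifnot(inherits(gt, "genotype_table"),
            all(c("anc_allele", "der_allele", "outgroup1", "outgroup2")
                %in% names(gt$snps)))
  af <- allele_frequencies(gt, populations)
  sn <- gt$snps
  agree <- sn$outgroup1 == sn$outgroup2
  inferred_anc <- ifelse(agree, sn$outgroup1, NA_character_)
  usable <- agree & (inferred_anc == sn$anc_allele | inferred_anc == sn$der_allele)
  flipped <- usable & inferred_anc == sn$der_allele

  out <- matrix("excluded", nrow(af$freq), ncol(af$freq),
                dimnames = dimnames(af$freq))
  for (j in seq_len(ncol(af$freq))) {
    p <- af$freq[, j]
    p[flipped] <- 1 - p[flipped]
    out[, j] <- classify_major_allele(p, usable, tie = tie)
  }
  out
}

#' Percentage of intronic SNPs per gene
#'
#' @param gt A [genotype_table()] with an `annotation` column in `snps`.
#' @return Data frame `gene`, `n_snps`, `pct_intronic`.
#' @export
pct_intronic <- function(gt) {
  stopifnot("annotation" %in% names(gt$snps))
  genes <- unique(gt$snps$gene)
  n <- as.integer(table(factor(gt$snps$gene, levels = genes)))
  ni <- as.integer(table(factor(gt$snps$gene[gt$snps$annotation == "intronic"],
                                levels = genes)))
  data.frame(gene = genes, n_snps = n, pct_intronic = 100 * ni / n,
             stringsAsFactors = FALSE)
}
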