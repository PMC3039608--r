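# tagSNP selection: composite-LD r2 on genotype dosages and a greedy
# set-cover tagger run per population, intersected across populations.

#' Pairwise r-squared between two SNPs (composite LD)
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples; no phasing is attempted, so this is the composite (genotypic)
#' linkage-disequilibrium measure.
#'
#' @param x,y Dosage vectors for the two SNPs in one population
#'   (`{0,1,2,NA}`).
#' @return r-squared in `[0, 1]`; `NA` if either SNP is monomorphic over the
#'   pairwise-complete samples or fewer than 2 complete pairs exist.
#' @examples
#' pairwise_r2(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)) # 1
#' @export
pairwise_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# Greedy cover for one population. dosage: SNPs x samples for the gene's
# SNPs in that population; returns indices (into rows) of the tag set.
greedy_tag_cover <- function(dosage, pos, r2_min) {
  n_samp <- ncol(dosage)
  m <- nrow(dosage)
  if (m == 0L) return(integer(0))
  if (m == 1L) return(1L)
  r2 <- suppressWarnings(stats::cor(t(dosage), use = "pairwise.complete.obs")^2)
  r2[!is.finite(r2)] <- 0 # unverifiable coverage is treated as no coverage
  diag(r2) <- 1
  covers <- r2 >= r2_min

  tags <- integer(0)
  uncovered <- rep(TRUE, m)
  while (any(uncovered)) {
    gain <- rowSums(covers[, uncovered, drop = FALSE])
    best <- which(gain == max(gain))
    if (length(best) > 1L) best <- best[which.min(pos[best])]
    tags <- c(tags, best)
    uncovered <- uncovered & !covers[best, ]
  }
  sort(tags)
}

#' Select tagSNPs for one gene
#'
#' Within each population, SNPs are eligible if their genotyping call rate is
#' at least `call_min`, their minor-allele frequency at least `maf_min`, and
#' they are polymorphic there. A greedy set cover then repeatedly picks the
#' eligible SNP that tags (r-squared >= `r2_min`) the largest number of
#' still-untagged eligible SNPs, breaking ties by lower genomic position,
#' until every eligible SNP is covered by some tag. The returned set is the
#' intersection of the per-population tag sets; minimality is not guaranteed,
#' only the per-population coverage contract: every eligible non-tag SNP has
#' r-squared >= `r2_min` with at least one tag of its population's set.
#'
#' @param gt A [genotype_table()].
#' @param gene Gene ID whose SNPs are to be tagged.
#' @param r2_min Tagging threshold (default 0.8).
#' @param maf_min Minimum minor-allele frequency for eligibility (default 0.1).
#' @param call_min Minimum genotyping call rate for eligibility (default 0.75).
#' @param populations Populations to tag in (default: all in `gt`).
#' @return Character vector of SNP IDs tagging in *all* requested
#'   populations (possibly empty, with a message). Attributes:
#'   `per_population` (list of per-population tag ID sets) and `eligible`
#'   (list of per-population eligible ID sets).
#' @export
select_tag_snps <- function(gt, gene, r2_min = 0.8, maf_min = 0.1,
                            call_min = 0.75, populations = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  pops <- if (is.null(populations)) unique(gt$samples$population) else populations
  snp_idx <- which(gt$snps$gene == gene)
  if (!length(snp_idx)) stop("gene not found: ", gene)
  ids <- gt$snps$snp_id[snp_idx]
  pos <- gt$snps$pos[snp_idx]

  per_pop <- stats::setNames(vector("list", length(pops)), pops)
  eligible_sets <- per_pop
  for (pop in pops) {
    block <- gt$dosage[snp_idx, gt$samples$population == pop, drop = FALSE]
    n_called <- rowSums(!is.na(block))
    call_rate <- n_called / ncol(block)
    freq <- rowSums(block, na.rm = TRUE) / (2 * n_called)
    maf <- pmin(freq, 1 - freq)
    elig <- which(call_rate >= call_min & !is.na(maf) & maf >= maf_min &
                    maf > 0)
    eligible_sets[[pop]] <- ids[elig]
    tag_rel <- greedy_tag_cover(block[elig, , drop = FALSE], pos[elig], r2_min)
    per_pop[[pop]] <- ids[elig][tag_rel]
  }
  tags <- Reduce(intersect, per_pop)
  if (!length(tags)) {
    message("select_tag_snps: no SNP tags in all populations for gene ", gene)
  }
  structure(tags, per_population = per_pop, eligible = eligible_sets)
}

#' Gene-level FST profiles across population pairs
#'
#' Computes, for every gene and every requested population pooling
#' (pairwise and/or global over all populations), the per-SNP
#' Weir--Cockerham thetas aggregated as mean, max, and tagSNP mean, together
#' with SNP counts, tag counts, percent intronic SNPs and the
#' extreme-frequency percentage (pairwise poolings only).
#'
#' @param gt A [genotype_table()].
#' @param pairs List of length-2 character vectors of population labels;
#'   defaults to all pairs present in `gt`.
#' @param include_global Add a pooling over all populations (labelled
#'   `"global"`) when more than two populations are present.
#' @param tag_sets Optional named list (by gene) of tag SNP ID vectors, e.g.
#'   from [select_tag_snps()]; if `NULL` tag columns are `NA`.
#' @return Long data frame: `gene`, `comparison` (e.g. `"EUR-EAS"`),
#'   `n_snps`, `n_defined`, `mean_fst`, `max_fst`, `tag_mean_fst`,
#'   `n_tag_snps`, `pct_intronic`, `extreme_freq_pct`.
#' @export
gene_fst_profiles <- function(gt, pairs = NULL, include_global = TRUE,
                              tag_sets = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  pops <- unique(gt$samples$population)
  if (is.null(pairs)) {
    pairs <- if (length(pops) >= 2) utils::combn(pops, 2, simplify = FALSE)
             else list()
  }
  poolings <- lapply(pairs, identity)
  names(poolings) <- vapply(pairs, paste, character(1), collapse = "-")
  if (include_global && length(pops) > 2) poolings$global <- pops

  intron <- pct_intronic(gt)
  genes <- intron$gene
  out <- list()
  for (cmp in names(poolings)) {
    theta <- snp_fst(gt, poolings[[cmp]])
    ex <- if (length(poolings[[cmp]]) == 2L)
      extreme_frequency_pct(gt, poolings[[cmp]]) else NULL
    rows <- data.frame(
      gene = genes, comparison = cmp,
      n_snps = intron$n_snps, n_defined = NA_integer_,
      mean_fst = NA_real_, max_fst = NA_real_, tag_mean_fst = NA_real_,
      n_tag_snps = NA_integer_, pct_intronic = intron$pct_intronic,
      extreme_freq_pct = NA_real_, stringsAsFactors = FALSE
    )
    for (i in seq_along(genes)) {
      th <- theta[gt$snps$gene == genes[i]]
      rows$n_defined[i] <- sum(!is.na(th))
      rows$mean_fst[i] <- aggregate_gene_fst(th, "mean")
      rows$max_fst[i] <- suppressWarnings(aggregate_gene_fst(th, "max"))
      if (!is.null(tag_sets)) {
        tg <- tag_sets[[genes[i]]]
        rows$n_tag_snps[i] <- length(tg)
        if (length(tg)) {
          rows$tag_mean_fst[i] <- aggregate_gene_fst(th, "tag_mean", tags = tg)
        }
      }
      if (!is.null(ex)) rows$extreme_freq_pct[i] <- ex$extreme_freq_pct[i]
    }
    out[[cmp]] <- rows
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}
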