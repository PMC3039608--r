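#' Simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' association-study and genotype generator. Defaults emulate the structure of
#' a candidate-gene replication corpus genotyped on HapMap-style panels:
#' three continental populations (60 EUR, 90 EAS, 60 AFR diploids), genes of
#' 5--40 SNPs, and association studies whose outcome follows a
#' power/false-positive model with per-continent causal status.
#'
#' Population divergence follows the Balding--Nichols model: for a SNP with
#' ancestral frequency `p0`, the frequency in population *k* is drawn from
#' `Beta(p0 (1 - F_k) / F_k, (1 - p0)(1 - F_k) / F_k)`, whose parametric FST
#' equals `F_k`. Per-gene variation in divergence is introduced through a
#' multiplicative factor drawn from `gene_divergence_range`, so that genes
#' differ in their expected FST; `coupling` controls how strongly
#' continent-heterogeneous associations are assigned to high-divergence genes.
#'
#' @param n_genes Number of genes to simulate.
#' @param snps_per_gene Length-2 integer vector `c(min, max)`; SNP counts per
#'   gene are uniform on that range.
#' @param populations Data frame with columns `label`, `n` (diploid sample
#'   size, >= 2) and `fst` (baseline divergence parameter in `[0, 1)`).
#' @param gene_divergence_range Length-2 numeric; per-gene multiplier on the
#'   population `fst` values, uniform on this range. Use `c(1, 1)` for a
#'   homogeneous-divergence panel.
#' @param n_associations Number of gene--disease associations (each uses a
#'   distinct gene, so `n_associations <= n_genes`).
#' @param studies_per_continent Length-2 integer vector `c(min, max)`; number
#'   of studies per association in each of Europe and East Asia.
#' @param frac_heterogeneous Proportion of associations causal in exactly one
#'   continent; the remainder are causal in both.
#' @param coupling Strength in `[0, 1]` of the assignment bias of
#'   heterogeneous associations towards high-divergence genes (0 = uniform).
#' @param power_true Probability that a study of an association causal in its
#'   continent reports a positive outcome.
#' @param alpha_false Probability that a study of a non-causal association
#'   reports a positive outcome.
#' @param outgroup_error_rate Per-species probability that the simulated
#'   outgroup allele differs from the true ancestral allele.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param p0_range Support of the uniform prior on the ancestral derived-allele
#'   frequency; bounded away from 0 and 1 so monomorphic SNPs arise only
#'   through sampling.
#' @param seed Integer seed; all generator functions derive their streams
#'   from it, so a config is fully reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 10, n_associations = 5, seed = 1)
#' cfg$populations
#' @export
sim_config <- function(n_genes = 60L,
                       snps_per_gene = c(5L, 40L),
                       populations = data.frame(
                         label = c("EUR", "EAS", "AFR"),
                         n = c(60L, 90L, 60L),
                         fst = c(0.10, 0.10, 0.15),
                         stringsAsFactors = FALSE),
                       gene_divergence_range = c(0.2, 2),
                       n_associations = 40L,
                       studies_per_continent = c(8L, 12L),
                       frac_heterogeneous = 0.5,
                       coupling = 1,
                       power_true = 0.8,
                       alpha_false = 0.05,
                       outgroup_error_rate = 0.01,
                       missing_rate = 0.02,
                       p0_range = c(0.05, 0.95),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene),
    populations = populations,
    gene_divergence_range = as.numeric(gene_divergence_range),
    n_associations = as.integer(n_associations),
    studies_per_continent = as.integer(studies_per_continent),
    frac_heterogeneous = frac_heterogeneous,
    coupling = coupling,
    power_true = power_true,
    alpha_false = alpha_false,
    outgroup_error_rate = outgroup_error_rate,
    missing_rate = missing_rate,
    p0_range = as.numeric(p0_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    is.data.frame(cfg$populations),
    all(c("label", "n", "fst") %in% names(cfg$populations)),
    nrow(cfg$populations) >= 1,
    !anyDuplicated(cfg$populations$label)
  )
  if (any(cfg$populations$n < 2)) {
    stop("population diploid sample sizes must be >= 2")
  }
  if (any(cfg$populations$fst < 0 | cfg$populations$fst >= 1)) {
    stop("population divergence parameters must lie in [0, 1)")
  }
  probs <- c(cfg$frac_heterogeneous, cfg$coupling, cfg$power_true,
             cfg$alpha_false, cfg$outgroup_error_rate, cfg$missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (cfg$n_genes < 1L || cfg$n_associations < 0L) {
    stop("n_genes must be >= 1 and n_associations >= 0")
  }
  if (cfg$n_associations > cfg$n_genes) {
    stop("n_associations must not exceed n_genes (one distinct gene each)")
  }
  if (length(cfg$snps_per_gene) != 2L || cfg$snps_per_gene[1] < 1L ||
      cfg$snps_per_gene[1] > cfg$snps_per_gene[2]) {
    stop("snps_per_gene must be c(min, max) with 1 <= min <= max")
  }
  if (length(cfg$studies_per_continent) != 2L ||
      cfg$studies_per_continent[1] < 1L ||
      cfg$studies_per_continent[1] > cfg$studies_per_continent[2]) {
    stop("studies_per_continent must be c(min, max) with 1 <= min <= max")
  }
  if (length(cfg$p0_range) != 2L || cfg$p0_range[1] <= 0 ||
      cfg$p0_range[2] >= 1 || cfg$p0_range[1] > cfg$p0_range[2]) {
    stop("p0_range must lie strictly inside (0, 1)")
  }
  if (length(cfg$gene_divergence_range) != 2L ||
      any(cfg$gene_divergence_range < 0) ||
      cfg$gene_divergence_range[1] > cfg$gene_divergence_range[2]) {
    stop("gene_divergence_range must be non-negative c(min, max)")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  genes:", x$n_genes, " SNPs/gene:", x$snps_per_gene[1], "-",
      x$snps_per_gene[2], "\n")
  cat("  populations:", paste0(x$populations$label, " (n=", x$populations$n,
                               ", F=", x$populations$fst, ")",
                               collapse = ", "), "\n")
  cat("  associations:", x$n_associations,
      " heterogeneous fraction:", x$frac_heterogeneous,
      " coupling:", x$coupling, "\n")
  cat("  power:", x$power_true, " false-positive rate:", x$alpha_false,
      " seed:", x$seed, "\n")
  invisible(x)
}
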