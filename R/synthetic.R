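# Synthetic-data generator: Balding-Nichols population frequencies, binomial
# diploid genotypes with outgroup alleles, and study records drawn from a
# power/false-positive outcome model with per-continent causal status.

BASES <- c("A", "C", "G", "T")

# Uniform integer draw on [lo, hi] that is safe when lo == hi (avoids
# sample()'s scalar expansion).
sample_int_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(seq(lo, hi), n, replace = TRUE)
}

# Stage-specific streams are derived from the config seed so that each
# generator function is independently reproducible while stages stay
# decorrelated. Offsets kept small; seeds remain valid 32-bit integers.
stage_seed <- function(cfg, stage) {
  offs <- c(frequencies = 0L, genotypes = 1L, truth = 2L, records = 3L)
  as.integer((cfg$seed %% .Machine$integer.max) + offs[[stage]])
}

#' Simulate per-population allele frequencies (Balding--Nichols)
#'
#' Draws, for every SNP, an ancestral derived-allele frequency `p0` from
#' `Uniform(p0_range)` and a frequency in each population *k* from the
#' Balding--Nichols beta distribution
#' `Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)` with
#' `F = min(fst_k * m_g, 0.95)`, where `m_g` is the gene's divergence
#' multiplier. `F = 0` gives `p_k = p0` exactly. The parametric FST of this
#' model equals `F`, which makes estimator recovery directly testable.
#'
#' @param config A [sim_config()].
#' @return A data frame (one row per SNP) with columns `snp_id`, `gene`,
#'   `pos` (0-based), `annotation`, `anc_allele`, `der_allele`, `p0` and one
#'   `p_<label>` column per population. The per-gene divergence table
#'   (columns `gene`, `multiplier`, and effective `F_<label>` values) is
#'   attached as attribute `"genes"`.
#' @examples
#' fr <- simulate_population_frequencies(sim_config(n_genes = 3, n_associations = 2))
#' head(fr)
#' @export
simulate_population_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config <- validate_sim_config(config)
  set.seed(stage_seed(config, "frequencies"))

  genes <- data.frame(
    gene = sprintf("gene%03d", seq_len(config$n_genes)),
    multiplier = stats::runif(config$n_genes,
                              config$gene_divergence_range[1],
                              config$gene_divergence_range[2]),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(config$populations))) {
    lab <- config$populations$label[k]
    genes[[paste0("F_", lab)]] <-
      pmin(config$populations$fst[k] * genes$multiplier, 0.95)
  }

  n_per_gene <- sample_int_range(config$snps_per_gene[1],
                                 config$snps_per_gene[2], config$n_genes)
  gene_of_snp <- rep(genes$gene, n_per_gene)
  n_snps <- length(gene_of_snp)

  # genes laid out on a single contig, 100 kb apart; positions 0-based
  offset <- rep((seq_len(config$n_genes) - 1L) * 100000L, n_per_gene)
  within <- unlist(lapply(n_per_gene, function(m) sort(sample.int(50000L, m))), use.names = FALSE)
  pos <- offset + within - 1L

  anc <- sample(BASES, n_snps, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(BASES, a), 1L), character(1))
  annotation <- sample(c("intronic", "exonic", "UTR"), n_snps,
                       replace = TRUE, prob = c(0.95, 0.02, 0.03))

  out <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n_snps)),
    gene = gene_of_snp,
    pos = pos,
    annotation = annotation,
    anc_allele = anc,
    der_allele = unname(der),
    p0 = stats::runif(n_snps, config$p0_range[1], config$p0_range[2]),
    stringsAsFactors = FALSE
  )

  gi <- match(out$gene, genes$gene)
  for (k in seq_len(nrow(config$populations))) {
    lab <- config$populations$label[k]
    f <- genes[[paste0("F_", lab)]][gi]
    p <- out$p0
    draw <- f > 0
    if (any(draw)) {
      p[draw] <- stats::rbeta(sum(draw),
                              out$p0[draw] * (1 - f[draw]) / f[draw],
                              (1 - out$p0[draw]) * (1 - f[draw]) / f[draw])
    }
    out[[paste0("p_", lab)]] <- p
  }
  attr(out, "genes") <- genes
  out
}

#' Simulate a diploid genotype table from population frequencies
#'
#' Each genotype is drawn as `Binomial(2, p_k)` copies of the derived allele;
#' missing calls are injected independently at `config$missing_rate`. Two
#' outgroup-species alleles are simulated per SNP: each equals the true
#' ancestral allele with probability `1 - outgroup_error_rate`, otherwise a
#' uniformly chosen different base (which may coincide with the derived
#' allele, giving the parsimony rule a genuine failure mode).
#'
#' @param freqs Output of [simulate_population_frequencies()].
#' @param config The same [sim_config()].
#' @return A [genotype_table()].
#' @export
simulate_genotype_table <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "genotypes"))
  n_snps <- nrow(freqs)

  blocks <- list()
  samples <- list()
  for (k in seq_len(nrow(config$populations))) {
    lab <- config$populations$label[k]
    nk <- config$populations$n[k]
    p <- freqs[[paste0("p_", lab)]]
    g <- matrix(stats::rbinom(n_snps * nk, 2L, rep(p, nk)),
                nrow = n_snps, ncol = nk)
    blocks[[lab]] <- g
    samples[[lab]] <- data.frame(
      sample_id = sprintf("%s_%03d", lab, seq_len(nk)),
      population = lab, stringsAsFactors = FALSE
    )
  }
  dosage <- do.call(cbind, blocks)
  samples <- do.call(rbind, c(samples, list(make.row.names = FALSE)))
  if (config$missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < config$missing_rate] <- NA_integer_
  }

  outgroup <- function() {
    og <- freqs$anc_allele
    err <- stats::runif(n_snps) < config$outgroup_error_rate
    if (any(err)) {
      og[err] <- vapply(freqs$anc_allele[err],
                        function(a) sample(setdiff(BASES, a), 1L), character(1))
    }
    og
  }
  snps <- freqs[, c("snp_id", "gene", "pos", "annotation",
                    "anc_allele", "der_allele")]
  snps$outgroup1 <- outgroup()
  snps$outgroup2 <- outgroup()
  genotype_table(dosage, samples, snps)
}

#' Assign ground-truth causal status to associations
#'
#' Each association links one distinct gene to one disease and is either
#' heterogeneous (causal in exactly one of Europe/East Asia) or homogeneous
#' (causal in both). With coupling strength *s*, heterogeneous associations
#' are assigned to genes with sampling weight `(1 - s) + s * q^2` where `q`
#' is the gene's divergence rank quantile (and `(1 - s) + s * (1 - q)^2` for
#' homogeneous ones), so `s = 1` places discordant associations on the most
#' divergent genes and `s = 0` assigns genes uniformly.
#'
#' @param config A [sim_config()].
#' @param freqs Output of [simulate_population_frequencies()] (its `"genes"`
#'   attribute supplies the divergence ranking).
#' @return Data frame with one row per association: `association_id`, `gene`,
#'   `disease`, `causal_eur`, `causal_eas`, `gene_divergence`.
#' @export
simulate_ground_truth <- function(config, freqs) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "truth"))
  genes <- attr(freqs, "genes")
  if (is.null(genes)) stop("freqs must carry the 'genes' attribute")
  n_assoc <- config$n_associations
  if (n_assoc == 0L) {
    return(data.frame(association_id = character(), gene = character(),
                      disease = character(), causal_eur = logical(),
                      causal_eas = logical(), gene_divergence = numeric(),
                      stringsAsFactors = FALSE))
  }
  n_het <- round(config$frac_heterogeneous * n_assoc)
  s <- config$coupling
  q <- (rank(genes$multiplier, ties.method = "first") - 1) /
    max(nrow(genes) - 1, 1)

  pick <- function(n, w, exclude) {
    avail <- setdiff(seq_len(nrow(genes)), exclude)
    if (n == 0L) return(integer(0))
    avail[sample.int(length(avail), n, prob = w[avail] + 1e-9)]
  }
  het_idx <- pick(n_het, (1 - s) + s * q^2, integer(0))
  hom_idx <- pick(n_assoc - n_het, (1 - s) + s * (1 - q)^2, het_idx)

  idx <- c(het_idx, hom_idx)
  het <- rep(c(TRUE, FALSE), c(length(het_idx), length(hom_idx)))
  het_in_eur <- stats::runif(n_assoc) < 0.5
  truth <- data.frame(
    association_id = sprintf("assoc%03d", seq_len(n_assoc)),
    gene = genes$gene[idx],
    disease = sprintf("disease%03d", seq_len(n_assoc)),
    causal_eur = ifelse(het, het_in_eur, TRUE),
    causal_eas = ifelse(het, !het_in_eur, TRUE),
    gene_divergence = genes$multiplier[idx],
    stringsAsFactors = FALSE
  )
  truth
}

EUROPE_LABELS <- c("Caucasian", "European American", "Finnish", "German",
                   "Spanish", "Italian")
EASTASIA_LABELS <- c("Japanese", "Chinese", "Han Chinese", "Korean",
                     "East Asian")

#' Simulate association-study records
#'
#' For every association, draws a number of studies in each of Europe and
#' East Asia uniform on `config$studies_per_continent`, with a positive
#' outcome with probability `power_true` where the association is causal in
#' that continent and `alpha_false` elsewhere. Ancestry labels are free-text
#' strings drawn from continent-specific pools (e.g. "Caucasian",
#' "Japanese") so that the curation mapping step is exercised; sample sizes
#' are log-normal around 300 and years uniform on 1995--2007. Each
#' association has a focal marker (a SNP of its gene); studies record it with
#' probability 0.8, mirroring the sparse marker reporting of curated
#' association databases.
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_ground_truth()].
#' @param freqs Optional frequency table used to pick each association's
#'   focal marker among its gene's SNPs; without it `marker_id` is `NA`.
#' @return Data frame of study records with columns `record_id`, `gene`,
#'   `disease`, `outcome` ("Y"/"N"), `ancestry_label`, `sample_size`, `year`,
#'   `marker_id`.
#' @export
simulate_study_records <- function(config, truth, freqs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "records"))
  rows <- vector("list", nrow(truth) * 2L)
  ri <- 0L
  for (i in seq_len(nrow(truth))) {
    marker <- NA_character_
    if (!is.null(freqs)) {
      cand <- freqs$snp_id[freqs$gene == truth$gene[i]]
      if (length(cand)) marker <- cand[sample.int(length(cand), 1L)]
    }
    for (cont in c("Europe", "EastAsia")) {
      n_st <- sample_int_range(config$studies_per_continent[1],
                               config$studies_per_continent[2], 1L)
      causal <- if (cont == "Europe") truth$causal_eur[i] else truth$causal_eas[i]
      p_pos <- if (causal) config$power_true else config$alpha_false
      labels <- if (cont == "Europe") EUROPE_LABELS else EASTASIA_LABELS
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        gene = truth$gene[i],
        disease = truth$disease[i],
        outcome = ifelse(stats::runif(n_st) < p_pos, "Y", "N"),
        ancestry_label = sample(labels, n_st, replace = TRUE),
        sample_size = pmax(50L, round(stats::rlnorm(n_st, log(300), 0.6))),
        year = sample(1995:2007, n_st, replace = TRUE),
        marker_id = ifelse(stats::runif(n_st) < 0.8, marker, NA_character_),
        stringsAsFactors = FALSE
      )
    }
  }
  rec <- do.call(rbind, rows[seq_len(ri)])
  rec <- cbind(record_id = sprintf("rec%05d", seq_len(nrow(rec))), rec,
               stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  rec
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator: population allele frequencies, diploid genotypes
#' with outgroup alleles, ground-truth causal assignments, and study records.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `config`,
#'   `frequencies`, `genotypes`, `truth`, `records`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 8, n_associations = 4,
#'                                   snps_per_gene = c(3, 6)))
#' ds$genotypes
#' @export
simulate_dataset <- function(config = sim_config()) {
  freqs <- simulate_population_frequencies(config)
  gt <- simulate_genotype_table(freqs, config)
  truth <- simulate_ground_truth(config, freqs)
  records <- simulate_study_records(config, truth, freqs)
  structure(list(config = config, frequencies = freqs, genotypes = gt,
                 truth = truth, records = records),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$frequencies), "SNPs,",
      x$config$n_genes, "genes,", nrow(x$truth), "associations,",
      nrow(x$records), "study records\n")
  invisible(x)
}
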