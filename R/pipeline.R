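# End-to-end analysis: simulate (or accept) a dataset, curate the Global and
# Continental sets, compute gene FST profiles and phi, and run the report
# analyses (set-level resampling test, phi-FST correlation grid, stepwise
# regression, derived-allele stratum tests, marker-level correlation).

#' Assemble the predictor matrix for the stepwise regression
#'
#' One row per Continental-Set association, with the response `phi` and the
#' candidate predictors: mean gene FST between Europe and East Asia, number
#' of SNPs in the gene (a gene-length proxy), percent intronic SNPs, total /
#' European / East Asian study counts, mean sample size and mean publication
#' year, and optionally the extreme-frequency percentage.
#'
#' @param cont_set Continental-Set summary with a `phi` column (see
#'   [add_phi()]).
#' @param profiles Gene FST profiles from [gene_fst_profiles()]; the
#'   `comparison` used is `"EUR-EAS"` (or set `comparison`).
#' @param comparison Which profile pooling supplies `mean_fst` and
#'   `extreme_freq_pct`.
#' @param min_snps Minimum SNPs per gene for a defined mean FST; genes below
#'   it get `NA` (and are then dropped with the incomplete rows). `NULL`
#'   disables the filter.
#' @param include_extreme Include `extreme_freq_pct` as a candidate.
#' @return Data frame with `gene`, `disease`, `phi` and predictor columns.
#' @export
build_predictor_matrix <- function(cont_set, profiles,
                                   comparison = "EUR-EAS",
                                   min_snps = NULL,
                                   include_extreme = FALSE) {
  stopifnot("phi" %in% names(cont_set))
  prof <- profiles[profiles$comparison == comparison, , drop = FALSE]
  m <- match(cont_set$gene, prof$gene)
  out <- data.frame(
    gene = cont_set$gene, disease = cont_set$disease, phi = cont_set$phi,
    mean_fst = prof$mean_fst[m],
    n_snps = prof$n_snps[m],
    pct_intronic = prof$pct_intronic[m],
    n_studies = cont_set$n_studies,
    n_studies_eur = cont_set$n_studies_eur,
    n_studies_eas = cont_set$n_studies_eas,
    mean_sample_size = cont_set$mean_sample_size,
    mean_year = cont_set$mean_year,
    stringsAsFactors = FALSE)
  if (include_extreme) out$extreme_freq_pct <- prof$extreme_freq_pct[m]
  if (!is.null(min_snps)) {
    out$mean_fst[!is.na(out$n_snps) & out$n_snps < min_snps] <- NA_real_
  }
  out
}

safe_spearman <- function(x, y) {
  res <- try(spearman_correlation(x, y), silent = TRUE)
  if (inherits(res, "try-error")) list(rho = NA_real_, p_value = NA_real_,
                                       n = sum(is.finite(x) & is.finite(y)))
  else res
}

# phi-FST correlation grid over pooling modes and association sets,
# mirroring a Table-1 style summary. Per-SNP rows assign every SNP the phi
# of its gene's association (pseudo-replicated; flagged in the notes).
phi_fst_correlations <- function(cont_sets, profiles, theta_eur_eas,
                                 snp_gene, tag_sets, min_snps = 10L) {
  prof <- profiles[profiles$comparison == "EUR-EAS", , drop = FALSE]
  rows <- list()
  for (set_name in names(cont_sets)) {
    cs <- cont_sets[[set_name]]
    gm <- match(cs$gene, prof$gene)
    conservative <- set_name == "conservative"

    mean_fst <- prof$mean_fst[gm]
    if (conservative) {
      mean_fst[!is.na(prof$n_snps[gm]) & prof$n_snps[gm] < min_snps] <- NA_real_
    }
    sc <- safe_spearman(mean_fst, cs$phi)
    rows[[length(rows) + 1L]] <- data.frame(
      set = set_name, pooling = "by_gene", variable = "mean_fst",
      n = sc$n, rho = sc$rho, p_value = sc$p_value)

    snp_phi <- snp_theta <- numeric(0)
    for (i in seq_len(nrow(cs))) {
      idx <- which(snp_gene == cs$gene[i])
      snp_phi <- c(snp_phi, rep(cs$phi[i], length(idx)))
      snp_theta <- c(snp_theta, theta_eur_eas[idx])
    }
    sc <- safe_spearman(snp_theta, snp_phi)
    rows[[length(rows) + 1L]] <- data.frame(
      set = set_name, pooling = "per_snp", variable = "snp_fst",
      n = sc$n, rho = sc$rho, p_value = sc$p_value)

    tag_mean <- vapply(cs$gene, function(g) {
      th <- theta_eur_eas[snp_gene == g]
      tg <- tag_sets[[g]]
      if (is.null(tg) || !length(tg)) return(NA_real_)
      aggregate_gene_fst(th, "tag_mean", tags = tg)
    }, numeric(1))
    sc <- safe_spearman(tag_mean, cs$phi)
    rows[[length(rows) + 1L]] <- data.frame(
      set = set_name, pooling = "by_gene", variable = "tag_mean_fst",
      n = sc$n, rho = sc$rho, p_value = sc$p_value)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full replicability-vs-differentiation analysis
#'
#' Orchestrates the whole pipeline on a synthetic dataset (or one supplied
#' via `dataset`): curation into Global and Continental sets, gene-level FST
#' profiles with tagSNP sets, the phi discordance index, the set-level
#' resampling test, the phi--FST correlation grid (by-gene, per-SNP and
#' tagSNP poolings, full and conservative sets), forward stepwise regression
#' with and without the two largest genes, derived-allele stratum tables and
#' tests per population, and the marker-level phi--FST correlation where
#' marker IDs are present. All randomness derives from `config$seed` plus
#' the explicit `resample_seed`, so a rerun reproduces the report exactly.
#'
#' @param config A [sim_config()] describing the synthetic dataset.
#' @param dataset Optional pre-built [simulate_dataset()] output; when given,
#'   `config` is taken from it.
#' @param min_studies Global-Set threshold (default 4).
#' @param min_per_continent Continental-Set threshold (default 4).
#' @param conservative_pct Conservative replicability threshold (default 50).
#' @param min_snps Minimum SNPs per gene for conservative mean-FST analyses
#'   (default 10).
#' @param n_resamples Resampling-null size (default 10000).
#' @param outdir Optional directory: report tables are written as TSV plus a
#'   JSON summary and machine-readable run manifest.
#' @return List of class `replifst_report` with elements `manifest`,
#'   `global_set`, `continental_set`, `conservative_set`, `profiles`,
#'   `resampling`, `correlations`, `stepwise`, `stepwise_trimmed`,
#'   `derived_alleles`, `derived_tests`, `marker_correlation`, `notes`.
#' @export
run_full_analysis <- function(config = sim_config(), dataset = NULL,
                              min_studies = 4L, min_per_continent = 4L,
                              conservative_pct = 50, min_snps = 10L,
                              n_resamples = 10000L, outdir = NULL) {
  if (is.null(dataset)) dataset <- simulate_dataset(config)
  config <- dataset$config
  gt <- dataset$genotypes
  records <- assign_continents(dataset$records)

  global_set <- build_global_set(records, min_studies = min_studies)
  cont_set <- add_phi(build_continental_set(records, min_per_continent))
  conservative <- apply_conservative_filter(cont_set, conservative_pct)

  pops <- unique(gt$samples$population)
  all_genes <- unique(gt$snps$gene)
  tag_sets <- stats::setNames(
    lapply(all_genes, function(g) suppressMessages(
      as.character(select_tag_snps(gt, g)))), all_genes)
  profiles <- gene_fst_profiles(gt, tag_sets = tag_sets)

  # set-level FST: disease genes (Global Set) against the genome-wide pool
  pool_cmp <- if (length(pops) > 2) "global" else profiles$comparison[1]
  pool_prof <- profiles[profiles$comparison == pool_cmp, , drop = FALSE]
  pool <- stats::setNames(pool_prof$mean_fst, pool_prof$gene)
  disease_genes <- unique(global_set$gene)
  resampling <- NULL
  if (length(disease_genes) >= 1 &&
      sum(!is.na(pool)) > length(disease_genes)) {
    obs <- mean(pool[disease_genes], na.rm = TRUE)
    resampling <- resampling_mean_fst_test(
      obs, pool, set_size = length(disease_genes),
      n_resamples = n_resamples, tail = "lower",
      seed = stage_seed(config, "records") + 10L)
  }

  theta_eur_eas <- snp_fst(gt, c("EUR", "EAS"))
  correlations <- phi_fst_correlations(
    list(full = cont_set, conservative = conservative),
    profiles, theta_eur_eas, gt$snps$gene, tag_sets, min_snps = min_snps)

  pm <- build_predictor_matrix(cont_set, profiles)
  candidates <- c("mean_fst", "n_snps", "pct_intronic", "n_studies",
                  "n_studies_eur", "n_studies_eas", "mean_sample_size",
                  "mean_year")
  run_step <- function(d) {
    # an empty model is a valid outcome at report level, not a warning
    res <- try(suppressMessages(suppressWarnings(
      forward_stepwise(d, "phi", candidates))), silent = TRUE)
    if (inherits(res, "try-error")) NULL else res
  }
  stepwise <- run_step(pm)
  # exclusion of the two largest genes (by SNP count), which dominate the
  # per-SNP analyses and can drive the gene-length predictor
  big2 <- pm$gene[order(-pm$n_snps)][seq_len(min(2L, nrow(pm)))]
  stepwise_trimmed <- run_step(pm[!(pm$gene %in% big2), , drop = FALSE])

  derived_alleles <- derived_tests <- NULL
  if (nrow(global_set) >= 2) {
    split <- median_split(global_set)
    status <- major_allele_status(gt)
    derived_alleles <- derived_allele_table(status, gt, split)
    derived_tests <- do.call(rbind, lapply(pops, function(pop) {
      da <- derived_alleles[derived_alleles$population == pop, ]
      tab <- as.matrix(da[match(c("low", "high"), da$stratum), c("ANC", "DER")])
      if (any(rowSums(tab) == 0)) {
        return(data.frame(population = pop, chi2 = NA_real_, p_value = NA_real_))
      }
      ht <- derived_allele_test(tab)
      data.frame(population = pop, chi2 = ht$chi2, p_value = ht$p_value)
    }))
  }

  marker_correlation <- NULL
  if ("marker_id" %in% names(records)) {
    mk <- unique(records[!is.na(records$marker_id),
                         c("gene", "disease", "marker_id")])
    mk <- merge(mk, cont_set[, c("gene", "disease", "phi")],
                by = c("gene", "disease"))
    mk$theta <- theta_eur_eas[match(mk$marker_id, gt$snps$snp_id)]
    if (nrow(mk) >= 4) {
      sc <- safe_spearman(mk$theta, mk$phi)
      marker_correlation <- data.frame(n = sc$n, rho = sc$rho,
                                       p_value = sc$p_value)
    }
  }

  manifest <- list(
    package = "replifst",
    package_version = as.character(utils::packageVersion("replifst")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(min_studies = min_studies,
                      min_per_continent = min_per_continent,
                      conservative_pct = conservative_pct,
                      min_snps = min_snps,
                      n_resamples = n_resamples,
                      negative_theta_clamped = FALSE,
                      zero_margin_phi = 0,
                      tie_at_half_frequency = "DER")
  )
  notes <- c(
    "per_snp correlations duplicate gene-level phi across SNPs (pseudo-replicated)",
    "negative Weir-Cockerham thetas retained in averages (not clamped)",
    "zero-margin contingency tables assigned phi = 0 by convention")

  report <- structure(list(
    manifest = manifest, truth = dataset$truth,
    global_set = global_set, continental_set = cont_set,
    conservative_set = conservative, profiles = profiles,
    resampling = resampling, correlations = correlations,
    stepwise = stepwise, stepwise_trimmed = stepwise_trimmed,
    excluded_largest = big2,
    derived_alleles = derived_alleles, derived_tests = derived_tests,
    marker_correlation = marker_correlation, notes = notes
  ), class = "replifst_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write a report bundle to a directory
#'
#' Emits the report tables as TSV files plus `summary.json` (headline
#' numbers) and `manifest.json` (seed, thresholds, versions). Reruns with
#' the same configuration produce byte-identical tables.
#'
#' @param report A `replifst_report` from [run_full_analysis()].
#' @param outdir Output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(format(df, digits = 15, trim = TRUE),
                         file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(report$global_set, "global_set.tsv")
  wt(report$continental_set, "continental_set.tsv")
  wt(report$conservative_set, "conservative_set.tsv")
  wt(report$profiles, "gene_fst_profiles.tsv")
  wt(report$correlations, "phi_fst_correlations.tsv")
  wt(report$derived_alleles, "derived_allele_strata.tsv")
  wt(report$derived_tests, "derived_allele_tests.tsv")
  wt(report$marker_correlation, "marker_correlation.tsv")
  summarize_step <- function(sw) {
    if (is.null(sw) || !length(sw$predictors)) return(NULL)
    list(predictors = sw$predictors, beta = as.list(sw$beta),
         p_values = as.list(sw$p_values), tolerance = as.list(sw$tolerance),
         F = sw$F, df = sw$df, adj_r2 = sw$adj_r2, n = sw$n)
  }
  summary <- list(
    n_global = nrow(report$global_set),
    n_continental = nrow(report$continental_set),
    n_conservative = nrow(report$conservative_set),
    resampling = if (!is.null(report$resampling))
      report$resampling[c("observed", "pool_mean", "p_value", "p_label")],
    stepwise = summarize_step(report$stepwise),
    stepwise_trimmed = summarize_step(report$stepwise_trimmed),
    notes = report$notes)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.replifst_report <- function(x, ...) {
  cat("replifst analysis report\n")
  cat(sprintf("  Global Set: %d associations; Continental Set: %d (conservative: %d)\n",
              nrow(x$global_set), nrow(x$continental_set),
              nrow(x$conservative_set)))
  if (!is.null(x$resampling)) {
    cat(sprintf("  disease-gene mean FST %.4f vs pool %.4f (resampling p %s)\n",
                x$resampling$observed, x$resampling$pool_mean,
                x$resampling$p_label))
  }
  gene_row <- x$correlations[x$correlations$set == "full" &
                               x$correlations$variable == "mean_fst", ]
  if (nrow(gene_row)) {
    cat(sprintf("  phi ~ mean EUR-EAS FST: rho = %.3f (p = %.3g, n = %d)\n",
                gene_row$rho, gene_row$p_value, gene_row$n))
  }
  if (!is.null(x$stepwise) && length(x$stepwise$predictors)) {
    cat("  stepwise predictors:", paste(x$stepwise$predictors, collapse = ", "),
        sprintf("(adj R^2 = %.3f)\n", x$stepwise$adj_r2))
  }
  invisible(x)
}
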