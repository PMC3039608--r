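# Shared fixtures: hand-built genotype tables and an independent
# stepwise-selection oracle based on stats::add1/drop1 F tests.

# Build a genotype_table from a dosage matrix and a population vector,
# filling in minimal SNP metadata (one gene unless specified).
make_gt <- function(dosage, populations, gene = "geneA", pos = NULL,
                    annotation = "intronic", anc = "A", der = "G",
                    outgroup1 = NULL, outgroup2 = NULL) {
  dosage <- as.matrix(dosage)
  m <- nrow(dosage)
  snps <- data.frame(
    snp_id = sprintf("s%02d", seq_len(m)),
    gene = rep_len(gene, m),
    pos = if (is.null(pos)) seq_len(m) * 10L else pos,
    annotation = rep_len(annotation, m),
    anc_allele = rep_len(anc, m),
    der_allele = rep_len(der, m),
    stringsAsFactors = FALSE)
  snps$outgroup1 <- if (is.null(outgroup1)) snps$anc_allele else rep_len(outgroup1, m)
  snps$outgroup2 <- if (is.null(outgroup2)) snps$anc_allele else rep_len(outgroup2, m)
  samples <- data.frame(
    sample_id = sprintf("ind%03d", seq_along(populations)),
    population = populations, stringsAsFactors = FALSE)
  genotype_table(dosage, samples, snps)
}

# Random dosage matrix with given per-population frequencies (rows = SNPs).
random_dosage <- function(p_by_pop, n_by_pop) {
  blocks <- mapply(function(p, n) {
    matrix(rbinom(length(p) * n, 2, rep(p, n)), nrow = length(p))
  }, p_by_pop, n_by_pop, SIMPLIFY = FALSE)
  do.call(cbind, blocks)
}

# Independent forward-stepwise oracle: same enter/remove rules, but selection
# driven by stats::add1/drop1 partial-F tests instead of coefficient t tests.
stepwise_oracle <- function(data, response, candidates,
                            p_enter = 0.05, p_remove = 0.10) {
  z <- as.data.frame(scale(data[, c(response, candidates), drop = FALSE]))
  included <- character(0)
  repeat {
    rem <- setdiff(candidates, included)
    if (!length(rem)) break
    cur <- stats::lm(stats::reformulate(
      if (length(included)) included else "1", response), data = z)
    a1 <- stats::add1(cur, scope = stats::reformulate(c(included, rem)),
                      test = "F")
    p <- a1[rem, "Pr(>F)"]
    names(p) <- rem
    if (min(p) >= p_enter) break
    included <- c(included, names(p)[which.min(p)])
    repeat {
      fit <- stats::lm(stats::reformulate(included, response), data = z)
      d1 <- stats::drop1(fit, test = "F")
      pd <- d1[included, "Pr(>F)"]
      names(pd) <- included
      if (max(pd) <= p_remove) break
      included <- setdiff(included, names(pd)[which.max(pd)])
      if (!length(included)) break
    }
    if (!length(included)) break
  }
  included
}

# Brute-force check of the tagging coverage contract within one population:
# every eligible non-tag SNP must reach r2_min with at least one tag.
coverage_holds <- function(block, eligible_ids, tag_ids, ids, r2_min) {
  non_tags <- setdiff(eligible_ids, tag_ids)
  for (s in non_tags) {
    x <- block[match(s, ids), ]
    covered <- FALSE
    for (t in tag_ids) {
      r2 <- pairwise_r2(x, block[match(t, ids), ])
      if (!is.na(r2) && r2 >= r2_min) { covered <- TRUE; break }
    }
    if (!covered) return(FALSE)
  }
  TRUE
}
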