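# FST estimation, gene aggregation, extreme-frequency statistic and
# ancestral/derived classification.

test_that("allele frequencies equal direct counts", {
  # 60 diploids: 30 heterozygous, 30 homozygous ancestral -> freq 0.25
  gt <- make_gt(matrix(rep(c(1L, 0L), each = 30), nrow = 1), rep("EUR", 60))
  af <- allele_frequencies(gt)
  expect_equal(unname(af$freq[1, "EUR"]), 0.25)
  expect_equal(unname(af$n[1, "EUR"]), 120)
  # all homozygous derived -> 1
  gt2 <- make_gt(matrix(2L, 1, 10), rep("EUR", 10))
  expect_equal(unname(allele_frequencies(gt2)$freq[1, 1]), 1)

  # counting oracle on a random 10-SNP fixture with missing data
  set.seed(8)
  d <- matrix(sample(c(0:2, NA), 10 * 30, TRUE), nrow = 10)
  gt3 <- make_gt(d, rep(c("EUR", "EAS"), each = 15))
  af3 <- allele_frequencies(gt3)
  for (i in 1:10) {
    for (pop in c("EUR", "EAS")) {
      v <- d[i, (if (pop == "EUR") 1:15 else 16:30)]
      expect_equal(unname(af3$freq[i, pop]), sum(v, na.rm = TRUE) / (2 * sum(!is.na(v))))
    }
  }
})

test_that("Weir-Cockerham theta honours its boundary identities", {
  expect_equal(fst_wc(c(1, 0), c(120, 120)), 1)         # fixed difference
  expect_equal(fst_wc(c(0, 1), c(90, 120)), 1)          # unequal sizes too
  expect_lte(fst_wc(c(0.5, 0.5), c(120, 120)), 0)       # identical freqs
  expect_true(is.na(fst_wc(c(0, 0), c(120, 120))))      # pooled monomorphic
  expect_true(is.na(fst_wc(c(1, 1), c(120, 120))))
  expect_error(fst_wc(0.5, 120), "two populations")
  expect_error(fst_wc(c(0.5, 0.5), c(-2, 120)), "non-negative")
})

test_that("theta is invariant to population relabelling and allele swap", {
  set.seed(12)
  p <- matrix(runif(60), ncol = 3)
  n <- matrix(sample(c(90, 120, 180), 60, TRUE), ncol = 3)
  base <- fst_wc(p, n)
  perm <- c(3, 1, 2)
  expect_equal(fst_wc(p[, perm], n[, perm]), base)
  expect_equal(fst_wc(1 - p, n), base)
})

test_that("a population with no calls is dropped from the estimator", {
  # 3 populations, one entirely missing at a SNP: theta computed on the rest
  p <- c(0.2, 0.8, NaN)
  n <- c(100, 100, 0)
  expect_equal(fst_wc(p, n), fst_wc(c(0.2, 0.8), c(100, 100)))
  # with only one population left, theta is undefined
  expect_true(is.na(fst_wc(c(0.2, NaN), c(100, 0))))
})

test_that("gene aggregation follows the three pooling modes", {
  th <- c(a = 0.0, b = 0.2, c = 0.4)
  expect_equal(aggregate_gene_fst(th, "mean"), 0.2)
  expect_equal(aggregate_gene_fst(th, "max"), 0.4)
  expect_equal(aggregate_gene_fst(th["b"], "mean"),
               aggregate_gene_fst(th["b"], "max")) # single-SNP gene
  expect_equal(aggregate_gene_fst(c(th, d = NA), "mean"), 0.2) # NA excluded
  expect_equal(aggregate_gene_fst(th, "tag_mean", tags = c("a", "c")), 0.2)
  expect_error(aggregate_gene_fst(th, "tag_mean"), "tag set")
  expect_true(is.na(aggregate_gene_fst(c(x = NA_real_), "mean")))
  # order invariance and max >= mean on random gene profiles
  set.seed(3)
  for (i in 1:20) {
    th <- runif(sample(1:12, 1), -0.05, 0.6)
    names(th) <- paste0("s", seq_along(th))
    expect_equal(aggregate_gene_fst(sample(th), "mean"),
                 aggregate_gene_fst(th, "mean"))
    expect_gte(aggregate_gene_fst(th, "max"), aggregate_gene_fst(th, "mean"))
  }
})

test_that("max FST is more gene-length biased than mean FST", {
  ds <- simulate_dataset(sim_config(n_genes = 80, n_associations = 10,
                                    snps_per_gene = c(2, 60), seed = 19))
  prof <- gene_fst_profiles(ds$genotypes, pairs = list(c("EUR", "EAS")),
                            include_global = FALSE)
  r_max <- spearman_correlation(prof$n_snps, prof$max_fst)$rho
  r_mean <- spearman_correlation(prof$n_snps, prof$mean_fst)$rho
  expect_gt(r_max, r_mean)
})

test_that("extreme-frequency percentage counts rare-here-common-there SNPs", {
  # 10 diploids per pop: dosage sums give exact frequencies
  freqs_to_dosage <- function(f, n = 10) {
    # one population's dosages realising derived count round(2n f)
    cnt <- round(2 * n * f)
    v <- integer(n); i <- 1
    while (cnt >= 2) { v[i] <- 2L; cnt <- cnt - 2; i <- i + 1 }
    if (cnt == 1) { v[i] <- 1L }
    v
  }
  f_eur <- c(0.05, 0.40, 0.09, 0.30)
  f_eas <- c(0.30, 0.45, 0.15, 0.35)
  d <- cbind(t(sapply(f_eur, freqs_to_dosage)), t(sapply(f_eas, freqs_to_dosage)))
  gt <- make_gt(d, rep(c("EUR", "EAS"), each = 10))
  res <- extreme_frequency_pct(gt, c("EUR", "EAS"))
  # SNP1 qualifies (0.05 vs 0.30); SNP3 does not (0.15 <= 0.2 boundary)
  expect_equal(res$extreme_freq_pct, 25)

  # brute-force scan over a random 50-SNP fixture
  set.seed(9)
  p1 <- runif(50, 0.01, 0.99); p2 <- runif(50, 0.01, 0.99)
  d2 <- random_dosage(list(p1, p2), list(40, 40))
  gt2 <- make_gt(d2, rep(c("EUR", "EAS"), each = 40))
  af <- allele_frequencies(gt2)
  maf <- pmin(af$freq, 1 - af$freq)
  manual <- 100 * mean((maf[, 1] < 0.1 & maf[, 2] > 0.2) |
                         (maf[, 2] < 0.1 & maf[, 1] > 0.2))
  expect_equal(extreme_frequency_pct(gt2, c("EUR", "EAS"))$extreme_freq_pct,
               manual)
})

test_that("major-allele classification follows the frequency rule", {
  expect_equal(classify_major_allele(c(0.6, 0.4, 0.5, NaN), TRUE),
               c("DER", "ANC", "DER", "excluded"))
  expect_equal(classify_major_allele(0.5, TRUE, tie = "ANC"), "ANC")
  expect_equal(classify_major_allele(0.9, FALSE), "excluded")
})

test_that("outgroup parsimony gates and polarises the classification", {
  # 8 of 10 diploids homozygous derived -> derived frequency 0.8
  d <- matrix(rep(c(2L, 0L), c(8, 2)), nrow = 1)
  # outgroups agree on the ancestral allele: straightforward DER call
  gt <- make_gt(d, rep("EUR", 10), anc = "A", der = "G")
  expect_equal(unname(major_allele_status(gt)[1, "EUR"]), "DER")
  # outgroups disagree: excluded
  gt2 <- make_gt(d, rep("EUR", 10), anc = "A", der = "G",
                 outgroup1 = "A", outgroup2 = "C")
  expect_equal(unname(major_allele_status(gt2)[1, "EUR"]), "excluded")
  # outgroups agree on a third allele: excluded
  gt3 <- make_gt(d, rep("EUR", 10), anc = "A", der = "G",
                 outgroup1 = "C", outgroup2 = "C")
  expect_equal(unname(major_allele_status(gt3)[1, "EUR"]), "excluded")
  # outgroups agree on the derived human allele: polarity flips, so the
  # inferred derived frequency is 0.2 and the call is ANC
  gt4 <- make_gt(d, rep("EUR", 10), anc = "A", der = "G",
                 outgroup1 = "G", outgroup2 = "G")
  expect_equal(unname(major_allele_status(gt4)[1, "EUR"]), "ANC")
})

test_that("ANC/DER totals match a brute-force recount on simulated data", {
  ds <- simulate_dataset(sim_config(n_genes = 12, n_associations = 6,
                                    snps_per_gene = c(3, 8), seed = 23))
  gt <- ds$genotypes
  status <- major_allele_status(gt)
  af <- allele_frequencies(gt)
  sn <- gt$snps
  for (pop in colnames(status)) {
    manual <- character(nrow(sn))
    for (i in seq_len(nrow(sn))) {
      og <- c(sn$outgroup1[i], sn$outgroup2[i])
      if (og[1] != og[2] || !(og[1] %in% c(sn$anc_allele[i], sn$der_allele[i]))) {
        manual[i] <- "excluded"; next
      }
      p <- af$freq[i, pop]
      if (og[1] == sn$der_allele[i]) p <- 1 - p
      manual[i] <- if (!is.finite(p)) "excluded"
        else if (p > 0.5) "DER" else if (p < 0.5) "ANC" else "DER"
    }
    expect_equal(unname(status[, pop]), manual)
  }
})

test_that("dropping EUR/EAS-monomorphic SNPs leaves EUR-EAS aggregates unchanged", {
  ds <- simulate_dataset(sim_config(n_genes = 15, n_associations = 5,
                                    snps_per_gene = c(4, 10),
                                    p0_range = c(0.05, 0.5), seed = 29))
  gt <- ds$genotypes
  # force a handful of SNPs to be monomorphic (ancestral) in EUR and EAS
  eur_eas <- gt$samples$population %in% c("EUR", "EAS")
  forced <- seq(1, nrow(gt$dosage), by = 17)
  d <- gt$dosage
  d[forced, eur_eas] <- 0L
  gt <- genotype_table(d, gt$samples, gt$snps)
  af <- allele_frequencies(gt, c("EUR", "EAS"))
  f1 <- af$freq[, 1]; f2 <- af$freq[, 2]
  mono <- is.finite(f1) & is.finite(f2) &
    ((f1 == 0 & f2 == 0) | (f1 == 1 & f2 == 1))
  expect_gt(sum(mono), 0) # fixture must actually contain such SNPs
  keep_ids <- gt$snps$snp_id[!mono]
  full <- gene_fst_profiles(gt, pairs = list(c("EUR", "EAS")),
                            include_global = FALSE)
  slim <- gene_fst_profiles(subset_genotypes(gt, snp_ids = keep_ids),
                            pairs = list(c("EUR", "EAS")),
                            include_global = FALSE)
  shared <- intersect(full$gene, slim$gene)
  expect_equal(full$mean_fst[match(shared, full$gene)],
               slim$mean_fst[match(shared, slim$gene)])
  expect_equal(full$max_fst[match(shared, full$gene)],
               slim$max_fst[match(shared, slim$gene)])
})
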