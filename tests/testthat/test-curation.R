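# Curation: ancestry normalization, the Global/Continental filtering ladder,
# the conservative filter, and the TSV round trips.

rec_row <- function(gene, disease, outcome, label, n = 1L) {
  data.frame(record_id = replicate(n, paste0("r", sample.int(1e6, 1))),
             gene = gene, disease = disease, outcome = outcome,
             ancestry_label = label, sample_size = 100L, year = 2000L,
             marker_id = NA_character_, stringsAsFactors = FALSE)
}

test_that("ancestry labels map to continents, unknowns to Unassigned", {
  expect_equal(normalize_ancestry("Caucasian"), "Europe")
  expect_equal(normalize_ancestry("African American"), "Africa")
  expect_equal(normalize_ancestry("Japanese"), "EastAsia")
  expect_equal(normalize_ancestry("Iranian"), "MiddleEast")
  expect_equal(normalize_ancestry(" caucasian "), "Europe") # case/space-insensitive
  expect_message(out <- normalize_ancestry("Klingon"), "Klingon")
  expect_equal(out, "Unassigned")
})

test_that("Global Set applies the study-count threshold and replicability", {
  rec <- rbind(
    rec_row("g1", "d1", c("Y", "Y", "Y", "N"), "Caucasian"),
    rec_row("g2", "d2", c("Y", "Y", "N"), "Japanese"))
  gs <- build_global_set(rec, min_studies = 4)
  expect_equal(nrow(gs), 1L)          # the 3-study pair is excluded
  expect_equal(gs$gene, "g1")
  expect_equal(gs$replicability_pct, 75)
  expect_warning(build_global_set(rec[0, ]), "empty")
})

test_that("Continental Set needs the threshold in both continents", {
  rec <- rbind(
    rec_row("g1", "d1", c("Y", "Y", "Y", "N"), "Caucasian"),    # 4 EUR
    rec_row("g1", "d1", c("Y", "N", "N"), "Japanese"),          # 3 EAS
    rec_row("g2", "d2", c("Y", "Y", "Y", "Y", "N"), "German"),  # 5 EUR, 4 pos
    rec_row("g2", "d2", c("Y", "N", "N", "N"), "Chinese"),      # 4 EAS, 1 pos
    rec_row("g2", "d2", "Y", "Mixed"))                          # excluded here
  cs <- build_continental_set(rec, min_per_continent = 4)
  expect_equal(nrow(cs), 1L)          # g1-d1 misses the EAS threshold
  expect_equal(cs$gene, "g2")
  expect_equal(cs$repl_eur_pct, 80)
  expect_equal(cs$repl_eas_pct, 25)
  expect_equal(cs$n_studies, 9L)      # the Mixed record never enters counts
  # ... but Mixed does count towards the Global Set
  gs <- build_global_set(rec)
  expect_equal(gs$n_studies[gs$gene == "g2"], 10L)
  # endemic-disease drop list removes the pair outright
  expect_equal(nrow(build_continental_set(rec, drop_diseases = "d2")), 0L)
})

test_that("conservative filter keeps ties at the threshold", {
  cs <- data.frame(gene = c("a", "b", "c"), disease = "d",
                   replicability_pct = c(40, 49.9, 75),
                   repl_eur_pct = c(49.9, 50.0, 100),
                   repl_eas_pct = c(49.9, 20.0, 50))
  kept <- apply_conservative_filter(cs, 50)
  expect_equal(kept$gene, c("b", "c")) # 49.9/49.9 dropped; 50 in one kept
  gs <- data.frame(gene = c("a", "b"), disease = "d",
                   replicability_pct = c(50, 49.9))
  expect_equal(apply_conservative_filter(gs, 50)$gene, "a")
})

test_that("raising the study threshold never adds associations", {
  ds <- simulate_dataset(sim_config(n_genes = 20, n_associations = 15,
                                    snps_per_gene = c(2, 4),
                                    studies_per_continent = c(2L, 7L),
                                    seed = 31))
  prev <- build_global_set(ds$records, min_studies = 2)
  for (ms in 3:8) {
    cur <- build_global_set(ds$records, min_studies = ms)
    expect_true(all(paste(cur$gene, cur$disease) %in%
                      paste(prev$gene, prev$disease)))
    prev <- cur
  }
})

test_that("summary counts match a direct recount of the records", {
  ds <- simulate_dataset(sim_config(n_genes = 25, n_associations = 20,
                                    snps_per_gene = c(2, 4), seed = 17))
  rec <- ds$records
  gs <- build_global_set(rec, min_studies = 4)
  tab <- table(paste(rec$gene, rec$disease))
  expect_equal(nrow(gs), sum(tab >= 4))
  for (i in sample.int(nrow(gs), 5)) {
    sel <- rec$gene == gs$gene[i] & rec$disease == gs$disease[i]
    expect_equal(gs$n_studies[i], sum(sel))
    expect_equal(gs$n_positive[i], sum(rec$outcome[sel] == "Y"))
  }
  # per-continent study counts never exceed the total
  cs <- build_continental_set(rec)
  expect_true(all(cs$n_studies_eur + cs$n_studies_eas <= cs$n_studies + 1e-9))
})

test_that("records and summaries survive a TSV round trip", {
  ds <- simulate_dataset(sim_config(n_genes = 6, n_associations = 4,
                                    snps_per_gene = c(2, 3), seed = 41))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "records.tsv")
  write_study_records(ds$records, p)
  back <- read_study_records(p)
  expect_equal(back, ds$records)

  cs <- add_phi(build_continental_set(ds$records))
  p2 <- file.path(tmp, "summary.tsv")
  write_association_summaries(cs, p2)
  back2 <- read_association_summaries(p2)
  expect_equal(back2$phi, cs$phi, tolerance = 1e-12)
  expect_equal(back2$replicability_pct, cs$replicability_pct, tolerance = 1e-12)
  expect_identical(back2$gene, cs$gene)
})
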