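# Curation: from raw study records to the Global and Continental association
# sets, with replicability indices and the conservative filter.

#' Default ancestry-label to continent mapping
#'
#' Two-column table mapping free-text ancestry labels to one of the eight
#' continent categories (`Africa`, `Europe`, `MiddleEast`, `EastAsia`,
#' `Oceania`, `America`, `Mixed`, `Unassigned`). Conventions follow curated
#' association databases: "Caucasian" maps to Europe, "African American" to
#' Africa (recent migration assigned to ancestral continent), mixed panels
#' to `Mixed`. Matching in [normalize_ancestry()] is case-insensitive;
#' unknown labels become `Unassigned`.
#'
#' @return Data frame with columns `label`, `continent`.
#' @export
default_ancestry_map <- function() {
  map <- list(
    Europe = c("Caucasian", "European", "European American", "Finnish",
               "German", "Spanish", "French", "Italian", "British", "EUR"),
    Africa = c("African", "African American", "Yoruba",
               "Sub-Saharan African", "AFR"),
    EastAsia = c("Japanese", "Chinese", "Han Chinese", "Korean",
                 "East Asian", "EAS"),
    MiddleEast = c("Iranian", "Turkish", "Arab", "Israeli"),
    America = c("Amerindian", "Native American"),
    Oceania = c("Oceanian", "Polynesian", "Melanesian"),
    Mixed = c("Mixed", "Mixed panel", "Admixed")
  )
  data.frame(label = unlist(map, use.names = FALSE),
             continent = rep(names(map), lengths(map)),
             stringsAsFactors = FALSE)
}

#' Map free-text ancestry labels to continents
#'
#' Unknown labels are mapped to `"Unassigned"`, never dropped; every unknown
#' label is reported once via [message()] so curation decisions stay
#' auditable.
#'
#' @param labels Character vector of free-text ancestry labels.
#' @param mapping Two-column data frame (`label`, `continent`); defaults to
#'   [default_ancestry_map()].
#' @return Character vector of continent categories, same length as `labels`.
#' @examples
#' normalize_ancestry(c("Caucasian", "African American", "Klingon"))
#' @export
normalize_ancestry <- function(labels, mapping = default_ancestry_map()) {
  stopifnot(is.data.frame(mapping), all(c("label", "continent") %in% names(mapping)))
  idx <- match(tolower(trimws(labels)), tolower(trimws(mapping$label)))
  out <- mapping$continent[idx]
  unknown <- unique(labels[is.na(idx) & !is.na(labels)])
  if (length(unknown)) {
    message("normalize_ancestry: unmapped labels set to Unassigned: ",
            paste(unknown, collapse = ", "))
  }
  out[is.na(idx)] <- "Unassigned"
  out
}

#' Attach continent assignments to study records
#'
#' @param records Study-record data frame with an `ancestry_label` column.
#' @param mapping Label-to-continent table for [normalize_ancestry()].
#' @return `records` with a `continent` column appended (replaced if present).
#' @export
assign_continents <- function(records, mapping = default_ancestry_map()) {
  records$continent <- normalize_ancestry(records$ancestry_label, mapping)
  records
}

outcome_positive <- function(outcome) {
  o <- toupper(as.character(outcome))
  if (!all(o %in% c("Y", "N", "POSITIVE", "NEGATIVE"))) {
    stop("outcomes must be Y/N or positive/negative")
  }
  o %in% c("Y", "POSITIVE")
}

#' Build the Global association set
#'
#' Pools study records into one row per (gene, disease) pair, keeping only
#' pairs studied at least `min_studies` times (all continents counted), and
#' computes the replicability index: the percentage of positive studies over
#' all studies of the association.
#'
#' @param records Study-record data frame with columns `gene`, `disease`,
#'   `outcome`.
#' @param min_studies Minimum number of studies for a pair to be retained
#'   (default 4).
#' @return Data frame with columns `gene`, `disease`, `n_studies`,
#'   `n_positive`, `replicability_pct`.
#' @export
build_global_set <- function(records, min_studies = 4L) {
  empty <- data.frame(gene = character(), disease = character(),
                      n_studies = integer(), n_positive = integer(),
                      replicability_pct = numeric(), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) {
    warning("no study records supplied; returning empty Global Set")
    return(empty)
  }
  pos <- outcome_positive(records$outcome)
  key <- interaction(records$gene, records$disease, drop = TRUE, sep = "\r")
  agg <- data.frame(
    gene = tapply(records$gene, key, `[`, 1L),
    disease = tapply(records$disease, key, `[`, 1L),
    n_studies = as.integer(tapply(pos, key, length)),
    n_positive = as.integer(tapply(pos, key, sum)),
    stringsAsFactors = FALSE
  )
  agg <- agg[agg$n_studies >= min_studies, , drop = FALSE]
  agg$replicability_pct <- 100 * agg$n_positive / agg$n_studies
  agg <- agg[order(agg$gene, agg$disease), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Build the Continental association set
#'
#' Retains (gene, disease) pairs with at least `min_per_continent` studies in
#' Europe AND at least `min_per_continent` in East Asia. Only European and
#' East Asian studies enter the counts; records from other continents
#' (including `Mixed` and `Unassigned`) are excluded here but still count in
#' the Global Set. Diseases on `drop_diseases` (e.g. pathogens endemic to one
#' continent, which confound continental comparison) are removed first.
#'
#' @param records Study-record data frame; a `continent` column is computed
#'   from `ancestry_label` via `mapping` if absent.
#' @param min_per_continent Minimum studies required in each of Europe and
#'   East Asia (default 4).
#' @param mapping Label-to-continent table used when `continent` is missing.
#' @param drop_diseases Character vector of disease IDs excluded up front.
#' @return Data frame with one row per retained pair: `gene`, `disease`,
#'   `n_studies`, `n_positive`, `replicability_pct` (over the EUR+EAS studies),
#'   per-continent counts `n_studies_eur`, `n_positive_eur`, `n_studies_eas`,
#'   `n_positive_eas`, replicabilities `repl_eur_pct`, `repl_eas_pct`, and
#'   covariate summaries `mean_sample_size`, `mean_year`.
#' @export
build_continental_set <- function(records, min_per_continent = 4L,
                                  mapping = default_ancestry_map(),
                                  drop_diseases = character()) {
  empty <- data.frame(
    gene = character(), disease = character(), n_studies = integer(),
    n_positive = integer(), replicability_pct = numeric(),
    n_studies_eur = integer(), n_positive_eur = integer(),
    n_studies_eas = integer(), n_positive_eas = integer(),
    repl_eur_pct = numeric(), repl_eas_pct = numeric(),
    mean_sample_size = numeric(), mean_year = numeric(),
    stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) {
    warning("no study records supplied; returning empty Continental Set")
    return(empty)
  }
  if (!"continent" %in% names(records)) {
    records <- assign_continents(records, mapping)
  }
  records <- records[!(records$disease %in% drop_diseases), , drop = FALSE]
  records <- records[records$continent %in% c("Europe", "EastAsia"), , drop = FALSE]
  if (nrow(records) == 0L) return(empty)

  pos <- outcome_positive(records$outcome)
  eur <- records$continent == "Europe"
  key <- interaction(records$gene, records$disease, drop = TRUE, sep = "\r")
  num <- function(v, f) as.numeric(tapply(v, key, f))
  agg <- data.frame(
    gene = tapply(records$gene, key, `[`, 1L),
    disease = tapply(records$disease, key, `[`, 1L),
    n_studies_eur = as.integer(tapply(eur, key, sum)),
    n_positive_eur = as.integer(tapply(pos & eur, key, sum)),
    n_studies_eas = as.integer(tapply(!eur, key, sum)),
    n_positive_eas = as.integer(tapply(pos & !eur, key, sum)),
    mean_sample_size = if ("sample_size" %in% names(records))
      num(records$sample_size, function(x) mean(x, na.rm = TRUE)) else NA_real_,
    mean_year = if ("year" %in% names(records))
      num(records$year, function(x) mean(x, na.rm = TRUE)) else NA_real_,
    stringsAsFactors = FALSE
  )
  keep <- agg$n_studies_eur >= min_per_continent &
    agg$n_studies_eas >= min_per_continent
  agg <- agg[keep, , drop = FALSE]
  agg$n_studies <- agg$n_studies_eur + agg$n_studies_eas
  agg$n_positive <- agg$n_positive_eur + agg$n_positive_eas
  agg$replicability_pct <- 100 * agg$n_positive / agg$n_studies
  agg$repl_eur_pct <- 100 * agg$n_positive_eur / agg$n_studies_eur
  agg$repl_eas_pct <- 100 * agg$n_positive_eas / agg$n_studies_eas
  agg <- agg[order(agg$gene, agg$disease),
             c("gene", "disease", "n_studies", "n_positive",
               "replicability_pct", "n_studies_eur", "n_positive_eur",
               "n_studies_eas", "n_positive_eas", "repl_eur_pct",
               "repl_eas_pct", "mean_sample_size", "mean_year")]
  rownames(agg) <- NULL
  agg
}

#' Conservative replicability filter
#'
#' Keeps associations that replicated at least `threshold_pct` of the time:
#' in at least one continent for Continental-Set summaries (detected by the
#' presence of `repl_eur_pct`), or globally otherwise. The threshold is
#' inclusive (an association at exactly 50% is kept). The companion
#' minimum-SNP rule for mean-FST analyses is applied separately where
#' predictor matrices are built (see [build_predictor_matrix()]), since it
#' concerns genes, not associations.
#'
#' @param summaries An association-summary data frame from
#'   [build_global_set()] or [build_continental_set()].
#' @param threshold_pct Replicability threshold in percent (default 50).
#' @return The retained subset of `summaries`.
#' @export
apply_conservative_filter <- function(summaries, threshold_pct = 50) {
  if (all(c("repl_eur_pct", "repl_eas_pct") %in% names(summaries))) {
    keep <- summaries$repl_eur_pct >= threshold_pct |
      summaries$repl_eas_pct >= threshold_pct
  } else {
    keep <- summaries$replicability_pct >= threshold_pct
  }
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
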