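# Statistical analyses: Spearman correlations, the gene-resampling null for
# set-level FST, the replicability median split, derived-allele contingency
# tests, and forward stepwise regression with standardized coefficients.

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average ranks; the p-value uses the
#' t-approximation with `n - 2` degrees of freedom (via
#' [stats::cor.test()] with `exact = FALSE`), which handles ties.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4L) stop("at least 4 complete pairs are required")
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Gene-resampling test for the mean FST of a gene set
#'
#' Compares the observed mean FST of a set of genes (e.g. disease-associated
#' genes) against the distribution of mean FST in `n_resamples` equally
#' sized gene sets drawn without replacement from a genome-wide pool. The
#' empirical p-value is `k / n_resamples` where `k` counts resampled sets at
#' least as extreme as the observation in the stated tail; `k = 0` is
#' reported as "< 1/N" (the resolution bound of the Monte Carlo), with
#' `p_value` 0.
#'
#' @param observed_mean Observed mean FST of the gene set of interest.
#' @param pool Numeric vector of gene-level mean FST values for the
#'   genome-wide pool (NA entries dropped).
#' @param set_size Number of genes per resampled set.
#' @param n_resamples Number of random sets (default 10000).
#' @param tail `"lower"` (observed as low or lower) or `"upper"`.
#' @param seed Optional integer seed for the resampling stream.
#' @return Object of class `resampling_test`: list with `observed`,
#'   `pool_mean`, `set_size`, `n_resamples`, `tail`, `k`, `p_value`,
#'   `p_label`.
#' @export
resampling_mean_fst_test <- function(observed_mean, pool, set_size,
                                     n_resamples = 10000L,
                                     tail = c("lower", "upper"),
                                     seed = NULL) {
  tail <- match.arg(tail)
  pool <- pool[!is.na(pool)]
  if (set_size >= length(pool)) {
    stop("set_size must be smaller than the gene pool")
  }
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(seq_len(n_resamples), function(i) {
    mean(pool[sample.int(length(pool), set_size)])
  }, numeric(1))
  k <- if (tail == "lower") sum(means <= observed_mean)
       else sum(means >= observed_mean)
  p <- k / n_resamples
  structure(list(
    observed = observed_mean, pool_mean = mean(pool), set_size = set_size,
    n_resamples = n_resamples, tail = tail, k = k, p_value = p,
    p_label = if (k == 0L) sprintf("< %g", 1 / n_resamples) else sprintf("%g", p)
  ), class = "resampling_test")
}

#' @export
print.resampling_test <- function(x, ...) {
  cat(sprintf(
    "Gene-resampling test (%s tail): observed mean FST %.4f vs pool %.4f\n",
    x$tail, x$observed, x$pool_mean))
  cat(sprintf("  %d sets of %d genes; p %s\n",
              x$n_resamples, x$set_size, x$p_label))
  invisible(x)
}

#' Split associations at the median replicability
#'
#' Both strata are inclusive of ties at the median: the low stratum holds
#' associations with replicability <= median and the high stratum those with
#' replicability >= median, so ties appear in both and the strata partition
#' the set exactly when no association sits at the median.
#'
#' @param summaries Association-summary data frame with a
#'   `replicability_pct` column, or a bare numeric vector.
#' @return List with `median`, `low`, `high` (subsets of the input) and the
#'   stratum sizes `n_low`, `n_high`.
#' @export
median_split <- function(summaries) {
  x <- if (is.data.frame(summaries)) summaries$replicability_pct else summaries
  if (length(x) < 2L) stop("at least 2 associations are required")
  med <- stats::median(x)
  low_i <- which(x <= med)
  high_i <- which(x >= med)
  subset_of <- function(i) {
    if (is.data.frame(summaries)) summaries[i, , drop = FALSE] else summaries[i]
  }
  list(median = med, low = subset_of(low_i), high = subset_of(high_i),
       n_low = length(low_i), n_high = length(high_i))
}

#' Derived-allele stratum table for one population
#'
#' Pools ANC/DER major-allele classifications over the associations of each
#' replicability stratum: every association contributes the classifications
#' of all SNPs of its gene (a gene shared by several associations is counted
#' once per association).
#'
#' @param status Character matrix from [major_allele_status()] (SNPs x
#'   populations).
#' @param gt The [genotype_table()] the status matrix was computed from.
#' @param split Output of [median_split()] on a Global-Set summary.
#' @param populations Populations to tabulate (default: columns of `status`).
#' @return Data frame: `population`, `stratum` (`low`/`high`), `n_assoc`,
#'   `ANC`, `DER`, `der_pct`.
#' @export
derived_allele_table <- function(status, gt, split, populations = NULL) {
  pops <- if (is.null(populations)) colnames(status) else populations
  strata <- list(low = split$low, high = split$high)
  rows <- list()
  for (pop in pops) {
    for (st in names(strata)) {
      genes <- strata[[st]]$gene
      anc <- der <- 0L
      for (g in genes) {
        cls <- status[gt$snps$gene == g, pop]
        anc <- anc + sum(cls == "ANC")
        der <- der + sum(cls == "DER")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, stratum = st, n_assoc = length(genes),
        ANC = anc, DER = der,
        der_pct = if (anc + der > 0) 100 * der / (anc + der) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Chi-squared test on a derived-allele stratum table
#'
#' Pearson chi-square with Yates continuity correction (1 df, two-sided) on
#' the 2x2 table of (ANC, DER) counts by (low, high) replicability stratum.
#'
#' @param table 2x2 matrix: rows are strata, columns `c(ANC, DER)` counts.
#' @return List with `chi2`, `df`, `p_value`.
#' @examples
#' derived_allele_test(matrix(c(19017, 4533, 19783, 5173), 2, byrow = TRUE))
#' @export
derived_allele_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  ht <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Forward stepwise regression with standardized coefficients
#'
#' Candidates are entered one at a time: at each step the candidate with the
#' smallest partial-F p-value below `p_enter` is added; after every addition
#' any included predictor whose p-value exceeds `p_remove` is removed (worst
#' first). All variables (response included) are z-scored before fitting, so
#' the reported coefficients are standardized Betas. For every included
#' predictor the tolerance (1 minus the R-squared of that predictor
#' regressed on the other included predictors; 1 for a single predictor) is
#' reported, along with the model F statistic, its degrees of freedom,
#' R-squared and adjusted R-squared.
#'
#' @param data Data frame holding response and candidate columns; rows with
#'   any missing value among them are dropped (reported via `message`).
#' @param response Name of the response column.
#' @param candidates Names of candidate predictor columns (default: all
#'   others).
#' @param p_enter Entry threshold on the partial-F p-value (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @return Object of class `stepwise_model`: list with `predictors` (in
#'   entry order), `beta`, `p_values`, `tolerance`, `F`, `df`, `r2`,
#'   `adj_r2`, `n`, plus the thresholds used. An empty model (no candidate
#'   passes `p_enter`) is returned with a warning.
#' @export
forward_stepwise <- function(data, response, candidates = NULL,
                             p_enter = 0.05, p_remove = 0.10) {
  if (is.null(candidates)) candidates <- setdiff(names(data), response)
  stopifnot(response %in% names(data), all(candidates %in% names(data)))
  d <- data[, c(response, candidates), drop = FALSE]
  ok <- stats::complete.cases(d)
  if (any(!ok)) {
    message("forward_stepwise: dropping ", sum(!ok), " incomplete rows")
  }
  d <- d[ok, , drop = FALSE]
  if (nrow(d) <= length(candidates) + 2L) {
    stop("need more rows than candidates + 2")
  }
  const <- vapply(d, function(col) stats::sd(col) == 0, logical(1))
  if (any(const[candidates])) {
    warning("dropping constant candidates: ",
            paste(candidates[const[candidates]], collapse = ", "))
    candidates <- candidates[!const[candidates]]
  }
  z <- as.data.frame(scale(d))

  coef_p <- function(included, term) {
    fml <- stats::reformulate(c(included, term), response)
    fit <- stats::lm(fml, data = z)
    stats::coef(summary(fit))[term, "Pr(>|t|)"]
  }
  included <- character(0)
  repeat {
    remaining <- setdiff(candidates, included)
    if (!length(remaining)) break
    pvals <- vapply(remaining, function(tm) coef_p(included, tm), numeric(1))
    if (min(pvals) >= p_enter) break
    included <- c(included, remaining[which.min(pvals)])
    # backward purge after each entry
    repeat {
      fit <- stats::lm(stats::reformulate(included, response), data = z)
      ps <- stats::coef(summary(fit))[-1, "Pr(>|t|)", drop = TRUE]
      names(ps) <- included
      if (max(ps) <= p_remove) break
      included <- setdiff(included, names(ps)[which.max(ps)])
      if (!length(included)) break
    }
    if (!length(included)) break
  }

  if (!length(included)) {
    warning("no candidate passed the entry threshold; empty model")
    return(structure(list(predictors = character(0), beta = numeric(0),
                          p_values = numeric(0), tolerance = numeric(0),
                          F = NA_real_, df = c(NA_real_, NA_real_),
                          r2 = NA_real_, adj_r2 = NA_real_, n = nrow(d),
                          p_enter = p_enter, p_remove = p_remove),
                     class = "stepwise_model"))
  }
  fit <- stats::lm(stats::reformulate(included, response), data = z)
  sm <- summary(fit)
  tab <- stats::coef(sm)[included, , drop = FALSE]
  tol <- vapply(included, function(v) {
    others <- setdiff(included, v)
    if (!length(others)) return(1)
    1 - summary(stats::lm(stats::reformulate(others, v), data = z))$r.squared
  }, numeric(1))
  structure(list(
    predictors = included,
    beta = stats::setNames(tab[, "Estimate"], included),
    p_values = stats::setNames(tab[, "Pr(>|t|)"], included),
    tolerance = tol,
    F = unname(sm$fstatistic["value"]),
    df = unname(sm$fstatistic[c("numdf", "dendf")]),
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared, n = nrow(d),
    p_enter = p_enter, p_remove = p_remove
  ), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (!length(x$predictors)) {
    cat("Stepwise model: no predictors entered\n")
    return(invisible(x))
  }
  cat(sprintf("Stepwise model (n = %d): F(%d, %d) = %.3f, adj R^2 = %.3f\n",
              x$n, x$df[1], x$df[2], x$F, x$adj_r2))
  for (v in x$predictors) {
    cat(sprintf("  %-20s Beta = %6.3f  p = %.3g  tol = %.3f\n",
                v, x$beta[[v]], x$p_values[[v]], x$tolerance[[v]]))
  }
  invisible(x)
}
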