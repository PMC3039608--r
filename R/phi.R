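# Discordance of continental replicability: Cramer's phi on the 2x2
# continent-by-outcome table of an association.

#' Cramer's phi for a 2x2 contingency table
#'
#' For a table with cells `a, b / c, d`,
#' `phi = |ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))`, equivalently the square
#' root of the *uncorrected* Pearson chi-square over the grand total. Here
#' the rows are continents (Europe, East Asia) and the columns positive and
#' negative study counts, so `phi = 0` means identical replicability in both
#' continents and `phi = 1` complete discordance (e.g. 0% vs 100%). A
#' continuity correction would destroy the `phi = 1` boundary case and is
#' deliberately not applied. Tables with a zero margin (e.g. every study
#' positive in both continents) carry no evidence of discordance and return
#' 0 by convention.
#'
#' @param table 2x2 non-negative numeric matrix.
#' @return phi in `[0, 1]`.
#' @examples
#' cramers_phi(matrix(c(7, 3, 7, 3), 2, byrow = TRUE))   # 0
#' cramers_phi(matrix(c(0, 10, 10, 0), 2, byrow = TRUE)) # 1
#' @export
cramers_phi <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(is.na(table)) || any(table < 0)) {
    stop("cells must be non-negative and non-missing")
  }
  if (sum(table) < 1) stop("grand total must be at least 1")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  abs(a * d - b * c) / sqrt(denom)
}

#' Continent-by-outcome contingency table of an association
#'
#' @param summary One row of a Continental-Set summary (from
#'   [build_continental_set()]), or a data frame from which the first row is
#'   used.
#' @return 2x2 integer matrix, rows `Europe`/`EastAsia`, columns
#'   `positive`/`negative`.
#' @export
continental_contingency <- function(summary) {
  need <- c("n_studies_eur", "n_positive_eur", "n_studies_eas", "n_positive_eas")
  stopifnot(all(need %in% names(summary)))
  s <- summary[1, , drop = FALSE]
  if (s$n_studies_eur < 1 || s$n_studies_eas < 1) {
    stop("both continents need at least one study (association does not ",
         "belong to the Continental Set)")
  }
  if (s$n_positive_eur > s$n_studies_eur || s$n_positive_eas > s$n_studies_eas) {
    stop("positive counts exceed study counts")
  }
  matrix(c(s$n_positive_eur, s$n_studies_eur - s$n_positive_eur,
           s$n_positive_eas, s$n_studies_eas - s$n_positive_eas),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("Europe", "EastAsia"), c("positive", "negative")))
}

#' Append the phi discordance index to a Continental-Set summary
#'
#' @param summaries Continental-Set data frame from
#'   [build_continental_set()].
#' @return `summaries` with a `phi` column.
#' @export
add_phi <- function(summaries) {
  summaries$phi <- vapply(seq_len(nrow(summaries)), function(i) {
    cramers_phi(continental_contingency(summaries[i, , drop = FALSE]))
  }, numeric(1))
  summaries
}
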