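---
title: "Methods: replicability discordance and population differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicability discordance and population differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifst)
```

## The question and the data model

A gene–disease association reported in one population frequently fails to
replicate in another. One candidate explanation is genuine heterogeneity of
genetic architecture: if the causal (or tagging) variation at a locus has
drifted or been selected to different frequencies on different continents, a
real association may be detectable in one population and absent in another.
`replifst` operationalises this by combining two data streams:

* **Study records** — one row per published association test: gene, disease,
  binary outcome (positive/negative), free-text sample ancestry, sample
  size, year, optionally the tested marker. These emulate the schema of
  curated association databases, which are gene-centred: the marker is
  recorded only sporadically.
* **Genotypes** — a SNP × sample diploid dosage matrix over continental
  population panels, with a SNP→gene map, annotation class
  (intronic/exonic/UTR), and outgroup alleles from two species for
  ancestral-state inference.

The analysis asks whether the *discordance* of replicability between Europe
and East Asia covaries with the genetic differentiation of the underlying
genes between those populations.

## Curation ladder

Records are normalised (free-text ancestry labels mapped to continent
categories via an explicit table; unknown labels become `Unassigned` and are
reported, never silently dropped) and pooled per (gene, disease) pair.

* *Global Set*: pairs studied at least 4 times anywhere. Replicability is
  the percentage of positive studies. The 4-study floor exists because a
  proportion estimated from fewer studies carries too little information.
* *Continental Set*: pairs with at least 4 studies in Europe **and** at
  least 4 in East Asia; only studies from those two continents enter the
  counts. Mixed-panel and unassigned records are excluded here but still
  count globally. A configurable disease drop list removes conditions
  endemic to one continent (e.g. region-specific infectious disease), which
  would confound the continental comparison.
* *Conservative filter*: keeps associations replicated at least 50% of the
  time (in at least one continent for the Continental Set). The threshold is
  inclusive: "at least 50%" keeps an association at exactly 50%. Disease
  synonym resolution is delegated to an explicit input table — no fuzzy
  matching, since silent merges are harder to audit than an explicit map.

## Discordance: Cramér's phi

For one association, the 2×2 table of continent (Europe / East Asia) by
outcome (positive / negative counts) yields
`phi = |ad − bc| / sqrt((a+b)(c+d)(a+c)(b+d))`, the square root of the
*uncorrected* chi-square over the total. The continuity correction is
deliberately omitted inside phi — it would destroy the boundary identity
phi = 1 for the fully discordant 0%-vs-100% table. Tables with a zero margin
(e.g. every study positive in both continents) show no variation in outcome
and therefore no demonstrable discordance; they are assigned phi = 0 by
declared convention, recorded in the run manifest, since an index of
discordance should not be undefined on concordant data.

```{r phi}
cramers_phi(matrix(c(7, 3, 7, 3), 2, byrow = TRUE))   # 70% vs 70%
cramers_phi(matrix(c(0, 10, 10, 0), 2, byrow = TRUE)) # 0% vs 100%
```

## Differentiation: Weir–Cockerham theta and gene aggregation

Per-SNP FST uses the Weir–Cockerham variance-components estimator in its
allele-count form (frequencies and sampled allele counts per population),
`theta = a / (a + b)`, which keeps the fixed-difference identity
`theta = 1` exactly and matches frequency-based AMOVA-style inputs.
Conventions, all surfaced in output metadata:

* **Negative thetas are retained.** The estimator is unbiased around 0 for
  undifferentiated SNPs only if its negative excursions are kept; clamping
  at 0 would bias gene means upward.
* **Pooled-monomorphic SNPs are undefined** and excluded from aggregates
  (this also makes gene aggregates invariant to removing SNPs monomorphic in
  both of the compared populations).
* **Population pooling.** Pairwise values are computed for each population
  pair and a global value over all panels with the same r-population
  formulas.

Gene-level aggregation supports mean, max, and tagSNP-mean pooling. The mean
is the package's primary gene statistic: the maximum is mechanically coupled
to the number of SNPs in a gene (more draws, higher maximum), a bias the
report quantifies by correlating SNP count with both aggregates. At the
sample sizes used here the *mean of per-SNP thetas* sits slightly below the
parametric divergence of the simulation (about 0.082 for a true 0.1 with 60
diploids per population): per-SNP ratios from low-information SNPs are
individually noisy and their average is pulled down, a known property of
averaging ratio estimators. The classical ratio-of-sums combination is
exposed as `fst_wc_multilocus()` and is close to unbiased; the per-SNP mean
remains the gene statistic because per-gene means over few, possibly
monomorphic SNPs are the object the downstream correlation analyses
consume.

tagSNPs are selected per population by a greedy set cover: SNPs are eligible
if call rate ≥ 75% and MAF ≥ 0.1; each round picks the eligible SNP tagging
(r² ≥ 0.8, composite genotypic LD, no phasing) the most untagged SNPs, ties
broken by lower genomic position; the final set is the intersection of the
per-population tag sets. The contract is coverage, not minimality — every
eligible non-tag SNP reaches r² ≥ 0.8 with some tag of its population's set
— which is what removing LD-induced pseudo-replication requires.

## Ancestral and derived alleles

The ancestral state of a SNP is inferred by parsimony: usable only when both
outgroup species agree and the shared allele matches one of the two human
alleles. If the outgroups agree on the *derived* human allele the polarity
flips — the inferred derived frequency becomes 1 − p — which is exactly how
a misleading outgroup state propagates in real parsimony calls; outgroup
disagreement or a third allele excludes the SNP. The major allele
(frequency ≥ 0.5) is classified ANC or DER per population. At frequency
exactly 0.5 neither allele is strictly major; the package applies the ≥
reading to the derived allele (configurable), a declared convention recorded
in the manifest. High- vs low-replicability strata (split at the median,
ties included in both strata, both stratum sizes always reported) are
compared on pooled ANC/DER counts with a Yates-corrected chi-square — the
correction is used *here* (unlike inside phi) because it is the convention
that reproduces published worked examples of this test to printed rounding.

## Resampling null and regression

Set-level differentiation of disease genes is tested by drawing 10,000
equally sized gene sets without replacement from the genome-wide pool and
counting sets with mean FST at least as extreme as observed (stated tail);
`k = 0` is reported as "< 1/N", the Monte-Carlo resolution bound, never as
p = 0 in prose.

Forward stepwise regression explains phi from eight candidates: mean
EUR–EAS gene FST plus seven confounders (SNP count, % intronic, total /
European / East Asian study counts, mean sample size, mean publication
year; the extreme-frequency percentage — SNPs rare on one continent, common
on the other — can be added as a ninth). Entry uses the smallest
probability-of-F below 0.05, followed by removal of any included predictor
above 0.10; these are the conventional defaults of the era's statistics
packages and are exposed as arguments, since the procedure's provenance
does not pin them. All variables are z-scored, so coefficients are
standardized Betas; per-predictor tolerance (1 − R² against the other
included predictors) diagnoses collinearity. The analysis is repeated
without the two largest genes (by SNP count), which otherwise contribute
most of the per-SNP observations. Per-SNP correlations duplicate the
gene-level phi across a gene's SNPs and are flagged as pseudo-replicated in
the report notes.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions for all recovery tests.

* **Populations**: EUR (60 diploids), EAS (90), AFR (60) — the unrelated-
  sample sizes of classic HapMap-style panels, with the two East Asian
  panels pooled for FST. Baseline divergence `F` = 0.10/0.10/0.15; the AFR
  value is higher because African vs non-African differentiation exceeds
  the within-Eurasia level in human data.
* **Frequencies**: ancestral frequency `p0 ~ Uniform(0.05, 0.95)` — bounded
  away from 0/1 so monomorphic SNPs arise only through sampling and must be
  handled downstream rather than dominating the panel; population
  frequencies from the Balding–Nichols beta distribution, whose parametric
  FST equals `F`, giving a closed-form recovery target.
* **Per-gene divergence**: a multiplier `m_g ~ Uniform(0.2, 2)` on `F`
  makes genes genuinely differ in expected FST, the variation the phi–FST
  correlation needs; `c(1, 1)` gives a homogeneous panel for estimator
  tests.
* **Genotypes**: `Binomial(2, p_k)` per diploid, 2% missing calls; two
  outgroup species each match the true ancestral allele except with error
  1%, errors drawn uniformly over the other three bases so the parsimony
  rule has both failure modes (agreement on the derived allele, and a
  third-allele exclusion).
* **Studies**: 8–12 per association per continent; outcome positive with
  probability 0.8 where causal (typical single-study power for a true
  moderate effect) and 0.05 otherwise (the conventional test level); sample
  sizes log-normal around 300, years 1995–2007. Half of the associations
  are heterogeneous (causal in exactly one continent, the others causal in
  both); with coupling strength s, heterogeneous associations are assigned
  to genes with weight `(1−s) + s·q²` in the divergence rank quantile `q`
  (homogeneous ones mirror-image), so s = 1 ties discordance to divergence
  and s = 0 severs it. The studies-per-association distribution is a
  configurable choice, not calibrated to any corpus, which only records a
  ≥ 4 filter.

What the generator does **not** emulate: linkage disequilibrium beyond
optionally duplicated SNP columns (no haplotype blocks, no recombination
map), coalescent demography, publication bias, disease-name noise and
synonymy, and the empirical distribution of studies per association.
Passing recovery tests therefore show the pipeline's statistics behave
correctly under the stated sampling model; they do not certify performance
on the messier dependence structure of real curation corpora.

## Numerical and reproducibility choices

* Every stage derives its RNG stream from the configuration seed plus a
  fixed stage offset, so each generator function is independently
  bit-reproducible and a rerun writes byte-identical report tables.
* Degenerate inputs have defined behaviour: empty record sets warn and
  return empty summaries; genes with no eligible SNPs yield empty tag sets
  with a message; associations with a zero margin get phi = 0; SNPs without
  a usable ancestral call are excluded, not guessed.
* Genomic coordinates are 0-based half-open internally; VCF positions are
  converted at the I/O boundary.
* Genes with fewer than 10 SNPs are masked from conservative mean-FST
  analyses (a mean over very few SNPs is an unreliable gene distance) but
  retained in per-SNP analyses.

Test problem sizes are chosen to exercise the statistics at meaningful
resolution while keeping the suite quick: estimator recovery uses 5,000
SNPs at 60 diploids per population; null calibration uses 200 repetitions
of a 1,000-draw resampling test over a 150-gene pool; parameter recovery
uses 40 associations with 8–12 studies per continent, and the
no-coupling control spans 50 replicate seeds.

## Known limitations

* The per-SNP-mean gene FST carries the small-sample downward pull
  discussed above; comparisons *between* genes (the package's use case) are
  unaffected because all genes share the estimator, but absolute values
  should not be read as unbiased divergence estimates.
* The greedy tagger guarantees coverage, not the minimal tag set, and the
  cross-population intersection can legitimately be empty for short or
  low-MAF genes.
* Per-SNP correlation rows are pseudo-replicated by construction and should
  be read as descriptive, as flagged in the report.
* Cramér's phi from 4–12 studies per continent is granular; with few
  studies it takes few distinct values, which is why rank-based
  correlations are used throughout.

```{r example, eval = FALSE}
report <- run_full_analysis(sim_config(seed = 1), n_resamples = 2000)
print(report)
report$correlations
```
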