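# Correlations, resampling null, median split, derived-allele test and
# forward stepwise regression.

test_that("Spearman correlation handles monotone and tied inputs", {
  x <- 1:10
  expect_equal(spearman_correlation(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  # 8-point fixture with ties against the average-rank formula
  a <- c(1, 2, 2, 3, 4, 4, 4, 5)
  b <- c(2, 1, 3, 3, 5, 4, 6, 7)
  manual_rho <- cor(rank(a), rank(b))
  res <- spearman_correlation(a, b)
  expect_equal(res$rho, manual_rho)
  tstat <- manual_rho * sqrt((8 - 2) / (1 - manual_rho^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 8 - 2))
  expect_error(spearman_correlation(1:3, 1:3), "at least 4")
})

test_that("resampling test is calibrated at the pool mean and bounded below it", {
  set.seed(10)
  pool <- rnorm(500, 0.1, 0.02) # symmetric pool
  res <- resampling_mean_fst_test(mean(pool), pool, set_size = 40,
                                  n_resamples = 2000, tail = "lower", seed = 1)
  expect_gt(res$p_value, 0.4)
  expect_lt(res$p_value, 0.6)
  res2 <- resampling_mean_fst_test(min(pool) - 0.01, pool, set_size = 40,
                                   n_resamples = 2000, tail = "lower", seed = 1)
  expect_equal(res2$p_value, 0)
  expect_match(res2$p_label, "^< ")
  expect_equal(res2$p_label, "< 0.0005") # 1/N resolution bound
  expect_error(resampling_mean_fst_test(0.1, pool, set_size = 500), "smaller")
  # seed-reproducible
  r1 <- resampling_mean_fst_test(0.1, pool, 40, 500, seed = 7)
  r2 <- resampling_mean_fst_test(0.1, pool, 40, 500, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("median split is inclusive of ties on both sides", {
  sp <- median_split(c(0, 50, 100))
  expect_equal(sp$median, 50)
  expect_equal(sp$low, c(0, 50))
  expect_equal(sp$high, c(50, 100))
  # with no tie at the median the strata partition the set
  df <- data.frame(gene = letters[1:4], disease = "d",
                   replicability_pct = c(10, 40, 60, 90))
  sp2 <- median_split(df)
  expect_equal(sp2$n_low + sp2$n_high, 4)
  expect_setequal(c(sp2$low$gene, sp2$high$gene), letters[1:4])
  expect_error(median_split(5), "at least 2")
})

test_that("derived-allele test is Yates-corrected and row-symmetric", {
  even <- matrix(c(800, 200, 1600, 400), 2, byrow = TRUE)
  res <- derived_allele_test(even)
  expect_lt(res$chi2, 0.01)
  expect_gt(res$p_value, 0.9)
  tab <- matrix(c(500, 120, 480, 160), 2, byrow = TRUE)
  expect_equal(derived_allele_test(tab)$chi2,
               derived_allele_test(tab[2:1, ])$chi2)
  # Yates correction: matches chisq.test with correct = TRUE, not without
  ref <- chisq.test(tab, correct = TRUE)
  expect_equal(derived_allele_test(tab)$p_value, ref$p.value)
  expect_false(isTRUE(all.equal(derived_allele_test(tab)$p_value,
                                chisq.test(tab, correct = FALSE)$p.value)))
})

test_that("stepwise recovers a single informative predictor", {
  set.seed(30)
  n <- 60
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 2 * d$x1 + rnorm(n, sd = 0.1)
  m <- forward_stepwise(d, "y", c("x1", "x2", "x3"))
  expect_equal(m$predictors[1], "x1")
  expect_gt(m$beta[["x1"]], 0.9) # standardized beta near 1
  expect_gt(m$adj_r2, 0.95)
})

test_that("orthogonal informative predictors both enter with high tolerance", {
  set.seed(31)
  n <- 80
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  d$y <- d$x1 + 0.8 * d$x2 + rnorm(n, sd = 0.4)
  m <- forward_stepwise(d, "y")
  expect_setequal(m$predictors, c("x1", "x2"))
  expect_true(all(m$tolerance > 0.9))
  expect_lte(m$adj_r2, m$r2)
})

test_that("stepwise is invariant to affine rescaling of predictors", {
  set.seed(32)
  n <- 50
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- d$x1 - 0.7 * d$x3 + rnorm(n, sd = 0.3)
  m1 <- forward_stepwise(d, "y")
  d2 <- d
  d2$x1 <- 1000 * d2$x1 + 5
  d2$x3 <- -0.01 * d2$x3
  m2 <- forward_stepwise(d2, "y")
  expect_equal(m2$predictors, m1$predictors)
  expect_equal(abs(unname(m2$beta)), abs(unname(m1$beta)), tolerance = 1e-8)
  expect_equal(m2$adj_r2, m1$adj_r2, tolerance = 1e-8)
})

test_that("pure-noise candidates give an empty model with a warning", {
  set.seed(33)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40), y = rnorm(40))
  expect_warning(m <- forward_stepwise(d, "y", c("x1", "x2")), "empty model")
  expect_length(m$predictors, 0)
})

test_that("stepwise selection matches the add1/drop1 oracle", {
  set.seed(34)
  for (rep_i in 1:12) {
    k <- sample(3:6, 1)
    n <- 45
    d <- as.data.frame(matrix(rnorm(n * k), n))
    names(d) <- paste0("x", 1:k)
    coefs <- runif(k, -1, 1) * rbinom(k, 1, 0.5)
    d$y <- as.matrix(d) %*% coefs + rnorm(n, sd = 0.7)
    m <- suppressWarnings(forward_stepwise(d, "y", paste0("x", 1:k)))
    oracle <- stepwise_oracle(d, "y", paste0("x", 1:k))
    expect_equal(m$predictors, oracle)
  }
})
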