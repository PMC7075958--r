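test_that("observed counts tally with multiplicity and respect the region", {
  m <- toy_map()
  D <- observed_counts(mutation_set(c(3, 3, 7)), m)
  expect_equal(unname(D), c(2L, 1L))
  expect_equal(unname(observed_counts(mutation_set(integer()), m)),
               c(0L, 0L))
  expect_error(observed_counts(mutation_set(11), m), "outside")
})

test_that("null resampling conserves counts and matches the binomial mean", {
  # tiling single domain: every bootstrap row sums to n
  r10 <- analysis_region(1, 10)
  mt <- domain_map("all", 1, 10, r10)
  nb <- bootstrap_null(r10, mt, n = 4, bootstrap_config(K = 200, seed = 3))
  expect_true(all(rowSums(nb$counts) == 4L))

  # one-fifth domain: column mean within 3 MC standard errors of n * 0.2
  m <- onefifth_map()
  cfg <- bootstrap_config(K = 10000, seed = 11)
  nb2 <- bootstrap_null(m$region, m, n = 10, cfg)
  se_mean <- sqrt(10 * 0.2 * 0.8 / cfg$K)
  expect_lt(abs(mean(nb2$counts[, 1]) - 2.0), 3 * se_mean)
  expect_true(all(nb2$counts >= 0 & nb2$counts <= 10))
  expect_true(all(rowSums(nb2$counts) <= 10))
})

test_that("resampling is reproducible from the seed", {
  m <- toy_map()
  a <- bootstrap_null(m$region, m, 5, bootstrap_config(K = 500, seed = 9))
  b <- bootstrap_null(m$region, m, 5, bootstrap_config(K = 500, seed = 9))
  d <- bootstrap_null(m$region, m, 5, bootstrap_config(K = 500, seed = 10))
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, d$counts))
  expect_error(bootstrap_null(m$region, m, 0, bootstrap_config(K = 10)),
               "empty")
})

test_that("without-replacement sampling is available for sensitivity analysis", {
  m <- toy_map()
  nb <- bootstrap_null(m$region, m, 10, bootstrap_config(K = 50, seed = 2),
                       replace = FALSE)
  expect_true(all(rowSums(nb$counts) == 10L))  # 10 of 10 residues, tiling
  expect_error(bootstrap_null(m$region, m, 11, bootstrap_config(K = 5),
                              replace = FALSE), "without replacement")
})

test_that("empirical p-values take the add-one form with the forced bounds", {
  null_col <- c(0L, 1L, 2L, 3L, 5L)
  K <- length(null_col)
  expect_equal(empirical_pvalue(0, null_col), 1)
  expect_equal(empirical_pvalue(max(null_col) + 1, null_col), 1 / (K + 1))
  # monotone non-increasing in the observed count
  ps <- vapply(0:6, empirical_pvalue, numeric(1), null_column = null_col)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 1 / (K + 1) & ps <= 1))
})

test_that("empirical p agrees with the exact binomial tail (single config)", {
  m <- onefifth_map()
  cfg <- bootstrap_config(K = 10000, seed = 17)
  nb <- bootstrap_null(m$region, m, n = 10, cfg)
  p_hat <- empirical_pvalue(6, nb$counts[, 1])
  b <- exact_binomial_pvalue(6, 10, 20, 100)
  target <- (1 + cfg$K * b) / (cfg$K + 1)
  mc_se <- sqrt(b * (1 - b) * cfg$K) / (cfg$K + 1)
  expect_lt(abs(p_hat - target), 3 * mc_se)
})

test_that("Bonferroni adjustment multiplies by J and caps at one", {
  expect_equal(adjust_bonferroni(0.004, 14), 0.056)
  expect_equal(adjust_bonferroni(0.2, 9), 1)
  expect_equal(adjust_bonferroni(1 / 10001, 14), 14 / 10001)
  p <- c(0.001, 0.02, 0.3)
  expect_equal(adjust_bonferroni(p), stats::p.adjust(p, "bonferroni"))
  expect_error(adjust_bonferroni(0), "0, 1")
})

test_that("the analytic binomial oracle matches direct enumeration", {
  expect_equal(exact_binomial_pvalue(0, 7, 3, 10), 1)
  expect_equal(exact_binomial_pvalue(4, 4, 50, 100), 1 / 16)
  # independent route: upper tail of the binomial CDF
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    L_X <- sample(50:1000, 1)
    L_j <- sample.int(L_X, 1)
    D <- sample(0:n, 1)
    expect_equal(exact_binomial_pvalue(D, n, L_j, L_X),
                 stats::pbinom(D - 1, n, L_j / L_X, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(exact_binomial_pvalue(5, 4, 1, 10), "0 <= D_j <= n")
  expect_error(exact_binomial_pvalue(1, 4, 11, 10), "L_j <= L_X")
})

test_that("the empirical expectation converges to the analytic mean in K", {
  m <- onefifth_map()
  for (K in c(100, 1000, 10000)) {
    nb <- bootstrap_null(m$region, m, n = 50, bootstrap_config(K = K,
                                                               seed = 23))
    se_mean <- sqrt(50 * 0.2 * 0.8 / K)
    expect_lt(abs(mean(nb$counts[, 1]) - 10), 3.5 * se_mean)
  }
})

test_that("the full pipeline flags a forced cluster and refuses empty input", {
  r <- analysis_region(1, 200)
  m <- domain_map(c("hot", "cold"), c(1, 101), c(20, 150), r)
  S <- mutation_set(c(rep(5L, 12), sample(21:200, 18)))
  res <- run_mhf(S, m, config = bootstrap_config(K = 2000, seed = 31))
  expect_s3_class(res, "hotspot_result")
  expect_true(res$significant[res$domain == "hot"])
  expect_false(res$significant[res$domain == "cold"])
  expect_equal(attr(res, "n"), 30L)
  expect_equal(attr(res, "K"), 2000L)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 2))

  df <- data.frame(variant = "A5V", class = "missense",
                   severity = "mild_bfne", stringsAsFactors = FALSE)
  expect_error(
    suppressWarnings(run_mhf(variant_catalog(df), m, r,
                             severity_filter = "nonpathogenic")),
    "empty mutation set")
})
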