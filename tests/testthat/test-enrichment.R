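test_that("odds ratios reproduce the published retention-table cells", {
  # complete-set multiple-copy cell: printed as 1.97 (two-decimal truncation)
  r1 <- category_odds_ratio(906, 1140, 9691, 14642)
  expect_equal(r1$odds, 1.978, tolerance = 1e-3)
  expect_equal(r1$odds_2dec, 1.97)
  expect_equal(100 * r1$p1, 79.5, tolerance = 0.05)

  # complete-set WGT cell: printed 1.45
  r2 <- category_odds_ratio(587, 1140, 6181, 14642)
  expect_equal(r2$odds_2dec, 1.45)
  expect_equal(100 * r2$p1, 51.5, tolerance = 0.05)

  # conserved-set multiple-copy cell: printed 2.18 (truncation of 2.188)
  r3 <- category_odds_ratio(561, 692, 9691, 14642)
  expect_equal(r3$odds_2dec, 2.18)

  # p1 = p2 gives odds exactly 1
  r4 <- category_odds_ratio(30, 100, 300, 1000)
  expect_equal(r4$odds, 1)

  expect_error(category_odds_ratio(0, 100, 300, 1000), "degenerate")
  expect_error(category_odds_ratio(100, 100, 300, 1000), "degenerate")
})

test_that("exact binomial tails match closed forms and enumeration", {
  expect_equal(binomial_enrichment(3, 3, 0.4), 0.4^3, tolerance = 1e-12)
  # enumeration oracle (log space to avoid overflow in the binomial weights)
  k <- 587; n <- 1140; p0 <- 6181 / 14642
  expect_equal(binomial_enrichment(k, n, p0),
               sum(exp(lchoose(n, k:n) + (k:n) * log(p0) +
                         (n - (k:n)) * log1p(-p0))),
               tolerance = 1e-12)
  # below expectation: upper tail at least 0.5
  expect_gte(binomial_enrichment(30, 100, 0.4), 0.5)
  # monotone decreasing in k
  ps <- vapply(40:60, binomial_enrichment, 1.0, n = 100, p0 = 0.5)
  expect_true(all(diff(ps) < 0))
})

test_that("published binomial p-values are reproduced by the two-sided test", {
  p0 <- 6181 / 14642
  r_complete <- category_odds_ratio(587, 1140, 6181, 14642)
  expect_equal(r_complete$p_value, 3.30e-10, tolerance = 0.01)
  r_conserved <- category_odds_ratio(355, 692, 6181, 14642)
  expect_equal(r_conserved$p_value, 1.71e-06, tolerance = 0.01)
})

test_that("pair-retention chi-square reproduces the published scenario", {
  res <- pair_retention_chi2(4292, 428, 120)
  expect_equal(res$expected_both, 4292 * (428 / 8584)^2, tolerance = 1e-9)
  expect_equal(res$expected_both, 10.67, tolerance = 1e-2)
  expect_lt(res$p_value, 2.2e-16)
  expect_equal(res$n_genes, 8584)

  # exact expectation: chi2 = 0, p = 1 when observed matches expectation
  q <- 0.5
  res0 <- pair_retention_chi2(100, 100, 25)
  expect_equal(res0$chi_sq, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)

  # brute-force recomputation on random instances
  set.seed(41)
  for (i in 1:5) {
    n_pairs <- sample(50:500, 1)
    m <- sample(10:(2 * n_pairs), 1)
    both_max <- min(n_pairs, floor(m / 2))
    both <- sample(0:both_max, 1)
    if (m - 2 * both > n_pairs - both) next
    res_i <- pair_retention_chi2(n_pairs, m, both)
    q_i <- m / (2 * n_pairs)
    e <- n_pairs * dbinom(0:2, 2, q_i)
    o <- c(n_pairs - both - (m - 2 * both), m - 2 * both, both)
    expect_equal(res_i$chi_sq, sum((o - e)^2 / e), tolerance = 1e-9)
  }
})

test_that("expected-both matches Monte-Carlo pair sampling", {
  n_pairs <- 300; m <- 90
  set.seed(7)
  sims <- replicate(2000, {
    genes <- sample(2 * n_pairs, m)   # which pair members are in the module
    pair_id <- (genes - 1) %/% 2
    sum(duplicated(pair_id))
  })
  expected <- n_pairs * (m / (2 * n_pairs))^2
  expect_lt(abs(mean(sims) - expected), 3 * sd(sims) / sqrt(2000) + 0.2)
})

test_that("upstream TE enrichment flags by inclusive window", {
  universe <- sprintf("g%04d", 1:2000)
  gene_set <- universe[1:200]
  # planted 3x insertion rate in the set
  set.seed(51)
  in_set <- sample(gene_set, 60)
  in_rest <- sample(setdiff(universe, gene_set), 180)
  ins <- tibble::tibble(
    gene = c(in_set, in_rest),
    family = "DTT-NIC1",
    distance = sample(0:1000, length(in_set) + length(in_rest), replace = TRUE)
  )
  res <- upstream_te_enrichment(gene_set, universe, ins, "DTT-NIC1")
  expect_lt(res$p_value, 0.01)
  expect_gt(res$odds, 1)

  # inclusive boundary at exactly the window size
  one <- tibble::tibble(gene = "g0001", family = "DTT-NIC1", distance = 1000)
  r1 <- upstream_te_enrichment(gene_set, universe, one, "DTT-NIC1")
  expect_equal(r1$k_set, 1)
  out <- tibble::tibble(gene = "g0001", family = "DTT-NIC1", distance = 1001)
  r2 <- upstream_te_enrichment(gene_set, universe, out, "DTT-NIC1")
  expect_equal(r2$k_set, 0)
  expect_equal(r2$p_value, 1)

  # wrong family never flags
  r3 <- upstream_te_enrichment(gene_set, universe, one, "OTHER")
  expect_equal(r3$k_genome, 0)
})

test_that("retention report assembles all rows with both precisions", {
  counts <- tibble::tibble(
    set = c("complete", "complete", "conserved"),
    category = c("multi", "wgt", "multi"),
    k_set = c(906, 587, 561), n_set = c(1140, 1140, 692),
    k_genome = c(9691, 6181, 9691), n_genome = 14642
  )
  rep <- retention_report(counts)
  expect_equal(rep$odds_2dec, c(1.97, 1.45, 2.18))
  expect_true(all(rep$p_value < 1e-5))
  expect_equal(names(rep)[1:2], c("set", "category"))
})
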