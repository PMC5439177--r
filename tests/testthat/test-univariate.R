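test_that("K-S statistic handles identical, disjoint, and overlapping samples", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4)),
               oracle_ks_d(c(1, 2, 3), c(2, 3, 4)))
  expect_error(ks_statistic(numeric(0), 1), "at least one")
})

test_that("K-S statistic equals the brute-force pooled-point maximum on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    # mix continuous values and heavy ties
    x <- if (i %% 3 == 0) sample(1:5, n1, TRUE) else rnorm(n1)
    y <- if (i %% 3 == 0) sample(1:5, n2, TRUE) else rnorm(n2, 0.3)
    d <- ks_statistic(x, y)
    expect_identical(d, oracle_ks_d(x, y))
    # independent reference implementation
    expect_equal(d, unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
  }
})

test_that("K-S statistic is invariant under strictly increasing transforms", {
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(15); y <- rnorm(12, 1)
    d <- ks_statistic(x, y)
    expect_equal(ks_statistic(exp(x), exp(y)), d)
    expect_equal(ks_statistic(atan(x), atan(y)), d)
    # Wilcoxon statistic shares the rank property
    expect_equal(rank_sum_test(x, y)$statistic,
                 rank_sum_test(exp(x), exp(y))$statistic)
  }
})

test_that("K-S decision matches permutation oracles", {
  # D = 0: no evidence at any level
  d0 <- ks_decision(0, 10, 10, alpha = 0.5)
  expect_equal(d0$p_value, 1)
  expect_false(d0$significant)

  # complete separation at n = 10/10: exactly 2 of choose(20,10)
  # assignments reach D = 1, so p = 2/184756 << 0.001
  d1 <- ks_decision(1, 10, 10, alpha = 0.001)
  expect_true(d1$significant)
  expect_equal(d1$p_value, 2 / choose(20, 10), tolerance = 1e-6)

  # Monte-Carlo permutation oracle at n = 50/50, D = 0.2
  set.seed(8)
  pooled <- rnorm(100)
  hits <- 0; nperm <- 20000
  for (i in seq_len(nperm)) {
    idx <- sample(100, 50)
    if (ks_statistic(pooled[idx], pooled[-idx]) >= 0.2 - 1e-12) hits <- hits + 1
  }
  expect_lt(abs(ks_decision(0.2, 50, 50)$p_value - hits / nperm), 0.02)

  expect_error(ks_decision(0.5, 10, 10, alpha = 0), "alpha")
  expect_error(ks_decision(1.5, 10, 10), "D must")
})

test_that("rank-sum test matches the exact enumeration oracle", {
  # identical samples: standardized statistic 0, p ~ 1
  res <- rank_sum_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(res$p_value, 0.9)
  expect_false(res$significant)

  # fully separated 5 vs 5: exact two-sided p is 2/252
  x <- 1:5; y <- 6:10
  expect_equal(oracle_wilcoxon_exact_p(x, y), 2 / 252)
  res <- rank_sum_test(x, y, alpha = 0.05)
  expect_true(res$significant)
  expect_equal(res$statistic, sum(1:5))

  # statistic is the rank sum of the smaller group, with midranks
  res <- rank_sum_test(c(2, 2, 4), c(1, 2, 3, 5))
  r <- rank(c(2, 2, 4, 1, 2, 3, 5))
  expect_equal(res$statistic, sum(r[1:3]))

  # all values identical: degenerate, never significant
  res <- rank_sum_test(rep(3, 5), rep(3, 6))
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  # approximate p close to the exact one on a small overlapping case
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5, 0.8)
    expect_lt(abs(rank_sum_test(x, y)$p_value - oracle_wilcoxon_exact_p(x, y)),
              0.05)
  }
})

test_that("Welch t test matches the direct formula oracle and is antisymmetric", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  res <- welch_t_test(x, y)
  ref <- oracle_welch(x, y)
  expect_equal(res$statistic, ref$t)
  expect_equal(res$p_value, ref$p)

  flipped <- welch_t_test(y, x)
  expect_equal(flipped$statistic, -res$statistic)
  expect_equal(flipped$p_value, res$p_value)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # zero variance in both groups
  degen <- welch_t_test(rep(2, 4), rep(2, 5))
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_value, 1)
})

test_that("filter_genes keeps gene order, handles alpha = 1 and constant genes", {
  set.seed(12)
  X <- cbind(matrix(rnorm(80), 20, 4), rep(5, 20))
  ds <- toy_dataset(X, rep(c("tumor", "normal"), each = 10),
                    gene_ids = c("a", "b", "c", "d", "flat"))
  for (tst in c("ks", "wilcoxon", "t")) {
    rep1 <- filter_genes(ds, tst, alpha = 1)
    expect_identical(rep1$gene_id, c("a", "b", "c", "d", "flat"))
    expect_equal(sum(rep1$significant), 5)  # alpha = 1 keeps every gene
    expect_length(selected_genes(rep1)$gene_ids, 5)

    rep05 <- filter_genes(ds, tst, alpha = 0.05)
    expect_false(rep05$significant[rep05$gene_id == "flat"])
    expect_equal(rep05$p_value[rep05$gene_id == "flat"], 1)
  }
  expect_error(filter_genes(ds, "ks", alpha = 0), "alpha")
})

test_that("selections are nested across significance levels", {
  sim <- simulate_expression(n_pos = 25, n_neg = 25, n_shift = 10,
                             shift_effect = 1, n_scale = 5, scale_ratio = 2,
                             n_redundant = 0, n_noise = 200, seed = 21)
  ds <- zscore_standardize(sim$data)
  alphas <- c(0.001, 0.005, 0.01, 0.05, 1)
  for (tst in c("ks", "wilcoxon", "t")) {
    sel <- lapply(alphas, function(a) {
      selected_genes(filter_genes(ds, tst, a))$gene_ids
    })
    for (i in seq_len(length(alphas) - 1)) {
      expect_true(all(sel[[i]] %in% sel[[i + 1]]))
    }
  }
})

test_that("filter reports serialize to TSV with stable order", {
  ds <- toy_dataset(matrix(rnorm(40), 10, 4), rep(c("A", "B"), 5))
  rep <- filter_genes(ds, "ks", 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_filter_report(rep, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_identical(names(back), c("gene_id", "statistic", "p_value", "significant"))
  expect_identical(back$gene_id, rep$gene_id)
  expect_equal(back$p_value, rep$p_value)
})
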