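test_that("symmetrical uncertainty matches its defining cases and is symmetric", {
  a <- c(0, 0, 1, 1)
  expect_equal(symmetric_uncertainty(a, a), 1)
  expect_equal(symmetric_uncertainty(a, 1 - a), 1)  # relabeling preserves MI
  expect_equal(symmetric_uncertainty(a, c(0, 1, 0, 1)), 0)  # factorizing joint
  expect_equal(symmetric_uncertainty(a, rep(1, 4)), 0)      # constant input

  set.seed(31)
  for (i in 1:25) {
    x <- sample(1:4, 30, TRUE); y <- sample(1:3, 30, TRUE)
    expect_identical(symmetric_uncertainty(x, y), symmetric_uncertainty(y, x))
    su <- symmetric_uncertainty(x, y)
    expect_gte(su, 0); expect_lte(su, 1)
  }
})

test_that("MDL discretization finds informative cuts and rejects noise", {
  set.seed(32)
  y <- rep(c(0, 1), each = 40)
  x <- rnorm(80, mean = 3 * y)  # one clear boundary
  codes <- discretize_mdl(x, y)
  expect_length(attr(codes, "cuts"), 1)
  expect_gt(symmetric_uncertainty(codes, y), 0.5)

  noise <- rnorm(80)
  codes_n <- discretize_mdl(noise, y)
  expect_length(attr(codes_n, "cuts"), 0)  # single bin: no class information
  expect_equal(symmetric_uncertainty(codes_n, y), 0)

  # equal-frequency fallback
  q <- discretize_quantile(rnorm(100), bins = 10)
  expect_equal(length(unique(q)), 10)
  expect_true(all(table(q) == 10))
})

test_that("CFS merit follows its algebra", {
  expect_equal(cfs_merit(numeric(0)), 0)
  expect_equal(cfs_merit(0.8), 0.8)  # k = 1 reduces to r_cf
  # perfect duplicate never raises merit
  expect_equal(cfs_merit(c(0.8, 0.8), 1), 0.8)
  # an irrelevant uncorrelated gene lowers merit
  expect_equal(cfs_merit(c(0.8, 0), 0), 0.8 / sqrt(2))
  # matrix and scalar mean forms agree
  R <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(cfs_merit(c(0.6, 0.5), R), cfs_merit(c(0.6, 0.5), 0.3))
})

test_that("best-first search attains the exhaustive-subset maximum merit", {
  set.seed(33)
  for (i in 1:25) {
    p <- sample(4:9, 1)
    X <- matrix(rnorm(40 * p), 40, p)
    y <- rep(c("a", "b"), each = 20)
    k <- sample(0:3, 1)
    if (k > 0) X[y == "b", seq_len(k)] <- X[y == "b", seq_len(k)] + 0.8
    ds <- toy_dataset(X, y)
    sel <- cfs_select(ds, locally_predictive = FALSE)
    assoc <- oracle_cfs_assoc(ds)
    expect_equal(sel$params$merit, oracle_max_merit(assoc$rcf, assoc$rff),
                 tolerance = 1e-9)
  }
})

test_that("CFS finds a perfectly predictive gene among noise", {
  set.seed(34)
  y <- rep(c("tumor", "normal"), each = 40)
  X <- cbind(ifelse(y == "tumor", 1, -1) + rnorm(80, 0, 0.1),
             matrix(rnorm(80 * 20), 80, 20))
  ds <- toy_dataset(X, y, gene_ids = c("marker", paste0("n", 1:20)))
  sel <- cfs_select(ds)
  expect_true("marker" %in% sel$gene_ids)
  expect_lt(length(sel$gene_ids), 10)
})

test_that("CFS keeps at most one member of each duplicate group and covers distinct signals", {
  sim <- simulate_expression(n_pos = 40, n_neg = 40, n_shift = 3,
                             shift_effect = 2, n_scale = 0, n_redundant = 3,
                             redundancy_noise = 0.05, n_noise = 50, seed = 35)
  ds <- zscore_standardize(sim$data)
  sel <- cfs_select(ds)
  gi <- sim$gene_info
  signals <- gi$signal_id[match(sel$gene_ids, gi$gene_id)]
  expect_gte(length(unique(na.omit(signals))), 2)
  expect_false(any(duplicated(na.omit(signals))))
  # the univariate filter, by contrast, keeps whole duplicate groups
  ks_sel <- selected_genes(filter_genes(ds, "ks", 0.01))$gene_ids
  expect_true(all(gi$gene_id[!is.na(gi$signal_id)] %in% ks_sel))
})

test_that("CFS on all-constant candidates warns and returns an empty subset", {
  ds <- toy_dataset(matrix(2, 10, 3), rep(c("A", "B"), 5))
  expect_warning(sel <- cfs_select(ds), "class association")
  expect_length(sel$gene_ids, 0)
})

test_that("mRMR ranking matches the greedy oracle and penalizes duplicates", {
  set.seed(36)
  y <- rep(c(0, 1), each = 30)
  strong <- rnorm(60, 2 * y)
  dup <- strong + rnorm(60, 0, 0.05)
  moderate <- rnorm(60, 1.2 * y)
  ds <- toy_dataset(cbind(strong, dup, moderate, matrix(rnorm(60 * 9), 60, 9)),
                    ifelse(y == 1, "tumor", "normal"),
                    gene_ids = c("strong", "dup", "moderate", paste0("n", 1:9)))
  ranked <- mrmr_rank(ds, k = 12)
  # first gene maximizes mutual information with the class
  expect_identical(ranked$gene_id[1], "strong")
  # the near-duplicate ranks below the independent moderately relevant gene
  expect_lt(match("moderate", ranked$gene_id), match("dup", ranked$gene_id))

  # full ranking equals an independent greedy recursion
  codes <- lapply(gene_columns(ds), function(g) {
    x <- ds[[g]]
    as.integer(x > mean(x) + sd(x)) - as.integer(x < mean(x) - sd(x)) + 2L
  })
  oracle_order <- oracle_mrmr_order(codes, y, 12)
  expect_identical(ranked$gene_id, gene_columns(ds)[oracle_order])

  # invariant to candidate input order
  ranked2 <- mrmr_rank(ds, candidates = rev(gene_columns(ds)), k = 12)
  expect_identical(ranked2$gene_id, ranked$gene_id)
})

test_that("ReliefF weights equal a direct implementation on a toy dataset", {
  set.seed(37)
  X <- matrix(rnorm(18), 6, 3)
  X[, 1] <- c(1, 1.2, 0.9, -1, -1.1, -0.8)  # separates the classes
  X[, 3] <- 5                                # constant gene
  y <- c("A", "A", "A", "B", "B", "B")
  ds <- toy_dataset(X, y)
  ranked <- relieff_rank(ds, k_neighbors = 2)
  w_oracle <- oracle_relieff(X, y, 2)
  ord <- order(-w_oracle, seq_len(3))
  expect_equal(ranked$score, w_oracle[ord], tolerance = 1e-12)
  expect_identical(ranked$gene_id, paste0("g", ord))
  expect_equal(ranked$score[ranked$gene_id == "g3"], 0)  # constant gene
  expect_identical(ranked$gene_id[1], "g1")

  expect_error(relieff_rank(ds, k_neighbors = 3), "k_neighbors")
})

test_that("ReliefF ranks shift genes above all noise genes", {
  sim <- simulate_expression(n_pos = 50, n_neg = 50, n_shift = 5,
                             shift_effect = 2, n_scale = 0, n_redundant = 0,
                             n_noise = 30, seed = 38)
  ds <- zscore_standardize(sim$data)
  ranked <- relieff_rank(ds, k_neighbors = 10)
  shift_ids <- sim$gene_info$gene_id[sim$gene_info$role == "shift"]
  expect_setequal(ranked$gene_id[1:5], shift_ids)
  # scores nonincreasing
  expect_true(all(diff(ranked$score) <= 1e-12))
})

test_that("forward selection follows the strict-improvement rule", {
  ranked <- c("a", "b", "c", "d", "e")
  target <- c("a", "c", "e")
  sel <- forward_select(ranked, function(ids) sum(ids %in% target))
  expect_identical(sel$gene_ids, target)

  # constant evaluator: ties never grow the subset
  sel0 <- forward_select(ranked, function(ids) 42)
  expect_identical(sel0$gene_ids, "a")
  expect_equal(sel0$params$accuracy, 42)

  expect_error(forward_select(character(0), function(ids) 1), "empty")
})
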