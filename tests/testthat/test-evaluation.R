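make_separable <- function(seed = 51) {
  sim <- simulate_expression(n_pos = 30, n_neg = 30, n_shift = 10,
                             shift_effect = 6, n_scale = 0, n_redundant = 0,
                             n_noise = 40, seed = seed)
  list(data = zscore_standardize(sim$data),
       informative = sim$gene_info$gene_id[sim$gene_info$role == "shift"])
}

test_that("cross-validation is deterministic and perfect on separable data", {
  sep <- make_separable()
  cv <- svm_cv_accuracy(sep$data, sep$informative, folds = 10, seed = 4)
  expect_equal(nrow(cv), 10)
  expect_true(all(cv$accuracy == 100))
  expect_equal(sum(cv$n_test), nrow(sep$data))

  cv2 <- svm_cv_accuracy(sep$data, sep$informative, folds = 10, seed = 4)
  expect_identical(cv, cv2)

  expect_error(svm_cv_accuracy(sep$data, character(0)), "empty")
  expect_error(svm_cv_accuracy(sep$data, "no_such_gene"), "not in data")
})

test_that("fold count is reduced with a warning when a class is small", {
  ds <- toy_dataset(matrix(rnorm(10 * 4), 10, 4),
                    c(rep("A", 6), rep("B", 4)))
  expect_warning(cv <- svm_cv_accuracy(ds, c("g1", "g2"), folds = 10, seed = 1),
                 "reducing folds")
  expect_equal(nrow(cv), 4)
})

test_that("accuracy on label-permuted data is near chance", {
  sep <- make_separable(52)
  accs <- vapply(1:10, function(r) {
    ds <- sep$data
    ds$class <- withr::with_seed(90 + r, sample(ds$class))
    ev <- repeated_shuffle_evaluation(ds, function(d) sep$informative,
                                      folds = 10, repeats = 1, base_seed = 17)
    ev$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 15)
})

test_that("repeats = 1 reduces to one CV run of the selector's subset", {
  sep <- make_separable(53)
  sel_fun <- function(d) selected_genes(filter_genes(d, "ks", 0.01))
  ev <- repeated_shuffle_evaluation(sep$data, sel_fun, folds = 5, repeats = 1,
                                    base_seed = 40)
  # replicate the protocol by hand for the single repeat
  perm <- withr::with_seed(41, sample(nrow(sep$data)))
  shuffled <- sep$data[perm, ]
  cv <- svm_cv_accuracy(shuffled, sel_fun(shuffled), folds = 5, seed = 41)
  expect_equal(ev$accuracies$accuracy, cv$accuracy)
  expect_equal(nrow(ev$accuracies), 5)

  # end-to-end determinism
  ev2 <- repeated_shuffle_evaluation(sep$data, sel_fun, folds = 5, repeats = 1,
                                     base_seed = 40)
  expect_equal(tidy(ev), tidy(ev2))
  expect_equal(glance(ev), glance(ev2))
})

test_that("per-fold selection never sees the held-out samples", {
  sep <- make_separable(54)
  seen <- list()
  spy <- function(d) {
    seen[[length(seen) + 1]] <<- d$sample_id
    sep$informative
  }
  ev <- repeated_shuffle_evaluation(sep$data, spy, folds = 5, repeats = 1,
                                    base_seed = 7, per_fold = TRUE)
  expect_length(seen, 5)
  n <- nrow(sep$data)
  for (ids in seen) {
    expect_lt(length(ids), n)  # strictly a training subset
  }
  # every sample is held out exactly once across folds
  held_out <- lapply(seen, function(ids) setdiff(sep$data$sample_id, ids))
  expect_setequal(unlist(held_out), sep$data$sample_id)
  expect_equal(sum(lengths(held_out)), n)
})

test_that("empty selections are recorded as failed repeats and excluded", {
  sep <- make_separable(55)
  flip <- local({
    i <- 0
    function(d) {
      i <<- i + 1
      if (i == 2) character(0) else sep$informative
    }
  })
  expect_warning(
    ev <- repeated_shuffle_evaluation(sep$data, flip, folds = 5, repeats = 3,
                                      base_seed = 3),
    "empty subset"
  )
  expect_equal(sum(ev$repeats$failed), 1)
  expect_equal(nrow(ev$accuracies), 10)  # 2 good repeats x 5 folds
  expect_equal(glance(ev)$n_failed, 1)
})

test_that("evaluation serializes to TSV plus JSON summary", {
  sep <- make_separable(56)
  ev <- repeated_shuffle_evaluation(sep$data, function(d) sep$informative,
                                    folds = 4, repeats = 2, base_seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation(ev, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 8)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$mean_accuracy, ev$mean_accuracy)
  expect_equal(js$repeats, 2)
})
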