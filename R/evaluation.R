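#' Stratified cross-validated accuracy of a linear SVM on a gene subset
#'
#' Evaluates how well a gene subset separates the two classes: samples are
#' split into `folds` stratified folds (seeded, so the split is
#' reproducible), a support vector machine with linear kernel and fixed
#' penalty C = 1 is trained on each training fold restricted to the
#' subset's genes, and the held-out fold is scored. Accuracy is the
#' percentage of correctly classified test samples.
#'
#' If the smaller class has fewer than `folds` samples the fold count is
#' reduced to it, with a warning.
#'
#' @param data Dataset tibble.
#' @param genes A [gene_subset()], `ranked_genes`, or character vector
#'   (nonempty).
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @param class_col,positive Class column and orientation.
#' @return A tibble with one row per fold: `fold`, `n_test`, `accuracy`
#'   (percent). Mean accuracy is `mean(result$accuracy)`.
#' @export
svm_cv_accuracy <- function(data, genes, folds = 10, seed = 1,
                            class_col = "class", positive = NULL) {
  ids <- as_gene_ids(genes)
  if (length(ids) == 0) abort("gene subset is empty")
  ci <- class_info(data, class_col, positive)
  missing <- setdiff(ids, gene_columns(data, class_col))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) not in data: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  min_class <- min(ci$n_pos, ci$n_neg)
  if (min_class < folds) {
    warn(sprintf("reducing folds from %d to %d (smallest class size)",
                 folds, min_class))
    folds <- min_class
  }
  X <- as.matrix(data[ids])
  y <- factor(ifelse(ci$is_pos, "pos", "neg"), levels = c("neg", "pos"))
  fold_id <- make_stratified_folds(ci$is_pos, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    test <- fold_id == f
    fit <- e1071::svm(X[!test, , drop = FALSE], y[!test],
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, X[test, , drop = FALSE])
    100 * mean(pred == y[test])
  }, numeric(1))
  tibble(fold = seq_len(folds),
         n_test = as.integer(tabulate(fold_id, folds)),
         accuracy = acc)
}

# Seeded stratified fold assignment: within each class, samples are
# permuted and dealt round-robin across folds.
make_stratified_folds <- function(is_pos, folds, seed) {
  fold_id <- integer(length(is_pos))
  with_local_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      members <- which(is_pos == cls)
      perm <- sample(members)
      fold_id[perm] <- rep(seq_len(folds), length.out = length(members))
    }
  })
  fold_id
}

#' Build a cross-validated SVM evaluator for forward selection
#'
#' Returns a function mapping a character vector of gene ids to the mean
#' cross-validated linear-SVM accuracy on `data`, suitable as the
#' `evaluator` of [forward_select()].
#'
#' @inheritParams svm_cv_accuracy
#' @return A function `character -> numeric` (mean accuracy in percent).
#' @export
svm_evaluator <- function(data, folds = 10, seed = 1, class_col = "class",
                          positive = NULL) {
  force(data); force(folds); force(seed); force(class_col); force(positive)
  function(ids) {
    mean(svm_cv_accuracy(data, ids, folds = folds, seed = seed,
                         class_col = class_col, positive = positive)$accuracy)
  }
}

#' Repeated-shuffle evaluation of a selection method
#'
#' The evaluation protocol used throughout the package's comparisons: for
#' each repeat, the sample order is reshuffled (seed `base_seed + r`), the
#' selector is re-run on the shuffled dataset, and the selected subset is
#' scored by stratified k-fold linear-SVM cross-validation
#' ([svm_cv_accuracy()]). Reported are all per-(repeat, fold) accuracies,
#' their mean, and the mean selected-gene count over repeats.
#'
#' By default the selector sees the full shuffled dataset and
#' cross-validation follows — selection happens once, outside the fold
#' loop. That matches the protocol the package's comparison tables mirror,
#' but lets the selector peek at samples that later serve as test folds,
#' which optimistically biases accuracy. `per_fold = TRUE` instead re-runs
#' the selector inside each fold on the training samples only — the
#' methodologically cleaner, slower variant.
#'
#' @param data Dataset tibble.
#' @param selector Function taking a dataset tibble and returning a
#'   [gene_subset()] (or character vector). A repeat in which the
#'   selector returns an empty subset is recorded as failed and excluded
#'   from the means.
#' @param folds,repeats Cross-validation folds and shuffle repeats.
#' @param base_seed Integer; repeat r uses seed `base_seed + r`.
#' @param per_fold Re-run selection inside each training fold.
#' @param class_col,positive Class column and orientation.
#' @return An object of class `gene_eval`; see [tidy.gene_eval()] and
#'   [glance.gene_eval()].
#' @export
repeated_shuffle_evaluation <- function(data, selector, folds = 10,
                                        repeats = 10, base_seed = 1,
                                        per_fold = FALSE,
                                        class_col = "class", positive = NULL) {
  if (repeats < 1) abort("repeats must be >= 1")
  stopifnot(is.function(selector))
  acc_rows <- list()
  rep_rows <- list()
  for (r in seq_len(repeats)) {
    seed_r <- base_seed + r
    perm <- with_local_seed(seed_r, sample(nrow(data)))
    shuffled <- data[perm, , drop = FALSE]
    if (per_fold) {
      res <- per_fold_eval(shuffled, selector, folds, seed_r, class_col, positive)
      failed <- res$failed
      acc <- res$acc
      n_genes <- res$n_genes
    } else {
      sel <- selector(shuffled)
      ids <- as_gene_ids(sel)
      failed <- length(ids) == 0
      if (!failed) {
        cv <- svm_cv_accuracy(shuffled, ids, folds = folds, seed = seed_r,
                              class_col = class_col, positive = positive)
        acc <- cv$accuracy
      }
      n_genes <- length(ids)
    }
    if (failed) {
      warn(sprintf("repeat %d: selector returned an empty subset; excluded", r))
      rep_rows[[r]] <- tibble(rep = r, n_genes = NA_integer_, failed = TRUE)
    } else {
      acc_rows[[r]] <- tibble(rep = r, fold = seq_along(acc), accuracy = acc)
      rep_rows[[r]] <- tibble(rep = r, n_genes = as.integer(round(n_genes)),
                              failed = FALSE)
    }
  }
  accuracies <- dplyr::bind_rows(acc_rows)
  repeats_tbl <- dplyr::bind_rows(rep_rows)
  structure(
    list(accuracies = accuracies, repeats = repeats_tbl,
         mean_accuracy = if (nrow(accuracies)) mean(accuracies$accuracy) else NA_real_,
         mean_n_genes = mean(repeats_tbl$n_genes[!repeats_tbl$failed]),
         folds = folds, n_repeats = repeats, base_seed = base_seed,
         per_fold = per_fold),
    class = "gene_eval"
  )
}

# Stricter variant: selection re-run on each training fold.
per_fold_eval <- function(data, selector, folds, seed, class_col, positive) {
  ci <- class_info(data, class_col, positive)
  folds <- min(folds, ci$n_pos, ci$n_neg)
  fold_id <- make_stratified_folds(ci$is_pos, folds, seed)
  acc <- numeric(folds)
  sizes <- numeric(folds)
  for (f in seq_len(folds)) {
    train <- data[fold_id != f, , drop = FALSE]
    test <- data[fold_id == f, , drop = FALSE]
    ids <- as_gene_ids(selector(train))
    if (length(ids) == 0) {
      return(list(failed = TRUE, acc = numeric(0), n_genes = 0))
    }
    ciw <- class_info(train, class_col, positive)
    fit <- e1071::svm(as.matrix(train[ids]),
                      factor(ifelse(ciw$is_pos, "pos", "neg"),
                             levels = c("neg", "pos")),
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, as.matrix(test[ids]))
    truth <- ifelse(as.character(test[[class_col]]) == ciw$positive, "pos", "neg")
    acc[f] <- 100 * mean(as.character(pred) == truth)
    sizes[f] <- length(ids)
  }
  list(failed = FALSE, acc = acc, n_genes = mean(sizes))
}

#' @export
print.gene_eval <- function(x, ...) {
  cat(sprintf(
    "<gene_eval> %d repeat(s) x %d-fold linear-SVM CV (C = 1)\n",
    x$n_repeats, x$folds))
  cat(sprintf("  mean accuracy: %.1f%%   mean genes: %.1f   failed repeats: %d\n",
              x$mean_accuracy, x$mean_n_genes, sum(x$repeats$failed)))
  invisible(x)
}

#' Tidy a repeated-shuffle evaluation
#'
#' @param x A `gene_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per (repeat, fold): `rep`, `fold`,
#'   `accuracy`.
#' @method tidy gene_eval
#' @export
tidy.gene_eval <- function(x, ...) x$accuracies

#' One-row summary of a repeated-shuffle evaluation
#'
#' @param x A `gene_eval` object.
#' @param ... Unused.
#' @return Tibble with `mean_accuracy`, `mean_n_genes`, `folds`,
#'   `repeats`, `n_failed`, `base_seed`.
#' @method glance gene_eval
#' @export
glance.gene_eval <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, mean_n_genes = x$mean_n_genes,
         folds = x$folds, repeats = x$n_repeats,
         n_failed = sum(x$repeats$failed), base_seed = x$base_seed)
}

#' @method autoplot gene_eval
#' @export
autoplot.gene_eval <- function(object, ...) {
  ggplot2::ggplot(object$accuracies,
                  ggplot2::aes(x = factor(.data$rep), y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "shuffle repeat", y = "fold accuracy (%)",
                  title = sprintf("Mean accuracy %.1f%% over %d x %d-fold CV",
                                  object$mean_accuracy, object$n_repeats,
                                  object$folds)) +
    ggplot2::theme_minimal()
}

#' Write an evaluation to TSV and JSON summary
#'
#' Per-(repeat, fold) accuracies go to `path` (TSV) and the one-row
#' summary ([glance.gene_eval()]) to `<path>.json`.
#'
#' @param x A `gene_eval`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(x, path) {
  stopifnot(inherits(x, "gene_eval"))
  readr::write_tsv(x$accuracies, path, progress = FALSE)
  jsonlite::write_json(as.list(glance(x)), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
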