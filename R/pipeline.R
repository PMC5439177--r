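#' Two-stage gene selection: K-S filter then CFS
#'
#' The package's core algorithm. Stage 1 applies the per-gene two-sample
#' Kolmogorov-Smirnov filter at level `alpha` ([filter_genes()]),
#' discarding genes whose class-conditional distributions show no
#' significant difference and thereby shrinking the problem CFS has to
#' search. Stage 2 runs CFS with best-first search ([cfs_select()]) over
#' the surviving candidates to remove redundancy and return a compact
#' subset. The result's parent chain records the stage-1 candidate set,
#' and every returned gene is, by construction, K-S significant at
#' `alpha`.
#'
#' @param data Dataset tibble.
#' @param alpha Stage-1 significance level (default 0.01, the level the
#'   full pipeline is normally run at).
#' @param class_col,positive Class column and orientation.
#' @param ... Passed to [cfs_select()] (e.g. `discretizer`, `stall`).
#' @return A [gene_subset()] with method `"ks_cfs"`. If stage 1 selects
#'   nothing, an empty subset is returned with a warning naming `alpha`.
#' @export
ks_cfs_select <- function(data, alpha = 0.01, class_col = "class",
                          positive = NULL, ...) {
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  report <- filter_genes(data, test = "ks", alpha = alpha,
                         class_col = class_col, positive = positive)
  stage1 <- selected_genes(report)
  if (length(stage1) == 0) {
    warn(sprintf("K-S filter at alpha = %g selected no genes; returning empty subset",
                 alpha))
    return(gene_subset(character(0), method = "ks_cfs",
                       params = list(alpha = alpha), parent = stage1))
  }
  out <- cfs_select(data, candidates = stage1, class_col = class_col,
                    positive = positive, ...)
  gene_subset(out$gene_ids, method = "ks_cfs",
              params = c(list(alpha = alpha), out$params),
              parent = stage1)
}

# Selector factories shared by the comparison runners and the CLI. Each
# returns a function(data) -> gene_subset closing over the configuration.
method_selector <- function(method = c("ks_cfs", "cfs", "ks", "wilcoxon", "t",
                                       "mrmr", "relieff"),
                            alpha = 0.01, top_k = 50, folds = 10, seed = 1,
                            prescreen = FALSE, class_col = "class",
                            positive = NULL) {
  method <- match.arg(method)
  force(alpha); force(top_k); force(folds); force(seed); force(prescreen)
  candidates_for <- function(data) {
    if (!prescreen) return(NULL)
    selected_genes(filter_genes(data, "ks", alpha, class_col, positive))
  }
  switch(method,
    ks_cfs = function(data) ks_cfs_select(data, alpha, class_col, positive),
    cfs = function(data) cfs_select(data, candidates = candidates_for(data),
                                    class_col = class_col, positive = positive),
    ks = function(data) selected_genes(
      filter_genes(data, "ks", alpha, class_col, positive)),
    wilcoxon = function(data) selected_genes(
      filter_genes(data, "wilcoxon", alpha, class_col, positive)),
    t = function(data) selected_genes(
      filter_genes(data, "t", alpha, class_col, positive)),
    mrmr = function(data) {
      ranked <- mrmr_rank(data, candidates = candidates_for(data), k = top_k,
                          class_col = class_col, positive = positive)
      forward_select(ranked, svm_evaluator(data, folds, seed, class_col, positive))
    },
    relieff = function(data) {
      ranked <- relieff_rank(data, candidates = candidates_for(data), k = top_k,
                             class_col = class_col, positive = positive)
      forward_select(ranked, svm_evaluator(data, folds, seed, class_col, positive))
    }
  )
}

#' Significance-level sweep of the univariate filters
#'
#' For each test and each significance level: the number of genes the
#' filter keeps and the cross-validated linear-SVM accuracy of the kept
#' subset under the repeated-shuffle protocol. At `alpha = 1` every gene
#' is kept, giving the all-genes baseline, and for each test the kept
#' sets are nested as alpha decreases, so the counts are monotone along
#' the sweep.
#'
#' @param data Dataset tibble.
#' @param tests Subset of `c("ks", "wilcoxon", "t")`.
#' @param alphas Significance levels to sweep.
#' @param folds,repeats,base_seed Evaluation protocol parameters
#'   (defaults: 10-fold, 1 repeat).
#' @param class_col,positive Class column and orientation.
#' @return A `comparison_report` tibble: `test`, `alpha`, `n_genes`,
#'   `mean_accuracy`.
#' @export
run_alpha_sweep <- function(data, tests = c("ks", "wilcoxon", "t"),
                            alphas = c(1, 0.05, 0.01, 0.005, 0.001),
                            folds = 10, repeats = 1, base_seed = 1,
                            class_col = "class", positive = NULL) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (length(alphas) == 0) abort("alphas must be nonempty")
  grid <- expand.grid(alpha = alphas, test = tests,
                      stringsAsFactors = FALSE)[, c("test", "alpha")]
  rows <- purrr::map2(grid$test, grid$alpha, function(tst, a) {
      sel <- method_selector(tst, alpha = a, class_col = class_col,
                             positive = positive)
      ev <- repeated_shuffle_evaluation(data, sel, folds = folds,
                                        repeats = repeats,
                                        base_seed = base_seed,
                                        class_col = class_col,
                                        positive = positive)
      tibble(test = tst, alpha = a, n_genes = ev$mean_n_genes,
             mean_accuracy = ev$mean_accuracy)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("comparison_report", class(out)),
            kind = "alpha_sweep")
}

#' Head-to-head comparison of selection methods
#'
#' Runs each requested method through the repeated-shuffle evaluation
#' protocol on the same dataset and reports the mean selected-gene count
#' and mean cross-validated accuracy per method — one row per method,
#' mirroring the structure of a methods-comparison table. The ranking
#' methods (`mrmr`, `relieff`) rank the top `top_k` genes and then grow a
#' subset by SVM-guided forward selection; `cfs`, `mrmr`, and `relieff`
#' run on the full gene set by default, or on the K-S prescreened
#' candidates at `alpha` when `prescreen = TRUE`.
#'
#' A selector failure (empty selection) on some repeat is recorded for
#' that method, not fatal to the run.
#'
#' @param data Dataset tibble.
#' @param methods Subset of
#'   `c("ks_cfs", "cfs", "ks", "mrmr", "relieff", "wilcoxon", "t")`.
#' @param alpha Stage-1 / filter significance level (default 0.01).
#' @param top_k Ranked-list cutoff for `mrmr`/`relieff` (default 50).
#' @param folds,repeats,base_seed Evaluation protocol parameters.
#' @param prescreen Run `cfs`/`mrmr`/`relieff` on K-S prescreened
#'   candidates instead of the full gene set.
#' @param class_col,positive Class column and orientation.
#' @return A `comparison_report` tibble: `method`, `n_genes`,
#'   `mean_accuracy`, `n_failed`.
#' @export
run_method_comparison <- function(data,
                                  methods = c("ks_cfs", "cfs", "ks",
                                              "mrmr", "relieff"),
                                  alpha = 0.01, top_k = 50, folds = 10,
                                  repeats = 10, base_seed = 1,
                                  prescreen = FALSE,
                                  class_col = "class", positive = NULL) {
  methods <- match.arg(methods,
                       c("ks_cfs", "cfs", "ks", "mrmr", "relieff",
                         "wilcoxon", "t"),
                       several.ok = TRUE)
  rows <- purrr::map(methods, function(mth) {
    sel <- method_selector(mth, alpha = alpha, top_k = top_k, folds = folds,
                           seed = base_seed, prescreen = prescreen,
                           class_col = class_col, positive = positive)
    ev <- repeated_shuffle_evaluation(data, sel, folds = folds,
                                      repeats = repeats,
                                      base_seed = base_seed,
                                      class_col = class_col,
                                      positive = positive)
    tibble(method = mth, n_genes = ev$mean_n_genes,
           mean_accuracy = ev$mean_accuracy,
           n_failed = sum(ev$repeats$failed))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("comparison_report", class(out)),
            kind = "method_comparison",
            params = list(alpha = alpha, top_k = top_k, folds = folds,
                          repeats = repeats, base_seed = base_seed,
                          prescreen = prescreen))
}

#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  if (identical(attr(object, "kind"), "alpha_sweep")) {
    ggplot2::ggplot(as_tibble(object),
                    ggplot2::aes(x = .data$n_genes, y = .data$mean_accuracy,
                                 colour = .data$test)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(ggplot2::aes(group = .data$test)) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "genes kept (log scale)", y = "mean CV accuracy (%)",
                    colour = "filter") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(as_tibble(object),
                    ggplot2::aes(x = .data$n_genes, y = .data$mean_accuracy,
                                 label = .data$method)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_text(nudge_y = 0.8, size = 3) +
      ggplot2::labs(x = "mean selected genes", y = "mean CV accuracy (%)") +
      ggplot2::theme_minimal()
  }
}
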