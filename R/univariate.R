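#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Computes D, the maximum absolute difference between the empirical
#' cumulative distribution functions of the two samples, evaluated at the
#' pooled observation points (where the maximum is always attained, both
#' ECDFs being right-continuous step functions).
#'
#' @param pos_values,neg_values Numeric vectors of expression values for
#'   the positive and negative class (each of length >= 1).
#' @return D in \[0, 1\].
#' @export
ks_statistic <- function(pos_values, neg_values) {
  if (length(pos_values) < 1 || length(neg_values) < 1) {
    abort("both classes must have at least one observation")
  }
  if (anyNA(pos_values) || anyNA(neg_values)) abort("missing values in input")
  sp <- sort(pos_values)
  sn <- sort(neg_values)
  at <- sort(unique(c(sp, sn)))
  f1 <- findInterval(at, sp) / length(sp)
  f2 <- findInterval(at, sn) / length(sn)
  max(abs(f1 - f2))
}

# Kolmogorov survival function Q(lambda) = 2 sum_{j>=1} (-1)^{j-1} exp(-2 j^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0.05) return(1)
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov significance decision
#'
#' Converts a two-sample D statistic into a p-value and an accept/reject
#' decision at level `alpha`: `p_value <= alpha` is equivalent to
#' `D >= D_crit(alpha, n_pos, n_neg)` since the p-value is monotone in D.
#'
#' For `n_pos * n_neg <= 10000` the p-value is exact, from the null
#' distribution of D under all class assignments (assuming continuous
#' data, via [stats::psmirnov()]); beyond that the asymptotic Kolmogorov
#' distribution is evaluated at `(sqrt(m) + 0.12 + 0.11/sqrt(m)) * D`
#' with effective sample size `m = n_pos * n_neg / (n_pos + n_neg)`
#' (Stephens' small-sample correction), which reproduces the standard
#' critical-value tables at the sample sizes where it is used.
#'
#' @param D K-S statistic in \[0, 1\].
#' @param n_pos,n_neg Class sample sizes.
#' @param alpha Significance level in (0, 1).
#' @return List with `p_value` and logical `significant`.
#' @export
ks_decision <- function(D, n_pos, n_neg, alpha = 0.05) {
  if (!is.finite(D) || D < 0 || D > 1) abort("D must be in [0, 1]")
  if (n_pos < 1 || n_neg < 1) abort("both class sizes must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  p <- if (n_pos * n_neg <= 10000) {
    stats::psmirnov(D, sizes = c(n_pos, n_neg), exact = TRUE,
                    lower.tail = FALSE)
  } else {
    m <- n_pos * n_neg / (n_pos + n_neg)
    kolmogorov_sf((sqrt(m) + 0.12 + 0.11 / sqrt(m)) * D)
  }
  p <- min(1, max(0, p))
  list(p_value = p, significant = p <= alpha)
}

#' Wilcoxon rank-sum test for one gene
#'
#' Reports the rank sum of the smaller group (midranks under ties) and a
#' two-sided p-value from the normal approximation with tie-corrected
#' variance and 0.5 continuity correction, the convention standard
#' statistical software uses at these sample sizes. When all pooled values
#' are identical the test is degenerate: p = 1, never significant.
#'
#' @param pos_values,neg_values Numeric vectors, each of length >= 2.
#' @param alpha Significance level.
#' @return List with `statistic` (rank sum of the smaller group),
#'   `p_value`, `significant`.
#' @export
rank_sum_test <- function(pos_values, neg_values, alpha = 0.05) {
  n1 <- length(pos_values); n2 <- length(neg_values)
  if (n1 < 2 || n2 < 2) abort("both classes must have at least 2 observations")
  pooled <- c(pos_values, neg_values)
  r <- rank(pooled)
  w <- if (n1 <= n2) sum(r[seq_len(n1)]) else sum(r[n1 + seq_len(n2)])
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = w, p_value = 1, significant = 1 <= alpha))
  }
  p <- suppressWarnings(
    stats::wilcox.test(pos_values, neg_values, exact = FALSE,
                       correct = TRUE)$p.value
  )
  if (!is.finite(p)) p <- 1
  list(statistic = w, p_value = p, significant = p <= alpha)
}

#' Welch two-sample t test for one gene
#'
#' Unequal-variance (Welch) t statistic oriented positive-minus-negative,
#' with a two-sided p-value. Degenerate inputs (zero variance in both
#' groups) fall back to t = 0, p = 1 when the group means agree, and to a
#' certain rejection when they differ.
#'
#' @inheritParams rank_sum_test
#' @return List with `statistic` (t), `p_value`, `significant`.
#' @export
welch_t_test <- function(pos_values, neg_values, alpha = 0.05) {
  if (length(pos_values) < 2 || length(neg_values) < 2) {
    abort("both classes must have at least 2 observations")
  }
  res <- tryCatch(
    stats::t.test(pos_values, neg_values, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # constant data: t.test refuses; decide from the means
    if (isTRUE(all.equal(mean(pos_values), mean(neg_values)))) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(pos_values) - mean(neg_values)) * Inf; p <- 0
    }
  } else {
    t <- unname(res$statistic); p <- res$p.value
  }
  list(statistic = t, p_value = p, significant = p <= alpha)
}

#' Per-gene univariate filtering at a significance level
#'
#' Runs one two-sample test (K-S, Wilcoxon rank-sum, or Welch t) on every
#' gene and flags the significant ones. This is stage 1 of the two-stage
#' selection pipeline: at a small `alpha` it discards the bulk of
#' uninformative genes, leaving a candidate set for redundancy-aware
#' stage-2 selection. `alpha = 1` keeps every gene (each p-value is <= 1
#' by construction), giving the all-genes baseline.
#'
#' Genes that are constant across all samples are never selected
#' (D = 0, p = 1), so flat probes pass through the filter harmlessly.
#'
#' @param data Dataset tibble (samples in rows).
#' @param test One of `"ks"`, `"wilcoxon"`, `"t"`.
#' @param alpha Significance level in (0, 1].
#' @param class_col Label column name.
#' @param positive Positive-class label; default the lexicographically
#'   larger one.
#' @return A `filter_report` tibble with one row per gene, in input gene
#'   order: `gene_id`, `statistic`, `p_value`, `significant`. Attributes
#'   record the test, alpha, and class orientation. Use
#'   [selected_genes()] to extract the significant genes as a
#'   [gene_subset()].
#' @export
filter_genes <- function(data, test = c("ks", "wilcoxon", "t"), alpha = 0.05,
                         class_col = "class", positive = NULL) {
  test <- match.arg(test)
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  ci <- class_info(data, class_col, positive)
  genes <- gene_columns(data, class_col)
  if (length(genes) == 0) abort("no gene columns found")
  mat <- as.matrix(data[genes])
  res <- lapply(seq_along(genes), function(j) {
    x <- mat[ci$is_pos, j]
    y <- mat[!ci$is_pos, j]
    switch(test,
      ks = {
        D <- ks_statistic(x, y)
        # alpha = 1 is the keep-everything baseline; the decision rule
        # p <= 1 always holds, so compute p at a nominal level
        dec <- ks_decision(D, length(x), length(y),
                           alpha = if (alpha < 1) alpha else 0.5)
        list(statistic = D, p_value = dec$p_value,
             significant = dec$p_value <= alpha)
      },
      wilcoxon = rank_sum_test(x, y, alpha),
      t = welch_t_test(x, y, alpha)
    )
  })
  out <- tibble(
    gene_id = genes,
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    significant = vapply(res, `[[`, logical(1), "significant")
  )
  structure(out,
            class = c("filter_report", class(out)),
            test = test, alpha = alpha,
            positive = ci$positive, negative = ci$negative,
            n_pos = ci$n_pos, n_neg = ci$n_neg)
}

#' Extract the selected genes from a filter report
#'
#' @param report A `filter_report` from [filter_genes()].
#' @return A [gene_subset()] of the significant genes, in original gene
#'   order.
#' @export
selected_genes <- function(report) {
  stopifnot(inherits(report, "filter_report"))
  gene_subset(report$gene_id[report$significant],
              method = paste0(attr(report, "test"), "_filter"),
              params = list(alpha = attr(report, "alpha")))
}

#' Write a filter report to TSV
#'
#' One row per gene in stable order: `gene_id`, `statistic`, `p_value`,
#' `significant`.
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}

#' @method autoplot filter_report
#' @export
autoplot.filter_report <- function(object, ...) {
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.02),
                            fill = "grey35", colour = "white", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = alpha, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "p-value", y = "genes",
      title = sprintf("%s filter: %d / %d genes significant at alpha = %g",
                      attr(object, "test"), sum(object$significant),
                      nrow(object), alpha)
    ) +
    ggplot2::theme_minimal()
}
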