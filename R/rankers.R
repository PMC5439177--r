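new_ranked_genes <- function(gene_id, score, method, params = list()) {
  out <- tibble(rank = seq_along(gene_id), gene_id = as.character(gene_id),
                score = as.numeric(score))
  structure(out, class = c("ranked_genes", class(out)),
            method = method, params = params)
}

#' @export
print.ranked_genes <- function(x, ...) {
  cat(sprintf("<ranked_genes> %d gene(s) ranked by '%s'\n",
              nrow(x), attr(x, "method")))
  NextMethod()
}

#' Write a gene ranking to TSV with a JSON provenance side-car
#'
#' @param x A `ranked_genes` table.
#' @param path Output TSV path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ranked_genes <- function(x, path) {
  stopifnot(inherits(x, "ranked_genes"))
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  jsonlite::write_json(list(method = attr(x, "method"),
                            params = attr(x, "params"), n_genes = nrow(x)),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Greedy minimum-redundancy maximum-relevance gene ranking
#'
#' Ranks genes by the mRMR criterion over mutual information (bits)
#' between three-level discretized expression (cuts at mean +/- sd) and
#' the class. The first gene maximizes relevance `I(gene; class)`; each
#' subsequent gene maximizes, in the difference (MID) form,
#' `I(gene; class) - mean over selected s of I(gene; s)`, or in the
#' quotient (MIQ) form the analogous ratio. Ties break toward original
#' gene order, making the ranking deterministic and independent of
#' candidate input order.
#'
#' @param data Dataset tibble.
#' @param candidates Candidate genes (`gene_subset`, character vector, or
#'   `NULL` for all).
#' @param k Number of genes to rank (top of the list); capped at the
#'   number of candidates.
#' @param class_col,positive Class column and orientation.
#' @param variant `"mid"` (difference, default) or `"miq"` (quotient).
#' @return A `ranked_genes` tibble (`rank`, `gene_id`, `score`); the score
#'   is the greedy criterion value at selection time.
#' @export
mrmr_rank <- function(data, candidates = NULL, k = 50, class_col = "class",
                      positive = NULL, variant = c("mid", "miq")) {
  variant <- match.arg(variant)
  if (k < 1) abort("k must be >= 1")
  ci <- class_info(data, class_col, positive)
  genes <- if (is.null(candidates)) gene_columns(data, class_col)
           else as_gene_ids(candidates)
  if (length(genes) == 0) abort("candidate set is empty")
  genes <- genes[order(match(genes, gene_columns(data, class_col)))]
  p <- length(genes)
  k <- min(k, p)

  codes <- lapply(genes, function(g) discretize_threelevel(data[[g]]))
  y <- as.integer(ci$is_pos)
  relevance <- vapply(codes, mi_discrete, numeric(1), b = y)

  picked <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)  # sum of MI against already-picked genes
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    crit <- if (step == 1) {
      relevance[remaining]
    } else if (variant == "mid") {
      relevance[remaining] - red_sum[remaining] / length(picked)
    } else {
      relevance[remaining] / pmax(red_sum[remaining] / length(picked), 1e-12)
    }
    best <- remaining[which.max(crit)]  # which.max: first max -> gene order
    picked <- c(picked, best)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0) break
    add <- vapply(remaining, function(j) mi_discrete(codes[[j]], codes[[best]]),
                  numeric(1))
    red_sum[remaining] <- red_sum[remaining] + add
  }
  new_ranked_genes(genes[picked], scores, "mrmr",
                   params = list(variant = variant, k = k))
}

#' ReliefF gene weighting
#'
#' Instance-based feature weighting: for each sampled instance, each
#' gene's weight is decreased by its normalized distance to the instance's
#' `k_neighbors` nearest same-class neighbors (hits) and increased by its
#' class-prior-weighted normalized distance to the `k_neighbors` nearest
#' neighbors in each other class (misses). Genes that separate classes
#' locally gain weight; genes that vary within a class lose it. A
#' constant gene contributes no distance anywhere and gets weight exactly
#' 0.
#'
#' Distances are Manhattan over range-normalized values. With
#' `n_iterations = NULL` every sample is used once, in order, and the
#' result is fully deterministic; a smaller `n_iterations` samples
#' instances with `seed`.
#'
#' @param data Dataset tibble.
#' @param candidates Candidate genes (`gene_subset`, character, or `NULL`).
#' @param k_neighbors Neighbors per class; must be smaller than each class
#'   size.
#' @param n_iterations Number of instances sampled, `NULL` for all.
#' @param k Return the top-`k` genes by weight (default: all candidates).
#' @param class_col,positive Class column and orientation.
#' @param seed Seed used only when subsampling instances.
#' @return A `ranked_genes` tibble sorted by nonincreasing weight, ties
#'   broken by original gene order.
#' @export
relieff_rank <- function(data, candidates = NULL, k_neighbors = 10,
                         n_iterations = NULL, k = NULL, class_col = "class",
                         positive = NULL, seed = 1) {
  ci <- class_info(data, class_col, positive)
  genes <- if (is.null(candidates)) gene_columns(data, class_col)
           else as_gene_ids(candidates)
  if (length(genes) == 0) abort("candidate set is empty")
  genes <- genes[order(match(genes, gene_columns(data, class_col)))]
  y <- factor(ifelse(ci$is_pos, ci$positive, ci$negative))
  counts <- table(y)
  if (any(counts <= k_neighbors)) {
    abort(sprintf("k_neighbors (%d) must be smaller than every class size (min %d)",
                  k_neighbors, min(counts)))
  }
  X <- as.matrix(data[genes])
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) diff(range(col)))
  Xn <- X
  nonflat <- rng > 0
  Xn[, nonflat] <- sweep(X[, nonflat, drop = FALSE], 2, rng[nonflat], "/")
  Xn[, !nonflat] <- 0

  idx <- if (is.null(n_iterations) || n_iterations >= n) {
    seq_len(n)
  } else {
    with_local_seed(seed, sample(n, n_iterations))
  }
  m <- length(idx)
  prior <- as.numeric(counts) / n
  names(prior) <- names(counts)

  w <- numeric(p)
  for (i in idx) {
    d <- rowSums(abs(Xn - matrix(Xn[i, ], n, p, byrow = TRUE)))
    own <- as.character(y[i])
    for (cl in levels(y)) {
      members <- which(y == cl & seq_len(n) != i)
      nb <- members[order(d[members])][seq_len(k_neighbors)]
      diffs <- colSums(abs(Xn[nb, , drop = FALSE] -
                             matrix(Xn[i, ], k_neighbors, p, byrow = TRUE)))
      if (cl == own) {
        w <- w - diffs / (m * k_neighbors)
      } else {
        w <- w + (prior[cl] / (1 - prior[own])) * diffs / (m * k_neighbors)
      }
    }
  }
  ord <- order(-w, seq_len(p))
  if (!is.null(k)) ord <- ord[seq_len(min(k, p))]
  new_ranked_genes(genes[ord], w[ord], "relieff",
                   params = list(k_neighbors = k_neighbors,
                                 n_iterations = m))
}

#' Wrapper-style forward selection over a ranked gene list
#'
#' Walks the ranking from the top: the first gene is always kept, and each
#' subsequent gene is kept if and only if adding it *strictly* improves
#' the evaluator's score of the growing subset (ties never grow the
#' subset, so a constant evaluator yields exactly the top gene). Typical
#' evaluators are cross-validated classifier accuracies, e.g. built with
#' [svm_evaluator()].
#'
#' @param ranked A `ranked_genes` table, `gene_subset`, or character
#'   vector, best first.
#' @param evaluator Function taking a character vector of gene ids and
#'   returning a single numeric score (higher is better).
#' @return A [gene_subset()] (method `"forward_selection"`) whose
#'   `params$accuracy` holds the final evaluator score.
#' @export
forward_select <- function(ranked, evaluator) {
  ids <- as_gene_ids(ranked)
  if (length(ids) == 0) abort("ranked list is empty")
  parent <- gene_subset(ids, method = "ranked_candidates")
  current <- ids[1]
  score <- evaluator(current)
  for (g in ids[-1]) {
    cand_score <- evaluator(c(current, g))
    if (cand_score > score) {
      current <- c(current, g)
      score <- cand_score
    }
  }
  gene_subset(current, method = "forward_selection",
              params = list(accuracy = score), parent = parent)
}
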