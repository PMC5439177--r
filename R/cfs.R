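#' CFS merit of a feature subset
#'
#' The correlation-based feature selection heuristic scores a subset of k
#' features as
#' `merit = k * mean(r_cf) / sqrt(k + k * (k - 1) * mean(r_ff))`,
#' where `r_cf` are the feature-class associations and `r_ff` the pairwise
#' feature-feature associations (here symmetrical uncertainty, both in
#' \[0, 1\]). High class association raises merit, mutual redundancy
#' lowers it; for k = 1 merit reduces to the single feature's `r_cf`, and
#' the empty subset scores 0.
#'
#' @param rcf Numeric vector of feature-class associations for the subset.
#' @param rff Either a k x k symmetric matrix of feature-feature
#'   associations, a single number giving their mean over distinct pairs,
#'   or `NULL` (only allowed for k <= 1).
#' @return The merit value.
#' @export
cfs_merit <- function(rcf, rff = NULL) {
  k <- length(rcf)
  if (k == 0) return(0)
  if (k == 1) return(unname(rcf))
  if (is.null(rff)) abort("rff is required for subsets of 2 or more features")
  mean_rff <- if (is.matrix(rff)) {
    stopifnot(nrow(rff) == k, ncol(rff) == k)
    mean(rff[upper.tri(rff)])
  } else {
    as.numeric(rff)
  }
  k * mean(rcf) / sqrt(k + k * (k - 1) * mean_rff)
}

# Association cache for CFS over one dataset: class associations given up
# front, pairwise gene associations filled lazily. `features` is a list
# of per-gene representations and `assoc` a symmetric function over them.
new_cfs_cache <- function(features, rcf, assoc) {
  p <- length(features)
  env <- new.env(parent = emptyenv())
  env$features <- features
  env$assoc <- assoc
  env$rcf <- rcf
  env$rff <- matrix(NA_real_, p, p)
  diag(env$rff) <- 1
  env
}

cache_rff <- function(cache, i, j) {
  v <- cache$rff[i, j]
  if (is.na(v)) {
    v <- cache$assoc(cache$features[[i]], cache$features[[j]])
    cache$rff[i, j] <- v
    cache$rff[j, i] <- v
  }
  v
}

# Absolute Pearson correlation (point-biserial when one side is a 0/1
# class indicator); 0 for constant inputs.
abs_pearson <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  min(1, abs(stats::cor(a, b)))
}

# Merit of an integer index subset using the cache.
cache_merit <- function(cache, idx) {
  k <- length(idx)
  if (k == 0) return(0)
  sum_rcf <- sum(cache$rcf[idx])
  if (k == 1) return(sum_rcf)
  sum_rff <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      sum_rff <- sum_rff + cache_rff(cache, idx[a], idx[b])
    }
  }
  sum_rcf / sqrt(k + 2 * sum_rff)
}

#' CFS subset selection by best-first search
#'
#' Selects a compact gene subset whose members are strongly associated
#' with the class and weakly associated with each other, by maximizing the
#' CFS merit ([cfs_merit()]) over subsets of the candidate genes with a
#' forward best-first search.
#'
#' Two association measures are available. The default, `"pearson"`,
#' scores gene-gene association by absolute Pearson correlation and
#' gene-class association by absolute point-biserial correlation, working
#' directly on the continuous expression values. This keeps near-copies
#' of a gene at association ~1, where the merit denominator actually
#' excludes them; discretizing each gene independently before an
#' information-theoretic comparison blurs exactly those near-ties (two
#' near-identical genes can land on different cut points), letting
#' redundant copies slip in. `"su"` uses symmetrical uncertainty over
#' class-supervised MDL-discretized codes (quantile bins via
#' `discretizer = "quantile"`), which additionally captures nonlinear
#' class association at the cost of that redundancy blindness.
#'
#' Before the search, clusters of near-duplicate candidates (pairwise
#' association at or above `dedup_threshold`) are collapsed to their most
#' class-associated member. This step is what actually guarantees that at
#' most one member of a duplicated gene survives: the merit is exactly
#' invariant under duplicating every subset member uniformly (merit^2 =
#' (sum rcf)^2 / (sum of squared copy counts) when within-copy
#' association is 1 and cross association is fully class-driven), so with
#' finite-sample association just below 1 a merit-guided search alone can
#' land on either side of the tie.
#'
#' Search: starting from the empty set, the open node with the highest
#' merit is expanded by adding each absent candidate gene; the search
#' stops after `stall` consecutive expansions that fail to improve the
#' best merit seen. Ties are broken toward the earlier-generated node,
#' which makes the result deterministic and biased toward original gene
#' order. The returned merit is always at least the best singleton's.
#'
#' @param data Dataset tibble.
#' @param candidates Candidate genes: a [gene_subset()], a character
#'   vector, or `NULL` for all genes.
#' @param class_col,positive Class column and orientation.
#' @param association `"pearson"` (default) or `"su"`; see Details.
#' @param discretizer `"mdl"` (default) or `"quantile"`; used only by
#'   `association = "su"`.
#' @param stall Consecutive non-improving expansions tolerated before the
#'   search stops (default 5).
#' @param dedup_threshold Association level at or above which two
#'   candidates count as duplicates of one signal (default 0.95,
#'   calibrated for the correlation measure).
#' @param locally_predictive After the search, sweep in any unselected
#'   gene whose class association exceeds its association with every
#'   selected gene (on by default). The merit averages associations over
#'   the whole subset, so an independently informative gene can fail to
#'   move it once the subset is large; this classic post-step recovers
#'   such genes without readmitting redundant ones.
#' @param bins Bin count for the quantile discretizer.
#' @return A [gene_subset()] (method `"cfs"`, parent = the candidate
#'   set) with the achieved merit in `params$merit`. If every candidate
#'   carries zero class association (e.g. all constant), the selection is
#'   empty and a warning is raised.
#' @export
cfs_select <- function(data, candidates = NULL, class_col = "class",
                       positive = NULL, association = c("pearson", "su"),
                       discretizer = c("mdl", "quantile"),
                       stall = 5, dedup_threshold = 0.95,
                       locally_predictive = TRUE, bins = 10) {
  association <- match.arg(association)
  discretizer <- match.arg(discretizer)
  ci <- class_info(data, class_col, positive)
  genes <- if (is.null(candidates)) gene_columns(data, class_col)
           else as_gene_ids(candidates)
  if (length(genes) == 0) abort("candidate set is empty")
  missing <- setdiff(genes, gene_columns(data, class_col))
  if (length(missing) > 0) {
    abort(sprintf("candidate gene(s) not in data: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  parent <- if (inherits(candidates, "gene_subset")) candidates
            else gene_subset(genes, method = "candidates")

  class_codes <- as.integer(ci$is_pos)
  if (association == "pearson") {
    # class association on the raw values; gene-gene association on the
    # within-class-centered values, so correlation that flows through the
    # class signal itself is not double-counted as redundancy
    features <- lapply(genes, function(g) {
      x <- as.numeric(data[[g]])
      x[ci$is_pos] <- x[ci$is_pos] - mean(x[ci$is_pos])
      x[!ci$is_pos] <- x[!ci$is_pos] - mean(x[!ci$is_pos])
      x
    })
    rcf <- vapply(genes, function(g) {
      abs_pearson(as.numeric(data[[g]]), as.numeric(class_codes))
    }, numeric(1))
    cache <- new_cfs_cache(features, rcf, abs_pearson)
    # correlations are cheap in bulk; prefill the pair matrix
    M <- do.call(cbind, features)
    sds <- apply(M, 2, sd)
    R <- suppressWarnings(abs(stats::cor(M)))
    R[!is.finite(R)] <- 0
    R[sds == 0, ] <- 0
    R[, sds == 0] <- 0
    diag(R) <- 1
    cache$rff <- pmin(R, 1)
  } else {
    codes <- lapply(genes, function(g) {
      x <- data[[g]]
      if (discretizer == "mdl") discretize_mdl(x, class_codes)
      else discretize_quantile(x, bins)
    })
    rcf <- vapply(codes, su_discrete, numeric(1), b = class_codes)
    cache <- new_cfs_cache(codes, rcf, su_discrete)
  }

  if (all(cache$rcf <= 0)) {
    warn("no candidate gene has any class association; returning empty selection")
    return(gene_subset(character(0), method = "cfs",
                       params = list(association = association, merit = 0),
                       parent = parent))
  }

  keep <- dedup_candidates(cache, dedup_threshold)
  sub_cache <- new_cfs_cache(cache$features[keep], cache$rcf[keep], cache$assoc)
  sub_cache$rff <- cache$rff[keep, keep, drop = FALSE]

  best <- best_first_search(sub_cache, length(keep), stall)
  sel <- best$subset
  n_local <- 0L
  if (locally_predictive) {
    sel <- add_locally_predictive(sub_cache, sel)
    n_local <- length(sel) - length(best$subset)
  }
  gene_subset(genes[keep][sel], method = "cfs",
              params = list(association = association, stall = stall,
                            merit = best$merit,
                            dedup_threshold = dedup_threshold,
                            n_dedup_dropped = length(genes) - length(keep),
                            n_locally_predictive = n_local),
              parent = parent)
}

# Post-search sweep for "locally predictive" genes: repeatedly add the
# strongest unselected gene whose class association exceeds its
# association with every selected gene — it predicts class structure no
# selected gene covers, which the merit's global average can overlook.
add_locally_predictive <- function(cache, sel) {
  p <- length(cache$rcf)
  repeat {
    rem <- setdiff(order(-cache$rcf, seq_len(p)), sel)
    added <- FALSE
    for (i in rem) {
      if (cache$rcf[i] <= 0) break
      max_ff <- if (length(sel)) {
        max(vapply(sel, function(j) cache_rff(cache, i, j), numeric(1)))
      } else -Inf
      if (cache$rcf[i] > max_ff) {
        sel <- sort(c(sel, i))
        added <- TRUE
        break
      }
    }
    if (!added) return(sel)
  }
}

# Collapse clusters of near-duplicate candidates, keeping each cluster's
# most class-associated member (ties -> original order). Returns sorted
# indices of the kept genes.
dedup_candidates <- function(cache, threshold) {
  p <- length(cache$rcf)
  keep <- integer(0)
  for (i in order(-cache$rcf, seq_len(p))) {
    dup <- FALSE
    for (j in keep) {
      if (cache_rff(cache, i, j) >= threshold) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  sort(keep)
}

# Forward best-first search over index subsets, maximizing cache_merit.
best_first_search <- function(cache, p, stall = 5) {
  key_of <- function(idx) paste0("k", paste(idx, collapse = ","))
  open_sets <- list(integer(0))
  open_merits <- 0
  seen <- new.env(parent = emptyenv())
  assign(key_of(integer(0)), TRUE, envir = seen)
  best_merit <- 0
  best_set <- integer(0)
  stale <- 0
  eps <- 1e-10

  while (length(open_sets) > 0) {
    i_star <- which.max(open_merits)  # ties -> earliest inserted
    node <- open_sets[[i_star]]
    open_sets <- open_sets[-i_star]
    open_merits <- open_merits[-i_star]
    improved <- FALSE
    for (g in setdiff(seq_len(p), node)) {
      child <- sort(c(node, g))
      key <- key_of(child)
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      m <- cache_merit(cache, child)
      open_sets[[length(open_sets) + 1]] <- child
      open_merits <- c(open_merits, m)
      if (m > best_merit + eps) {
        best_merit <- m
        best_set <- child
        improved <- TRUE
      }
    }
    if (improved) stale <- 0 else stale <- stale + 1
    if (stale >= stall) break
  }
  list(subset = best_set, merit = best_merit)
}
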