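# Independent oracles and small fixture builders. Each oracle is written
# as directly as possible (brute force, enumeration, closed form) and
# shares no code with the implementation it checks.

# Brute-force two-sample K-S statistic: evaluate both ECDFs at every
# pooled observation point and take the maximum absolute difference.
oracle_ks_d <- function(x, y) {
  pts <- c(x, y)
  d <- vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1))
  max(d)
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) assignments of the pooled ranks to group 1.
oracle_wilcoxon_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Welch t statistic and two-sided p from the defining formulas.
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# CFS associations computed independently: class association is the
# absolute point-biserial correlation, gene-gene association the
# absolute correlation of within-class-centered values.
oracle_cfs_assoc <- function(data, class_col = "class") {
  genes <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], class_col)
  u <- sort(unique(as.character(data[[class_col]])))
  yv <- as.numeric(as.character(data[[class_col]]) == u[2])
  X <- as.matrix(data[genes])
  Xc <- X
  for (cl in u) {
    rows <- as.character(data[[class_col]]) == cl
    Xc[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                        colMeans(X[rows, , drop = FALSE]))
  }
  rcf <- abs(suppressWarnings(stats::cor(X, yv)))[, 1]
  rcf[!is.finite(rcf)] <- 0
  R <- abs(suppressWarnings(stats::cor(Xc)))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  list(genes = genes, rcf = rcf, rff = R)
}

# Exhaustive maximum CFS merit over all nonempty subsets.
oracle_max_merit <- function(rcf, rff) {
  p <- length(rcf)
  best <- 0
  for (m in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    best <- max(best, cfs_merit(rcf[idx], rff[idx, idx, drop = FALSE]))
  }
  best
}

# Direct mutual information (bits) over discrete codes.
oracle_mi <- function(a, b) {
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  mi <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log2(joint[i, j] / (pa[i] * pb[j]))
      }
    }
  }
  max(0, mi)
}

# Direct greedy mRMR (difference form) over precomputed codes.
oracle_mrmr_order <- function(codes, y, k) {
  p <- length(codes)
  rel <- vapply(codes, function(cd) oracle_mi(cd, y), numeric(1))
  picked <- integer(0)
  for (step in seq_len(min(k, p))) {
    rem <- setdiff(seq_len(p), picked)
    crit <- vapply(rem, function(j) {
      if (length(picked) == 0) return(rel[j])
      rel[j] - mean(vapply(picked, function(s) oracle_mi(codes[[j]], codes[[s]]),
                           numeric(1)))
    }, numeric(1))
    picked <- c(picked, rem[which.max(crit)])
  }
  picked
}

# Direct ReliefF weights using all instances, k nearest hits/misses,
# Manhattan distance on range-normalized values.
oracle_relieff <- function(X, y, k_neighbors) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(cl) diff(range(cl)))
  rng[rng == 0] <- Inf  # constant gene: zero contribution everywhere
  Xn <- sweep(X, 2, rng, "/")
  prior <- table(y) / n
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j) sum(abs(Xn[i, ] - Xn[j, ])), numeric(1))
    for (cl in names(prior)) {
      members <- setdiff(which(y == cl), i)
      nb <- members[order(d[members])][seq_len(k_neighbors)]
      contrib <- colSums(abs(Xn[nb, , drop = FALSE] -
                               matrix(Xn[i, ], k_neighbors, p, byrow = TRUE)))
      if (cl == y[i]) {
        w <- w - contrib / (n * k_neighbors)
      } else {
        w <- w + (prior[[cl]] / (1 - prior[[as.character(y[i])]])) *
          contrib / (n * k_neighbors)
      }
    }
  }
  w
}

# Small labeled dataset from a matrix (rows = samples).
toy_dataset <- function(X, labels, gene_ids = NULL) {
  colnames(X) <- gene_ids %||% paste0("g", seq_len(ncol(X)))
  out <- tibble::as_tibble(X)
  out$class <- labels
  out$sample_id <- paste0("S", seq_len(nrow(X)))
  out[c("sample_id", "class", colnames(X))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
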