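# Entropy in bits of a count vector or table.
entropy_bits <- function(counts) {
  counts <- as.numeric(counts)
  tot <- sum(counts)
  if (tot <= 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

#' Supervised MDL discretization of a continuous gene
#'
#' Recursive entropy-minimizing binary splitting with the minimum
#' description length stopping rule (Fayyad-Irani): at each segment the
#' candidate cut minimizing the class-entropy of the partition is accepted
#' only if its information gain exceeds the MDL coding cost
#' `(log2(N-1) + log2(3^k - 2) - (k*H(S) - k1*H(S1) - k2*H(S2))) / N`.
#' Genes carrying no class information receive no cut and collapse to a
#' single bin, which downstream association measures treat as zero
#' association — this built-in feature rejection is why it is the default
#' discretizer for CFS.
#'
#' @param x Numeric vector.
#' @param class Class labels (any type coercible to factor), same length.
#' @return Integer bin codes in `1..(cuts+1)`, with the cut points in the
#'   `"cuts"` attribute (empty when no cut passed the MDL test).
#' @export
discretize_mdl <- function(x, class) {
  stopifnot(length(x) == length(class))
  y <- as.integer(factor(class))
  k_all <- max(y)
  ord <- order(x, method = "radix")
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)

  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2) return()
    seg_y <- ys[lo:hi]
    # cumulative class counts within the segment
    cum <- vapply(seq_len(k_all), function(cl) cumsum(seg_y == cl),
                  numeric(len))
    if (len == 1) cum <- matrix(cum, nrow = 1)
    tot <- cum[len, ]
    ent_s <- entropy_bits(tot)
    if (ent_s == 0) return()
    # candidate cuts: between adjacent distinct values
    cand <- which(xs[(lo:hi)[-len]] < xs[(lo:hi)[-1]])
    if (length(cand) == 0) return()
    best_gain <- -Inf; best_i <- NA_integer_
    best_e1 <- best_e2 <- NA_real_
    for (i in cand) {
      left <- cum[i, ]; right <- tot - left
      e1 <- entropy_bits(left); e2 <- entropy_bits(right)
      gain <- ent_s - (i * e1 + (len - i) * e2) / len
      if (gain > best_gain + 1e-12) {
        best_gain <- gain; best_i <- i; best_e1 <- e1; best_e2 <- e2
      }
    }
    if (!is.finite(best_gain)) return()
    left <- cum[best_i, ]; right <- tot - left
    k0 <- sum(tot > 0); k1 <- sum(left > 0); k2 <- sum(right > 0)
    delta <- log2(3^k0 - 2) - (k0 * ent_s - k1 * best_e1 - k2 * best_e2)
    if (best_gain <= (log2(len - 1) + delta) / len) return()
    cut <- (xs[lo + best_i - 1] + xs[lo + best_i]) / 2
    cuts <<- c(cuts, cut)
    recurse(lo, lo + best_i - 1)
    recurse(lo + best_i, hi)
  }
  recurse(1, n)
  cuts <- sort(cuts)
  codes <- findInterval(x, cuts) + 1L
  attr(codes, "cuts") <- cuts
  codes
}

#' Equal-frequency discretization
#'
#' Unsupervised fallback: bins at the empirical quantiles. Duplicate
#' quantiles (heavily tied data) collapse, so fewer than `bins` bins can
#' result.
#'
#' @param x Numeric vector.
#' @param bins Target number of bins.
#' @return Integer bin codes with cut points in the `"cuts"` attribute.
#' @export
discretize_quantile <- function(x, bins = 10) {
  qs <- quantile(x, probs = seq_len(bins - 1) / bins, names = FALSE, type = 7)
  cuts <- sort(unique(qs))
  codes <- findInterval(x, cuts) + 1L
  attr(codes, "cuts") <- cuts
  codes
}

# Three-level discretization at mean +/- sd (the usual mRMR convention
# for continuous expression values).
discretize_threelevel <- function(x) {
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(1L, length(x)))
  as.integer(x > m + s) - as.integer(x < m - s) + 2L
}

#' Symmetrical uncertainty between two variables
#'
#' `SU(a, b) = 2 I(a; b) / (H(a) + H(b))` with entropies in bits over the
#' (discretized) values: 0 for independent variables, 1 for a
#' deterministic relabeling, and defined as 0 when either variable is
#' constant (zero entropy). Symmetric in its arguments.
#'
#' @param a,b Equal-length vectors. Treated as categorical as given when
#'   `discretizer = "none"`; otherwise discretized first.
#' @param discretizer `"none"` (default), `"mdl"` (requires `class`), or
#'   `"quantile"`.
#' @param class Class labels, required by the MDL discretizer.
#' @param bins Bin count for the quantile discretizer.
#' @return SU in \[0, 1\].
#' @export
symmetric_uncertainty <- function(a, b, discretizer = c("none", "mdl", "quantile"),
                                  class = NULL, bins = 10) {
  discretizer <- match.arg(discretizer)
  stopifnot(length(a) == length(b))
  if (discretizer == "mdl") {
    if (is.null(class)) abort("the MDL discretizer requires `class`")
    a <- discretize_mdl(a, class); b <- discretize_mdl(b, class)
  } else if (discretizer == "quantile") {
    a <- discretize_quantile(a, bins); b <- discretize_quantile(b, bins)
  }
  su_discrete(a, b)
}

su_discrete <- function(a, b) {
  tab <- table(a, b)
  ha <- entropy_bits(rowSums(tab))
  hb <- entropy_bits(colSums(tab))
  if (ha + hb <= 0) return(0)
  mi <- ha + hb - entropy_bits(tab)
  min(1, max(0, 2 * mi / (ha + hb)))
}

mi_discrete <- function(a, b) {
  tab <- table(a, b)
  max(0, entropy_bits(rowSums(tab)) + entropy_bits(colSums(tab)) -
        entropy_bits(tab))
}
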