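#' Pearson product-moment correlation of two expression profiles
#'
#' Standard Pearson r, clipped to `[-1, 1]` against floating-point rounding.
#' Constant vectors make r undefined and raise an error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  max(-1, min(1, stats::cor(x, y)))
}

#' Fisher asymptotic p-value for a Pearson correlation
#'
#' Under the null of zero correlation, the Fisher z-transform
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))` scaled by `sqrt(n - 3)` is
#' approximately standard normal; the two-sided p-value is
#' `2 * pnorm(-|z| * sqrt(n - 3))`. `|r| = 1` gives p = 0 exactly. This is
#' the normal-approximation dialect used by WGCNA-style coexpression
#' pipelines; the Student-t alternative
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom is
#' available via `method = "t"`.
#'
#' @param r Correlation coefficient(s), `|r| <= 1`. Vectorized.
#' @param n Sample size(s) used to compute r; must be >= 4 for the Fisher-z
#'   method (so that `sqrt(n - 3)` is nondegenerate).
#' @param method `"fisherz"` (default) or `"t"`.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
fisher_asymptotic_p <- function(r, n, method = c("fisherz", "t")) {
  method <- match.arg(method)
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1")
  r <- pmax(-1, pmin(1, r))
  p <- numeric(length(r))
  exact1 <- abs(r) == 1
  if (method == "fisherz") {
    if (any(n < 4)) stop("Fisher-z p-value requires n >= 4")
    stat <- atanh(r) * sqrt(n - 3)  # atanh(+/-1) = +/-Inf -> p = 0
    p <- 2 * stats::pnorm(-abs(stat))
  } else {
    if (any(n < 3)) stop("t-based p-value requires n >= 3")
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  p[exact1] <- 0
  pmin(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with p-values sorted ascending,
#' `q_(i) = min_(j >= i) (p_(j) * m / j)`, capped at 1 and returned in the
#' input order. Thin validated wrapper around `stats::p.adjust(method="BH")`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Build an FDR-thresholded signed coexpression network
#'
#' Computes Pearson correlations for all unordered gene pairs of the scope,
#' converts each to a p-value by the Fisher asymptotic method, adjusts the
#' whole family of `g * (g - 1) / 2` tests by Benjamini-Hochberg, and keeps
#' the pairs with adjusted p below `alpha`. Edge sign records the sign of r.
#' Constant (zero-variance) genes are dropped before correlation with a
#' message, since r is undefined for them.
#'
#' @param matrix Normalized log2 expression matrix, genes x samples, >= 4
#'   samples.
#' @param alpha Adjusted-p threshold for keeping an edge (default 0.05).
#' @param genes Optional character vector restricting the gene universe
#'   (e.g. the differential genes only); default all rows.
#' @param method P-value method passed to [fisher_asymptotic_p()].
#' @param biotype Optional named character vector (gene to biotype), stored
#'   on the result for downstream neighborhood filtering.
#' @return An object of class `coexpression_network`: list with `edges`
#'   (data frame `gene_a`, `gene_b`, `r`, `n`, `p`, `p_adj`, `sign`,
#'   `support`), `alpha`, `n_tested`, `genes_tested` (the gene space the
#'   network was built over, used as the enrichment universe downstream) and
#'   `biotype`. Pairs are stored in canonical (lexicographic) order.
#' @export
build_network <- function(matrix, alpha = 0.05, genes = rownames(matrix),
                          method = "fisherz", biotype = NULL) {
  sub <- matrix[intersect(genes, rownames(matrix)), , drop = FALSE]
  n <- ncol(sub)
  if (n < 4) stop("Fisher-z p-value requires n >= 4")
  rv <- apply(sub, 1, stats::var)
  if (any(rv == 0)) {
    message(sprintf("build_network: dropping %d constant gene(s)",
                    sum(rv == 0)))
    sub <- sub[rv > 0, , drop = FALSE]
  }
  g <- nrow(sub)
  if (g < 2) stop("need at least 2 nonconstant genes")

  cm <- stats::cor(t(sub))
  ut <- upper.tri(cm)
  idx <- which(ut, arr.ind = TRUE)
  r <- pmax(-1, pmin(1, cm[ut]))
  p <- fisher_asymptotic_p(r, n, method = method)
  p_adj <- bh_adjust(p)
  message(sprintf("build_network: tested %d pairs over %d genes",
                  length(r), g))

  keep <- p_adj < alpha
  a <- rownames(sub)[idx[keep, 1]]
  b <- rownames(sub)[idx[keep, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(
    gene_a = a, gene_b = b,
    r = r[keep], n = rep(n, sum(keep)), p = p[keep], p_adj = p_adj[keep],
    sign = ifelse(r[keep] > 0, "positive", "negative"),
    support = rep(1L, sum(keep)), stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, alpha = alpha,
                 n_tested = length(r), genes_tested = rownames(sub),
                 biotype = biotype),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression network: %d edges (of %d tested pairs) at adjusted p < %g\n",
    nrow(x$edges), x$n_tested, x$alpha))
  invisible(x)
}

#' Consensus edges across multiple coexpression datasets
#'
#' Keeps an edge if it is detected in at least `min_support` of the input
#' edge sets, recording the support count. Edge identity is the unordered
#' node pair; by default sign disagreement across datasets is ignored, while
#' `strict_sign = TRUE` requires a consistent sign and counts support per
#' (pair, sign).
#'
#' @param networks List of edge data frames (each with `gene_a`, `gene_b`,
#'   and optionally `sign`), or of `coexpression_network` objects.
#' @param min_support Minimum number of datasets an edge must appear in.
#' @param strict_sign Require consistent edge sign across datasets.
#' @return Data frame `gene_a`, `gene_b`, (`sign`,) `support`, sorted by pair.
#' @export
aggregate_multi_dataset <- function(networks, min_support,
                                    strict_sign = FALSE) {
  if (length(networks) < 1) stop("need at least one input network")
  if (min_support > length(networks)) {
    warning("min_support exceeds the number of datasets; empty consensus")
  }
  canon <- function(e) {
    if (inherits(e, "coexpression_network")) e <- e$edges
    a <- pmin(e$gene_a, e$gene_b)
    b <- pmax(e$gene_a, e$gene_b)
    key <- if (strict_sign) paste(a, b, e$sign, sep = "\r")
           else paste(a, b, sep = "\r")
    unique(key)
  }
  keys <- unlist(lapply(networks, canon))
  tab <- table(keys)
  kept <- names(tab)[tab >= min_support]
  parts <- strsplit(kept, "\r", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[`, "", 1),
    gene_b = vapply(parts, `[`, "", 2),
    support = as.integer(tab[kept]),
    stringsAsFactors = FALSE
  )
  if (strict_sign && length(parts) > 0) {
    out$sign <- vapply(parts, `[`, "", 3)
    out <- out[, c("gene_a", "gene_b", "sign", "support")]
  }
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
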