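#' Hypergeometric upper-tail (over-representation) p-value
#'
#' Probability of drawing at least `x` annotated genes when `n_draw` genes
#' are drawn without replacement from a universe of `N` genes of which `K`
#' are annotated:
#' `p = sum_{k=x}^{min(n_draw, K)} C(K,k) C(N-K, n_draw-k) / C(N, n_draw)`.
#' Evaluated in stable log space via `stats::phyper`. `x = 0` gives p = 1.
#'
#' @param x Observed annotated genes in the draw.
#' @param K Annotated genes in the universe.
#' @param n_draw Size of the draw (e.g. a lncRNA's annotated neighbors).
#' @param N Universe size.
#' @return Upper-tail p-value in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(x, K, n_draw, N) {
  if (any(x < 0) || any(x > n_draw) || any(n_draw > N) || any(K > N) ||
      any(K < 0)) {
    stop("inconsistent counts: need 0 <= x <= n_draw <= N and 0 <= K <= N")
  }
  stats::phyper(x - 1, K, N - K, n_draw, lower.tail = FALSE)
}

#' Direct coexpressed neighbors of a lncRNA, filtered by biotype
#'
#' One-hop neighbors of `lncrna` in the coexpression edge set, keeping only
#' genes of the requested biotype (protein-coding by default). Both edge
#' signs are included: guilt-by-association uses every directly coexpressed
#' partner.
#'
#' @param network A `coexpression_network` (or bare edge data frame with
#'   `gene_a`, `gene_b`).
#' @param lncrna Gene symbol; must occur in the network.
#' @param biotype Named character vector, gene to biotype. If `NULL`, no
#'   biotype filter is applied.
#' @param biotype_filter Which biotype to keep (default `"protein_coding"`).
#' @return Character vector of neighbor symbols (possibly empty).
#' @export
neighborhood <- function(network, lncrna, biotype = NULL,
                         biotype_filter = "protein_coding") {
  edges <- if (inherits(network, "coexpression_network")) network$edges
           else network
  if (is.null(biotype) && inherits(network, "coexpression_network")) {
    biotype <- network$biotype
  }
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  if (!lncrna %in% nodes) stop("gene not present in the network: ", lncrna)
  nb <- c(edges$gene_b[edges$gene_a == lncrna],
          edges$gene_a[edges$gene_b == lncrna])
  nb <- unique(nb)
  if (!is.null(biotype)) {
    nb <- nb[!is.na(biotype[nb]) & biotype[nb] == biotype_filter]
  }
  unname(nb)
}

#' Annotate lncRNAs with GO terms enriched in their coexpressed neighbors
#'
#' Hub-based guilt-by-association: for every lncRNA whose protein-coding
#' neighborhood in the coexpression network is larger than `min_neighbors`
#' (strictly, so the default 3 means at least 4 neighbors), each GO term is
#' tested for over-representation among the lncRNA's annotated neighbors by
#' the hypergeometric upper tail. The universe is the intersection of the
#' gene-set collection's annotated genes with the network's gene space — the
#' genes the network was built over (`genes_tested` for a
#' `coexpression_network`; the edge endpoints for a bare edge table, unless
#' `universe` is given) — so K is never inflated by genes the network cannot
#' contain. P-values are
#' BH-adjusted per lncRNA (its own family of tested terms);
#' `family = "global"` adjusts over all lncRNA-term tests at once. Terms with
#' adjusted p below `alpha` are flagged as assigned.
#'
#' @param network A `coexpression_network` (with `biotype`) or an edge data
#'   frame plus a `biotype` argument.
#' @param gene_sets Named list of character vectors (term id to gene set),
#'   e.g. from [read_gmt()] or [simulate_go()].
#' @param biotype Named character vector, gene to biotype (needed if not on
#'   the network object).
#' @param min_neighbors Hub threshold: only lncRNAs with strictly more than
#'   this many protein-coding neighbors are tested (default 3).
#' @param alpha Adjusted-p threshold for assignment (default 0.05).
#' @param family `"per_lncrna"` (default) or `"global"` BH family.
#' @param universe Optional character vector overriding the network gene
#'   space used for the enrichment universe.
#' @return Data frame: `lncrna`, `term`, `x`, `n_draw`, `K`, `N`, `p`,
#'   `p_adj`, `assigned`. Only terms with `x >= 1` are reported.
#' @export
annotate_lncrnas <- function(network, gene_sets, biotype = NULL,
                             min_neighbors = 3, alpha = 0.05,
                             family = c("per_lncrna", "global"),
                             universe = NULL) {
  family <- match.arg(family)
  if (length(gene_sets) == 0) stop("empty gene-set collection")
  edges <- if (inherits(network, "coexpression_network")) network$edges
           else network
  if (is.null(biotype) && inherits(network, "coexpression_network")) {
    biotype <- network$biotype
  }
  if (is.null(biotype)) stop("a gene-to-biotype map is required")

  net_genes <- unique(c(edges$gene_a, edges$gene_b))
  gene_space <- if (!is.null(universe)) universe
                else if (inherits(network, "coexpression_network") &&
                         !is.null(network$genes_tested)) network$genes_tested
                else net_genes
  universe <- intersect(unique(unlist(gene_sets, use.names = FALSE)),
                        gene_space)
  N <- length(universe)
  if (N == 0) stop("gene sets and network share no genes")
  sets <- lapply(gene_sets, intersect, universe)
  sets <- sets[vapply(sets, length, 0L) > 0]
  sets <- sets[order(names(sets))]   # iteration-order independence

  lncs <- sort(net_genes[!is.na(biotype[net_genes]) &
                           biotype[net_genes] == "lncRNA"])
  rows <- list()
  for (ln in lncs) {
    nb <- neighborhood(edges, ln, biotype = biotype)
    if (length(nb) <= min_neighbors) next   # hub rule is strict
    ann_nb <- intersect(nb, universe)
    n_draw <- length(ann_nb)
    if (n_draw == 0) next
    for (term in names(sets)) {
      K <- length(sets[[term]])
      x <- length(intersect(ann_nb, sets[[term]]))
      if (x < 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna = ln, term = term, x = x, n_draw = n_draw, K = K, N = N,
        p = hypergeom_upper_tail(x, K, n_draw, N),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(lncrna = character(0), term = character(0),
                      x = integer(0), n_draw = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      assigned = logical(0)))
  }
  res <- do.call(rbind, rows)
  if (family == "per_lncrna") {
    res$p_adj <- stats::ave(res$p, res$lncrna, FUN = bh_adjust)
  } else {
    res$p_adj <- bh_adjust(res$p)
  }
  res$assigned <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Top-ranked predicted functions for a lncRNA
#'
#' Terms sorted by raw p ascending; ties broken by larger overlap `x`, then
#' by term id. Returns the first `k` (all, if fewer).
#'
#' @param results Output of [annotate_lncrnas()].
#' @param lncrna The lncRNA symbol to rank terms for.
#' @param k Number of terms to return (default 10).
#' @param assigned_only Restrict to terms passing the assignment threshold.
#' @return The ranked subset of `results`.
#' @export
top_terms <- function(results, lncrna, k = 10, assigned_only = FALSE) {
  sub <- results[results$lncrna == lncrna, , drop = FALSE]
  if (assigned_only) sub <- sub[sub$assigned, , drop = FALSE]
  sub <- sub[order(sub$p, -sub$x, sub$term), , drop = FALSE]
  utils::head(sub, k)
}
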