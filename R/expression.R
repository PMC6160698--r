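#' Quantile-normalize an expression matrix
#'
#' Forces every column onto a common distribution: the per-rank mean of the
#' input columns. After normalization every column holds the identical sorted
#' value multiset. Ties within a column receive the mean of the reference
#' values over their tied ranks, so the result is deterministic regardless of
#' input order. Idempotent: applying it twice equals applying it once.
#'
#' @param values Numeric matrix (probes x samples) with no missing entries.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 1) stop("matrix must have at least one column")
  if (anyNA(values)) stop("missing values are not supported")
  reference <- rowMeans(apply(values, 2, sort))
  out <- values
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    assigned <- numeric(length(col))
    assigned[order(col)] <- reference
    # tie groups share the mean of the reference values at their ranks
    out[, j] <- stats::ave(assigned, match(col, col))
  }
  out
}

#' Filter probes by presence calls
#'
#' Retains exactly the rows flagged as expressed ("present") in at least
#' `min_present` samples, in their original order. Presence flags normally
#' come from the array vendor's detection calls; [presence_flags_median()]
#' provides a fallback rule when no calls are available.
#'
#' @param matrix Numeric matrix, probes x samples.
#' @param presence_flags Logical matrix of the same shape.
#' @param min_present Minimum number of flagged samples per retained row.
#' @return The filtered matrix.
#' @export
presence_filter <- function(matrix, presence_flags, min_present) {
  if (!all(dim(matrix) == dim(presence_flags))) {
    stop("presence_flags must have the same shape as the matrix")
  }
  if (min_present > ncol(matrix)) {
    stop("min_present exceeds the number of samples")
  }
  keep <- rowSums(presence_flags) >= min_present
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("presence_filter: dropped %d of %d rows (< %d present)",
                    n_drop, nrow(matrix), min_present))
  }
  matrix[keep, , drop = FALSE]
}

#' Fallback presence calls: intensity above the column median
#'
#' @param matrix Numeric matrix, probes x samples.
#' @return Logical matrix of the same shape.
#' @export
presence_flags_median <- function(matrix) {
  med <- apply(matrix, 2, stats::median)
  sweep(matrix, 2, med, `>`)
}

#' Row-wise differential expression test on log2 intensities
#'
#' Computes, for every probe, the tumor-vs-normal fold change and a
#' two-sided t-test p-value on the log2 values: Welch's two-sample test by
#' default or a paired test when `paired = TRUE` (pairs matched via the
#' sample sheet's `pair` column). Rows with zero within-group variance and
#' zero mean difference get p = 1 with a warning rather than NaN; zero
#' variance with a nonzero difference gives p = 0.
#'
#' @param matrix Numeric matrix of log2 intensities, probes x samples, with
#'   column names matching `samples$sample`.
#' @param samples Sample sheet data frame with columns `sample`, `group`
#'   (`"tumor"`/`"normal"`) and, if paired, `pair`.
#' @param paired Use a paired t-test on within-pair differences.
#' @return A `DiffExprTable` data frame: `gene`, `mean_tumor`, `mean_normal`,
#'   `log2_fc`, `fold_change`, `p_value`. Fold change is oriented
#'   tumor/normal so `fold_change > 1` means higher in tumor.
#' @export
differential_test <- function(matrix, samples, paired = FALSE) {
  stopifnot(all(colnames(matrix) %in% samples$sample))
  samples <- samples[match(colnames(matrix), samples$sample), , drop = FALSE]
  bad <- setdiff(unique(samples$group), c("tumor", "normal"))
  if (length(bad) > 0) stop("unknown group label(s): ",
                            paste(bad, collapse = ", "))
  tum <- matrix[, samples$group == "tumor", drop = FALSE]
  nor <- matrix[, samples$group == "normal", drop = FALSE]
  n1 <- ncol(tum); n2 <- ncol(nor)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")

  mean_t <- rowMeans(tum)
  mean_n <- rowMeans(nor)

  if (paired) {
    pt_ <- samples$pair[samples$group == "tumor"]
    pn_ <- samples$pair[samples$group == "normal"]
    if (n1 != n2 || !setequal(pt_, pn_) || anyNA(pt_)) {
      stop("paired test requires complete tumor/normal pairs")
    }
    d <- tum - nor[, match(pt_, pn_), drop = FALSE]
    md <- rowMeans(d)
    sdd <- apply(d, 1, stats::sd)
    tstat <- md / (sdd / sqrt(n1))
    df <- rep(n1 - 1, nrow(matrix))
  } else {
    v1 <- apply(tum, 1, stats::var)
    v2 <- apply(nor, 1, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (mean_t - mean_n) / sqrt(se2)
    # Welch-Satterthwaite degrees of freedom
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }

  p <- 2 * stats::pt(-abs(tstat), df)
  # 0/0: no variance, no difference
  zero_zero <- is.nan(tstat)
  if (any(zero_zero)) {
    warning(sprintf(
      "%d row(s) with zero variance and zero difference; p set to 1",
      sum(zero_zero)))
    p[zero_zero] <- 1
  }
  inf_t <- is.infinite(tstat)       # nonzero difference, zero variance
  p[inf_t] <- 0

  data.frame(
    gene = rownames(matrix),
    mean_tumor = mean_t,
    mean_normal = mean_n,
    log2_fc = mean_t - mean_n,
    fold_change = 2^(mean_t - mean_n),
    p_value = p,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Select significantly differential genes by volcano thresholds
#'
#' Applies the joint fold-change and p-value rule: up means
#' `fold_change > fc_threshold` and `p < alpha`; down means
#' `fold_change < 1 / fc_threshold` and `p < alpha`. Both inequalities are
#' strict, so a fold change of exactly `fc_threshold` is excluded. Also adds
#' a `direction` column (`up` / `down` / `ns`) to the table.
#'
#' @param table A `DiffExprTable` from [differential_test()].
#' @param fc_threshold Fold-change threshold (linear scale), default 1.5.
#' @param alpha Significance level, default 0.05.
#' @return A list: `up` and `down` (character vectors of genes, disjoint) and
#'   `table` (the input with `direction` added).
#' @export
select_differential <- function(table, fc_threshold = 1.5, alpha = 0.05) {
  up <- table$fold_change > fc_threshold & table$p_value < alpha
  down <- table$fold_change < 1 / fc_threshold & table$p_value < alpha
  table$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(up = table$gene[up], down = table$gene[down], table = table)
}

#' Intersect internal differential calls with an external direction-labeled list
#'
#' Keeps the genes that an external study also calls differential in the same
#' direction. Gene symbols are case-normalized (upper case) on both sides
#' before comparison. Counts of retained genes per biotype are reported via
#' `message()` when a biotype map is supplied.
#'
#' @param up,down Character vectors of internally up-/downregulated genes.
#' @param external Data frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`), e.g. a published tumor-vs-normal differential list.
#' @param biotype Optional named character vector, gene to biotype, for the
#'   reported counts.
#' @return A list with filtered `up` and `down` character vectors.
#' @export
intersect_external <- function(up, down, external, biotype = NULL) {
  if (nrow(external) == 0) {
    warning("external differential list is empty; returning empty result")
    return(list(up = character(0), down = character(0)))
  }
  bad <- setdiff(unique(external$direction), c("up", "down"))
  if (length(bad) > 0) stop("bad external direction value(s): ",
                            paste(bad, collapse = ", "))
  both <- intersect(toupper(external$gene[external$direction == "up"]),
                    toupper(external$gene[external$direction == "down"]))
  if (length(both) > 0) {
    stop("gene(s) listed with both directions in the external list: ",
         paste(both, collapse = ", "))
  }
  ext_up <- toupper(external$gene[external$direction == "up"])
  ext_down <- toupper(external$gene[external$direction == "down"])
  keep_up <- up[toupper(up) %in% ext_up]
  keep_down <- down[toupper(down) %in% ext_down]
  if (!is.null(biotype)) {
    for (bt in unique(biotype)) {
      g <- names(biotype)[biotype == bt]
      message(sprintf("intersect_external: %s kept %d up, %d down", bt,
                      sum(keep_up %in% g), sum(keep_down %in% g)))
    }
  }
  list(up = keep_up, down = keep_down)
}

#' Hierarchical clustering of expression rows and samples
#'
#' Average-linkage agglomerative clustering with distance 1 - Pearson r,
#' applied to the selected rows and to the columns. Zero-variance rows make
#' the correlation undefined and raise an error naming the offending row(s).
#' `stats::hclust` resolves merge ties by original index, so leaf order is
#' deterministic.
#'
#' @param matrix Numeric log2 matrix, probes x samples.
#' @param rows Character vector of row names to cluster (default all).
#' @return A list with `row_hclust`, `col_hclust`, `row_order`, `col_order`.
#' @export
hierarchical_cluster <- function(matrix, rows = NULL) {
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- sprintf("row%d", seq_len(nrow(matrix)))
  }
  if (is.null(rows)) rows <- rownames(matrix)
  sub <- matrix[rows, , drop = FALSE]
  if (nrow(sub) < 2) stop("need at least 2 rows to cluster")
  rv <- apply(sub, 1, stats::var)
  if (any(rv == 0)) {
    stop("zero-variance row(s): ",
         paste(rownames(sub)[rv == 0], collapse = ", "))
  }
  dr <- stats::as.dist(1 - stats::cor(t(sub)))
  dc <- stats::as.dist(1 - stats::cor(sub))
  hr <- stats::hclust(dr, method = "average")
  hc <- stats::hclust(dc, method = "average")
  list(row_hclust = hr, col_hclust = hc,
       row_order = rownames(sub)[hr$order],
       col_order = colnames(sub)[hc$order])
}
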