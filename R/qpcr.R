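#' Delta-Cq: target quantification cycle relative to the reference gene
#'
#' `dCq = Cq(target) - Cq(reference)` for each sample, in cycles. Lower dCq
#' means higher expression (the standard Cq convention: fewer cycles are
#' needed to reach threshold when more template is present).
#'
#' @param cq Numeric vector of target-gene Cq values.
#' @param reference_cq Numeric vector of reference-gene (e.g. GAPDH) Cq
#'   values, same length.
#' @return Numeric vector of delta-Cq values.
#' @export
delta_cq <- function(cq, reference_cq) {
  if (length(reference_cq) != length(cq) || anyNA(reference_cq)) {
    stop("each Cq needs a matched reference Cq")
  }
  if (anyNA(cq)) stop("missing Cq value(s)")
  cq - reference_cq
}

#' Relative fold change by the comparative threshold-cycle method
#'
#' `FC = 2^-(dCq_tumor - dCq_normal) = 2^-ddCq`. A ddCq of 0 gives FC 1; a
#' ddCq of 1 (one extra cycle in tumor, i.e. lower expression) gives FC 0.5.
#' Satisfies the reciprocal identity `FC(a, b) * FC(b, a) = 1`.
#'
#' @param dcq_tumor,dcq_normal Delta-Cq of the tumor sample and its paired
#'   normal control.
#' @return Fold change (> 0).
#' @export
ddcq_fold_change <- function(dcq_tumor, dcq_normal) {
  2^(-(dcq_tumor - dcq_normal))
}

#' Paired tumor-vs-normal test on delta-Cq values
#'
#' Two-sided paired t-test on the within-patient tumor-minus-normal delta-Cq
#' differences. Zero variance of the differences leaves the statistic
#' undefined and raises an error.
#'
#' @param values_tumor,values_normal Paired numeric vectors (same patients,
#'   same order), length >= 2.
#' @return A list: `p`, `t`, `df`, `mean_diff`.
#' @export
paired_group_test <- function(values_tumor, values_normal) {
  if (length(values_tumor) != length(values_normal)) {
    stop("paired vectors must have equal length")
  }
  if (length(values_tumor) < 2) stop("need at least 2 pairs")
  d <- values_tumor - values_normal
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences; t statistic undefined")
  }
  n <- length(d)
  tt <- mean(d) / (stats::sd(d) / sqrt(n))
  list(p = 2 * stats::pt(-abs(tt), n - 1), t = tt, df = n - 1,
       mean_diff = mean(d))
}

#' Clinicopathological association table for delta-Cq expression levels
#'
#' For each characteristic (covariate column), reports per-category patient
#' counts, mean and SD of the tumor-tissue delta-Cq, and a p-value:
#' two-sample t-test for two categories (equal-variance by default, Welch via
#' `welch = TRUE`), one-way ANOVA for three or more. Categories with fewer
#' than 2 patients are excluded with a warning. Output row order is
#' independent of patient row order.
#'
#' @param dcq Named numeric vector of per-patient delta-Cq values (names are
#'   patient ids), or unnamed in the same order as `covariates`.
#' @param covariates Data frame, one row per patient, with a `patient` column
#'   plus one column per characteristic.
#' @param welch Use Welch's unequal-variance t-test for 2-category rows.
#' @return Data frame: `characteristic`, `category`, `n`, `mean`, `sd`, `p`,
#'   `test` (`"t"` or `"ANOVA"`; p repeated across the categories of one
#'   characteristic).
#' @export
association_table <- function(dcq, covariates, welch = FALSE) {
  if (!is.null(names(dcq))) {
    dcq <- dcq[covariates$patient]
  }
  if (length(dcq) != nrow(covariates) || anyNA(dcq)) {
    stop("every patient needs a delta-Cq value")
  }
  chars <- setdiff(names(covariates), "patient")
  out <- list()
  for (ch in chars) {
    lab <- as.character(covariates[[ch]])
    cnt <- table(lab)
    small <- names(cnt)[cnt < 2]
    if (length(small) > 0) {
      warning(sprintf(
        "characteristic '%s': excluded category(ies) with < 2 patients: %s",
        ch, paste(small, collapse = ", ")))
    }
    keep_lv <- sort(names(cnt)[cnt >= 2])
    if (length(keep_lv) < 2) next
    sel <- lab %in% keep_lv
    v <- dcq[sel]; g <- factor(lab[sel], levels = keep_lv)
    if (length(keep_lv) == 2) {
      ht <- stats::t.test(v ~ g, var.equal = !welch)
      p <- ht$p.value; test <- "t"
    } else {
      p <- stats::anova(stats::aov(v ~ g))[["Pr(>F)"]][1]
      test <- "ANOVA"
    }
    out[[length(out) + 1L]] <- data.frame(
      characteristic = ch, category = keep_lv,
      n = as.integer(table(g)),
      mean = as.numeric(tapply(v, g, mean)),
      sd = as.numeric(tapply(v, g, stats::sd)),
      p = p, test = test, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) > 0) do.call(rbind, out)
         else data.frame(characteristic = character(0),
                         category = character(0), n = integer(0),
                         mean = numeric(0), sd = numeric(0), p = numeric(0),
                         test = character(0))
  rownames(res) <- NULL
  res
}
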