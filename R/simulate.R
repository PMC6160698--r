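#' Simulation configuration for a planted-truth expression study
#'
#' Builds the parameter set used by [simulate_expression()] and its companion
#' generators. Defaults emulate a metabolism-pathway lncRNA microarray design:
#' 965 lncRNA and 458 protein-coding probes measured on three tumor/normal
#' tissue pairs, with a subset of genes given a planted log2 fold change and a
#' few blocks of genes sharing a latent factor so that they are coexpressed.
#'
#' @param n_lncrna Number of lncRNA probes.
#' @param n_pcg Number of protein-coding probes.
#' @param n_pairs Number of tumor/normal tissue pairs (total samples is
#'   `2 * n_pairs`).
#' @param de_fraction Fraction of genes given a planted differential effect,
#'   in `[0, 1]`. Split evenly between up- and downregulated.
#' @param log2_effect Planted mean log2 fold change (tumor minus normal) for
#'   differential genes, in log2 units.
#' @param noise_sd Residual standard deviation on the log2 scale; must be > 0.
#' @param n_modules Number of planted coexpression modules.
#' @param module_size Genes per module.
#' @param module_corr Target expected pairwise Pearson correlation within a
#'   module, in (0, 1).
#' @param n_go_terms Total number of GO terms emitted by [simulate_go()]; the
#'   first `n_modules` of them are module signature terms.
#' @param go_background_rate Per-gene probability of annotation to each
#'   non-signature (background) term.
#' @param mirna_count Number of planted miRNA-target pairs (an equal number of
#'   same-direction decoy pairs is generated alongside).
#' @param de_module_overlap If `FALSE` (default) differential genes are drawn
#'   disjointly from module genes, keeping ground-truth contingencies
#'   unambiguous.
#' @param seed Integer RNG seed; identical configurations give identical
#'   output.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_lncrna = 965, n_pcg = 458, n_pairs = 3,
                       de_fraction = 0.1, log2_effect = 2, noise_sd = 0.5,
                       n_modules = 3, module_size = 10, module_corr = 0.8,
                       n_go_terms = 20, go_background_rate = 0.05,
                       mirna_count = 10, de_module_overlap = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_lncrna = as.integer(n_lncrna), n_pcg = as.integer(n_pcg),
    n_pairs = as.integer(n_pairs), de_fraction = de_fraction,
    log2_effect = log2_effect, noise_sd = noise_sd,
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    module_corr = module_corr, n_go_terms = as.integer(n_go_terms),
    go_background_rate = go_background_rate,
    mirna_count = as.integer(mirna_count),
    de_module_overlap = isTRUE(de_module_overlap), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_lncrna", "n_pcg", "n_pairs", "n_modules", "module_size",
              "n_go_terms", "mirna_count")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("'%s' must be a nonnegative count", f))
    }
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("'de_fraction' must lie in [0, 1]")
  }
  if (cfg$n_modules > 0 &&
      (cfg$module_corr <= 0 || cfg$module_corr >= 1)) {
    stop("'module_corr' must lie in (0, 1)")
  }
  if (cfg$noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (cfg$go_background_rate < 0 || cfg$go_background_rate > 1) {
    stop("'go_background_rate' must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Simulate a paired tumor/normal log2 expression matrix with planted truth
#'
#' Generates log2-scale intensities for `n_lncrna + n_pcg` genes across
#' `2 * n_pairs` samples. A `de_fraction` of genes (half up, half down)
#' receive a `log2_effect` shift in the tumor columns before noise. Each of
#' `n_modules` blocks of `module_size` genes shares a per-sample latent
#' factor with loading `sqrt(module_corr)` (on the total-variance scale), so
#' the expected within-module pairwise Pearson correlation equals
#' `module_corr`. Expression is simulated directly on the log2 scale
#' (Gaussian residuals); the downstream pipeline consumes log2 intensities,
#' so intensity-scale realism is not attempted.
#'
#' @param config A [sim_config()] object.
#' @param truth Optional `truth` component from a previous run: reuse its
#'   planted differential genes and module membership and draw only new
#'   noise, emulating an independent dataset measuring the same biology
#'   (useful for multi-dataset consensus analyses).
#'
#' @return A list with components:
#'   \describe{
#'     \item{matrix}{numeric matrix, genes x samples, log2 intensities.}
#'     \item{samples}{data frame with `sample`, `group` (`tumor`/`normal`)
#'       and `pair` columns.}
#'     \item{genes}{data frame with `gene` and `biotype`
#'       (`lncRNA`/`protein_coding`) columns.}
#'     \item{truth}{ground truth: `de_genes` (data frame of `gene`,
#'       `direction`), `module_membership` (named integer vector, module ids
#'       dense from 0), and the config used.}
#'   }
#' @export
simulate_expression <- function(config, truth = NULL) {
  validate_sim_config(config)
  n_genes <- config$n_lncrna + config$n_pcg
  if (config$n_modules * config$module_size > n_genes) {
    stop("module_size * n_modules exceeds the total gene count")
  }
  n_samp <- 2L * config$n_pairs
  set.seed(config$seed)

  genes <- character(n_genes)
  if (config$n_lncrna > 0) {
    genes[seq_len(config$n_lncrna)] <-
      sprintf("LNC%04d", seq_len(config$n_lncrna))
  }
  if (config$n_pcg > 0) {
    genes[config$n_lncrna + seq_len(config$n_pcg)] <-
      sprintf("PCG%04d", seq_len(config$n_pcg))
  }
  biotype <- rep(c("lncRNA", "protein_coding"),
                 c(config$n_lncrna, config$n_pcg))

  samples <- data.frame(
    sample = c(sprintf("T%03d", seq_len(config$n_pairs)),
               sprintf("N%03d", seq_len(config$n_pairs))),
    group = rep(c("tumor", "normal"), each = config$n_pairs),
    pair = rep(sprintf("P%03d", seq_len(config$n_pairs)), 2L),
    stringsAsFactors = FALSE
  )

  # planted module membership: each module is a lncRNA-centered block (one
  # dedicated lncRNA hub where available, remaining members any biotype),
  # mirroring ceRNA neighborhoods on a lncRNA/mRNA array
  module_membership <- integer(0)
  module_idx <- integer(0)
  if (!is.null(truth)) {
    module_membership <- truth$module_membership
    module_idx <- match(names(module_membership), genes)
    if (anyNA(module_idx)) stop("reused truth names unknown in this config")
  } else if (config$n_modules > 0 && config$module_size > 0) {
    pool_lnc <- sample(seq_len(config$n_lncrna))
    pool_all <- sample.int(n_genes)
    for (m in seq_len(config$n_modules)) {
      hub <- utils::head(setdiff(pool_lnc, module_idx), 1)
      rest <- setdiff(pool_all, c(module_idx, hub))
      members <- c(hub, utils::head(rest, config$module_size - length(hub)))
      module_idx <- c(module_idx, members)
      module_membership <- c(module_membership,
                             rep(m - 1L, length(members)))
    }
    names(module_membership) <- genes[module_idx]
  }

  # planted DE genes, disjoint from module genes by default
  if (!is.null(truth)) {
    de_genes <- truth$de_genes
    de_idx <- match(de_genes$gene, genes)
    if (anyNA(de_idx)) stop("reused truth names unknown in this config")
    de_dir <- de_genes$direction
    n_de <- length(de_idx)
  } else {
    de_pool <- seq_len(n_genes)
    if (!config$de_module_overlap) de_pool <- setdiff(de_pool, module_idx)
    n_de <- round(config$de_fraction * n_genes)
    n_de <- min(n_de, length(de_pool))
    de_idx <- if (n_de > 0) sample(de_pool, n_de) else integer(0)
    de_dir <- rep_len(c("up", "down"), n_de)
    de_genes <- data.frame(gene = genes[de_idx], direction = de_dir,
                           stringsAsFactors = FALSE)
  }

  baseline <- stats::runif(n_genes, 6, 12)
  mat <- matrix(stats::rnorm(n_genes * n_samp, sd = config$noise_sd),
                n_genes, n_samp,
                dimnames = list(genes, samples$sample))
  mat <- mat + baseline

  # shared latent factor per module: loading sqrt(rho), residual sd
  # sqrt(1 - rho), both scaled by noise_sd, so pairwise corr == rho
  if (length(module_idx) > 0) {
    rho <- config$module_corr
    for (m in unique(module_membership)) {
      rows <- module_idx[module_membership == m]
      factor_s <- stats::rnorm(n_samp)
      resid <- matrix(stats::rnorm(length(rows) * n_samp), length(rows))
      signal <- config$noise_sd *
        (sqrt(rho) * matrix(factor_s, length(rows), n_samp, byrow = TRUE) +
           sqrt(1 - rho) * resid)
      mat[rows, ] <- baseline[rows] + signal
    }
  }

  # tumor-mean minus normal-mean equals +/- log2_effect before noise
  tumor_cols <- which(samples$group == "tumor")
  if (n_de > 0) {
    shift <- ifelse(de_dir == "up", config$log2_effect, -config$log2_effect)
    mat[de_idx, tumor_cols] <- mat[de_idx, tumor_cols] + shift
  }

  truth <- list(de_genes = de_genes,
                module_membership = module_membership,
                config = config)
  list(matrix = mat, samples = samples,
       genes = data.frame(gene = genes, biotype = biotype,
                          stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a GO biological-process annotation with planted signature terms
#'
#' Emits `n_go_terms` gene sets over the simulated gene space. The first
#' `n_modules` terms are module signature terms: each annotates at least 80%
#' of one planted module's members (plus background members). The remaining
#' terms annotate each gene independently with probability
#' `go_background_rate`.
#'
#' @param truth The `truth` component returned by [simulate_expression()].
#' @param config The same [sim_config()]; `n_go_terms` must be at least
#'   `n_modules` and positive whenever modules exist.
#' @param genes Character vector of all gene symbols in the study (the
#'   annotation universe).
#'
#' @return A named list of character vectors (term id to gene set), with a
#'   `term_name` attribute mapping ids to descriptions; GMT-ready via
#'   [write_gmt()]. Empty terms are dropped.
#' @export
simulate_go <- function(truth, config, genes) {
  validate_sim_config(config)
  n_modules <- config$n_modules
  if (n_modules > 0 && config$n_go_terms == 0) {
    stop("n_go_terms must be positive when planted modules exist")
  }
  if (config$n_go_terms < n_modules) {
    stop("n_go_terms must be at least n_modules (one signature term each)")
  }
  set.seed(config$seed + 104729L)  # independent stream from the matrix

  sets <- list()
  term_name <- character(0)
  if (n_modules > 0) {
    mm <- truth$module_membership
    for (m in seq_len(n_modules)) {
      members <- names(mm)[mm == (m - 1L)]
      k <- ceiling(0.8 * length(members))
      core <- if (length(members) > 0) sample(members, k) else character(0)
      id <- sprintf("GO:SIG%04d", m)
      sets[[id]] <- sort(core)
      term_name[id] <- sprintf("planted signature process module %d", m - 1L)
    }
  }
  n_bg <- config$n_go_terms - n_modules
  if (n_bg > 0 && config$go_background_rate > 0) {
    for (b in seq_len(n_bg)) {
      hit <- genes[stats::runif(length(genes)) < config$go_background_rate]
      id <- sprintf("GO:BG%04d", b)
      if (length(hit) > 0) {
        sets[[id]] <- sort(hit)
        term_name[id] <- sprintf("background process %d", b)
      }
    }
  }
  attr(sets, "term_name") <- term_name
  sets
}

#' Simulate miRNA direction and target tables with planted anti-correlation
#'
#' Generates `mirna_count` planted (miRNA, target) pairs in which the miRNA's
#' differential direction is opposite to its target's, and an equal number of
#' same-direction decoy pairs. Targets are drawn from the planted
#' differential genes, whose directions are known. Decoys are flagged in the
#' returned truth so tests can verify that the opposite-direction filter
#' removes exactly them.
#'
#' @param truth The `truth` component of [simulate_expression()]; must
#'   contain at least one differential gene when `mirna_count > 0`.
#' @param config A [sim_config()].
#'
#' @return A list with `pairs` (data frame: `mirna`, `target`, `planted`
#'   logical), and `mirna_directions` (data frame: `mirna`, `direction`).
#' @export
simulate_mirna <- function(truth, config) {
  validate_sim_config(config)
  n <- config$mirna_count
  if (n == 0 && nrow(truth$de_genes) > 0) {
    stop("mirna_count is 0 but targets were requested")
  }
  if (n == 0) {
    return(list(pairs = data.frame(mirna = character(0), target = character(0),
                                   planted = logical(0)),
                mirna_directions = data.frame(mirna = character(0),
                                              direction = character(0))))
  }
  if (nrow(truth$de_genes) == 0) {
    stop("no differential genes available as miRNA targets")
  }
  set.seed(config$seed + 224737L)
  targets <- truth$de_genes[
    sample.int(nrow(truth$de_genes), 2L * n, replace = TRUE), , drop = FALSE]
  mirna <- sprintf("miR-%04d", seq_len(2L * n))
  planted <- rep(c(TRUE, FALSE), each = n)
  flip <- c(up = "down", down = "up")
  direction <- ifelse(planted, flip[targets$direction], targets$direction)
  list(
    pairs = data.frame(mirna = mirna, target = targets$gene,
                       planted = planted, stringsAsFactors = FALSE),
    mirna_directions = data.frame(mirna = mirna,
                                  direction = unname(direction),
                                  stringsAsFactors = FALSE)
  )
}

#' Simulate a qPCR Cq table with clinicopathological covariates
#'
#' Generates, per patient, quantification cycles (Cq) for a target gene and
#' a reference gene (GAPDH-like) in tumor and paired normal tissue. The
#' tumor-tissue delta-Cq (target minus reference) differs from the normal
#' tissue by `effect_dcq` cycles. The reference gene carries no planted group
#' effect. Covariate columns mimic the usual clinicopathological categories
#' (age group, sex, invasion, metastasis, differentiation); named entries of
#' `covariate_effects` add that many cycles to the tumor delta-Cq of patients
#' in the second (or later) category of the covariate, planting a Table-1
#' style association.
#'
#' @param n_patients Number of patients (>= 2).
#' @param effect_dcq Planted tumor-minus-normal difference in delta-Cq,
#'   in cycles.
#' @param sd Residual Cq standard deviation in cycles; must be > 0.
#' @param covariate_effects Named numeric vector, e.g.
#'   `c(invasion = 1)`; names must be covariate column names.
#' @param seed Integer RNG seed.
#'
#' @return A list with `cq` (long data frame: `patient`, `tissue`, `gene`,
#'   `cq`, `reference_cq`) and `covariates` (one row per patient).
#' @export
simulate_cq <- function(n_patients, effect_dcq = 0, sd = 1,
                        covariate_effects = NULL, seed = 1L) {
  if (n_patients < 2) stop("'n_patients' must be at least 2")
  if (sd <= 0) stop("'sd' must be > 0")
  set.seed(as.integer(seed))
  pts <- sprintf("PT%03d", seq_len(n_patients))

  covariates <- data.frame(
    patient = pts,
    age = sample(c(">=60", "<60"), n_patients, TRUE, prob = c(0.66, 0.34)),
    sex = sample(c("male", "female"), n_patients, TRUE, prob = c(0.73, 0.27)),
    invasion = sample(c("T1-T3", "T4"), n_patients, TRUE,
                      prob = c(0.38, 0.62)),
    metastasis = sample(c("M0", "M1"), n_patients, TRUE, prob = c(0.91, 0.09)),
    differentiation = sample(c("well", "moderate", "poor"), n_patients, TRUE,
                             prob = c(0.09, 0.50, 0.41)),
    stringsAsFactors = FALSE
  )

  base_dcq <- 5            # target expressed ~5 cycles above reference
  ref_level <- 20          # reference-gene Cq level, both tissues

  tumor_shift <- rep(effect_dcq, n_patients)
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), names(covariates))
    if (length(bad) > 0) {
      stop("unknown covariate(s): ", paste(bad, collapse = ", "))
    }
    for (cv in names(covariate_effects)) {
      lv <- sort(unique(covariates[[cv]]))
      in_later <- covariates[[cv]] != lv[1]
      tumor_shift <- tumor_shift + covariate_effects[[cv]] * in_later
    }
  }

  mk <- function(tissue, shift) {
    ref <- stats::rnorm(n_patients, ref_level, sd)
    tgt <- ref + base_dcq + shift + stats::rnorm(n_patients, 0, sd)
    data.frame(patient = pts, tissue = tissue, gene = "TARGET",
               cq = tgt, reference_cq = ref, stringsAsFactors = FALSE)
  }
  cq <- rbind(mk("tumor", tumor_shift), mk("normal", 0))
  list(cq = cq, covariates = covariates)
}
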