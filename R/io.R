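#' Read an expression matrix with its sample sheet
#'
#' The matrix TSV has probe ids in the first column and one column per
#' sample; the sample sheet TSV supplies `sample`, `group`
#' (`tumor`/`normal`) and `pair` for every matrix column. An optional probe
#' annotation TSV (`gene`, `biotype`) is merged in. Gene symbols are
#' upper-cased at this boundary so joins against external tables are
#' case-insensitive.
#'
#' @param matrix_path Path to the expression TSV.
#' @param samples_path Path to the sample-sheet TSV.
#' @param annotation_path Optional path to the probe annotation TSV.
#' @return A list: `matrix` (numeric, probes x samples), `samples`
#'   (data frame), and `genes` (data frame or `NULL`).
#' @export
read_expression <- function(matrix_path, samples_path,
                            annotation_path = NULL) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  probes <- toupper(raw[[1]])
  dup <- unique(probes[duplicated(probes)])
  if (length(dup) > 0) {
    stop("duplicated probe id(s): ", paste(dup, collapse = ", "))
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(mat))) {
    stop("duplicated sample id(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "))
  }
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(mat), nrow(mat)))) & !is.na(raw[, -1]),
      arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad[1, 1], colnames(mat)[bad[1, 2]]))
  }
  rownames(mat) <- probes

  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(mat), samples$sample)
  if (length(missing) > 0) {
    stop("sample(s) missing from the sample sheet: ",
         paste(missing, collapse = ", "))
  }
  samples <- samples[match(colnames(mat), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL

  genes <- NULL
  if (!is.null(annotation_path)) {
    genes <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    genes$gene <- toupper(genes$gene)
  }
  list(matrix = mat, samples = samples, genes = genes)
}

#' Write an expression matrix and sample sheet as TSV
#'
#' @param matrix Numeric matrix, probes x samples.
#' @param samples Sample sheet data frame.
#' @param matrix_path,samples_path Output paths.
#' @param genes Optional probe annotation data frame, written to
#'   `annotation_path`.
#' @param annotation_path Optional output path for the annotation.
#' @param digits Decimal places written (default 6).
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(matrix, samples, matrix_path, samples_path,
                             genes = NULL, annotation_path = NULL,
                             digits = 6) {
  df <- data.frame(probe = rownames(matrix),
                   round(matrix, digits), check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genes) && !is.null(annotation_path)) {
    utils::write.table(genes, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then gene symbols. Symbols are upper-cased and deduplicated within each
#' term; terms left empty after parsing are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with a `term_name` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 0L) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  ids <- vapply(parts, `[`, "", 1)
  names_ <- vapply(parts, `[`, "", 2)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  names(sets) <- ids
  empty <- vapply(sets, length, 0L) == 0
  if (any(empty)) {
    warning(sprintf("dropped %d empty term(s)", sum(empty)))
    sets <- sets[!empty]; names_ <- names_[!empty]
  }
  attr(sets, "term_name") <- stats::setNames(names_, names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors; an optional `term_name`
#'   attribute supplies descriptions.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  nm <- attr(sets, "term_name")
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(nm) && !is.na(nm[id])) nm[id] else id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a coexpression edge table
#'
#' @param path TSV path with columns `gene_a`, `gene_b`, and any of `r`, `n`,
#'   `p`, `p_adj`, `sign`, `support`.
#' @return Data frame of edges.
#' @export
read_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_edges
#' @param edges Edge data frame (e.g. `build_network()$edges`).
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Thresholds default to the standard workflow values: differential genes at
#' fold change > 1.5 and p < 0.05; coexpression edges and GO assignments at
#' adjusted p < 0.05; lncRNA hubs need more than 3 coexpressed protein-coding
#' neighbors; consensus edges need support from at least 50 datasets.
#'
#' @param ... Overrides for any config field.
#' @return A named list (class `pipeline_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    fc_threshold = 1.5,
    alpha_de = 0.05,
    alpha_edge = 0.05,
    alpha_enrich = 0.05,
    min_neighbors = 3,
    min_support = 50,
    min_present = 3,
    paired = FALSE,
    seed = 1,
    stages = list(normalize = TRUE, diffexpr = TRUE, intersect = FALSE,
                  coexpress = TRUE, annotate = TRUE, integrate = FALSE),
    paths = list(matrix = NULL, samples = NULL, annotation = NULL,
                 gmt = NULL, external = NULL, ppi = NULL,
                 mirna_pairs = NULL, mirna_directions = NULL,
                 outdir = "results")
  )
  over <- list(...)
  for (k in names(over)) {
    if (k %in% c("stages", "paths")) {
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else cfg[[k]] <- over[[k]]
  }
  for (a in c("alpha_de", "alpha_edge", "alpha_enrich")) {
    if (cfg[[a]] <= 0 || cfg[[a]] > 1) stop(a, " must lie in (0, 1]")
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` the path (invisibly); `read_config` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on files
#'
#' Executes the enabled stages in order: quantile normalization and presence
#' filtering, differential expression and volcano selection, optional
#' intersection with an external direction-labeled list, coexpression network
#' construction over the differential genes, guilt-by-association GO
#' annotation of lncRNA hubs, and (when PPI/miRNA inputs are configured)
#' network integration with a link-type summary. Every intermediate is
#' written under `config$paths$outdir` and a JSON run manifest records the
#' config, input checksums and per-stage row counts.
#'
#' @param config A `pipeline_config` from [default_config()] /
#'   [read_config()]. `paths$matrix` and `paths$samples` are required;
#'   `paths$annotation` (biotype) and `paths$gmt` are required for the
#'   annotation stage.
#' @param presence_flags Optional logical matrix of vendor presence calls;
#'   when `NULL`, the above-column-median fallback rule is used.
#' @return The manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, presence_flags = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  if (is.null(p$matrix) || is.null(p$samples)) {
    stop("config$paths$matrix and $samples are required")
  }
  outdir <- p$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), counts = list(),
                  inputs = list(), tool_version = as.character(
                    utils::packageVersion("lncmetnet")))
  for (k in names(p)) {
    if (!is.null(p[[k]]) && k != "outdir" && file.exists(p[[k]])) {
      manifest$inputs[[k]] <- unname(tools::md5sum(p[[k]]))
    }
  }
  stage <- "read"
  res <- tryCatch({
    dat <- read_expression(p$matrix, p$samples, p$annotation)
    mat <- dat$matrix
    biotype <- if (!is.null(dat$genes)) {
      stats::setNames(dat$genes$biotype, dat$genes$gene)
    } else NULL

    if (isTRUE(config$stages$normalize)) {
      stage <- "normalize"
      mat <- quantile_normalize(mat)
      flags <- if (is.null(presence_flags)) presence_flags_median(mat)
               else presence_flags
      mat <- presence_filter(mat, flags, config$min_present)
      manifest$counts$retained_probes <- nrow(mat)
      write_expression(mat, dat$samples,
                       file.path(outdir, "normalized_matrix.tsv"),
                       file.path(outdir, "samples.tsv"))
    }

    de <- NULL
    if (isTRUE(config$stages$diffexpr)) {
      stage <- "diffexpr"
      tab <- differential_test(mat, dat$samples, paired = config$paired)
      de <- select_differential(tab, config$fc_threshold, config$alpha_de)
      manifest$counts$de_up <- length(de$up)
      manifest$counts$de_down <- length(de$down)
      out_tab <- de$table
      if (!is.null(biotype)) out_tab$biotype <- unname(biotype[out_tab$gene])
      utils::write.table(out_tab, file.path(outdir, "diffexpr.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (isTRUE(config$stages$intersect) && !is.null(p$external)) {
      stage <- "intersect"
      ext <- utils::read.delim(p$external, stringsAsFactors = FALSE)
      flt <- intersect_external(de$up, de$down, ext, biotype)
      de$up <- flt$up; de$down <- flt$down
      manifest$counts$de_up_external <- length(de$up)
      manifest$counts$de_down_external <- length(de$down)
    }

    net <- NULL
    if (isTRUE(config$stages$coexpress)) {
      stage <- "coexpress"
      scope_genes <- if (!is.null(de)) c(de$up, de$down) else rownames(mat)
      net <- build_network(mat, alpha = config$alpha_edge,
                           genes = scope_genes, biotype = biotype)
      manifest$counts$coexpr_edges <- nrow(net$edges)
      write_edges(net$edges, file.path(outdir, "coexpr_edges.tsv"))
    }

    if (isTRUE(config$stages$annotate) && !is.null(p$gmt)) {
      stage <- "annotate"
      sets <- read_gmt(p$gmt)
      enr <- annotate_lncrnas(net, sets, biotype = biotype,
                              min_neighbors = config$min_neighbors,
                              alpha = config$alpha_enrich)
      manifest$counts$enrichment_rows <- nrow(enr)
      manifest$counts$annotated_lncrnas <-
        length(unique(enr$lncrna[enr$assigned]))
      utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (isTRUE(config$stages$integrate) && !is.null(p$ppi) &&
        !is.null(p$mirna_pairs) && !is.null(p$mirna_directions)) {
      stage <- "integrate"
      ppi <- utils::read.delim(p$ppi, stringsAsFactors = FALSE)
      pairs <- utils::read.delim(p$mirna_pairs, stringsAsFactors = FALSE)
      mdir <- utils::read.delim(p$mirna_directions, stringsAsFactors = FALSE)
      dir_map <- stats::setNames(de$table$direction, de$table$gene)
      dir_map <- dir_map[dir_map != "ns"]
      kept <- filter_mirna_targets(pairs, mdir,
                                   data.frame(gene = names(dir_map),
                                              direction = unname(dir_map)))
      node_table <- data.frame(
        gene = de$table$gene,
        biotype = if (!is.null(biotype)) unname(biotype[de$table$gene])
                  else "protein_coding",
        direction = de$table$direction,
        log2_fc = de$table$log2_fc, stringsAsFactors = FALSE)
      node_table <- rbind(node_table, data.frame(
        gene = unique(mdir$mirna), biotype = "miRNA",
        direction = mdir$direction[match(unique(mdir$mirna), mdir$mirna)],
        log2_fc = NA_real_))
      inet <- integrate_network(net$edges, ppi, kept, node_table,
                                permissive = TRUE)
      summ <- summarize_network(inet)
      manifest$counts$network_summary <- summ
      export_network(inet, file.path(outdir, "network.graphml"), "GraphML")
      jsonlite::write_json(summ, file.path(outdir, "network_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest
  }, error = function(e) {
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(res, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}
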