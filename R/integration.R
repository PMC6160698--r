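#' Keep miRNA-target pairs whose miRNA is regulated in the opposite direction
#'
#' A candidate (miRNA, target) regulation is retained only when the miRNA's
#' differential direction in the disease differs from its target's, the
#' pattern expected of a repressive regulator. Pairs where either side has no
#' known direction are dropped with a logged count.
#'
#' @param pairs Data frame with columns `mirna`, `target`.
#' @param mirna_directions Named character vector or data frame
#'   (`mirna`, `direction`) with values `"up"`/`"down"`.
#' @param gene_directions Named character vector or data frame
#'   (`gene`, `direction`).
#' @return The filtered subset of `pairs` (same columns). Idempotent.
#' @export
filter_mirna_targets <- function(pairs, mirna_directions, gene_directions) {
  as_map <- function(x, key, val) {
    if (is.data.frame(x)) stats::setNames(x[[val]], x[[key]]) else x
  }
  mdir <- as_map(mirna_directions, "mirna", "direction")
  gdir <- as_map(gene_directions, "gene", "direction")
  bad <- setdiff(stats::na.omit(unique(c(mdir, gdir))), c("up", "down"))
  if (length(bad) > 0) {
    stop("malformed direction value(s): ", paste(bad, collapse = ", "))
  }
  dm <- unname(mdir[pairs$mirna])
  dg <- unname(gdir[pairs$target])
  unknown <- is.na(dm) | is.na(dg)
  if (any(unknown)) {
    message(sprintf(
      "filter_mirna_targets: dropped %d pair(s) with unknown direction",
      sum(unknown)))
  }
  keep <- !unknown & dm != dg
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate coexpression, PPI and miRNA-target evidence into a typed network
#'
#' Builds a typed multigraph over lncRNA, mRNA (protein-coding) and miRNA
#' nodes. A node pair may carry several edge types at once (e.g. both a PPI
#' and a positive coexpression link). Coexpression and PPI edges are
#' undirected; miRNA-target edges are stored miRNA -> target. Node
#' attributes (biotype, differential direction, |log2 FC|) are kept for
#' visualization and summaries.
#'
#' @param coexpr_edges Data frame `gene_a`, `gene_b`, `sign`
#'   (`positive`/`negative`), e.g. `build_network()$edges`.
#' @param ppi_edges Data frame `protein_a`, `protein_b`.
#' @param mirna_edges Data frame `mirna`, `target` (already direction
#'   filtered via [filter_mirna_targets()]).
#' @param node_table Data frame `gene`, `biotype`
#'   (`lncRNA`/`protein_coding`/`miRNA`), `direction`, `log2_fc`. Every node
#'   referenced by an edge must be present unless `permissive = TRUE`, in
#'   which case missing nodes are admitted with direction `"unknown"`.
#' @param permissive Admit edge endpoints absent from `node_table`.
#' @return An object of class `integrated_network`: list with `nodes` (data
#'   frame) and `edges` (data frame `from`, `to`, `type` with type in
#'   `coexpr_pos`, `coexpr_neg`, `ppi`, `mirna_target`).
#' @export
integrate_network <- function(coexpr_edges, ppi_edges, mirna_edges,
                              node_table, permissive = FALSE) {
  canon <- function(a, b) list(from = pmin(a, b), to = pmax(a, b))

  edges <- list()
  if (!is.null(coexpr_edges) && nrow(coexpr_edges) > 0) {
    cc <- canon(coexpr_edges$gene_a, coexpr_edges$gene_b)
    edges[[length(edges) + 1L]] <- data.frame(
      from = cc$from, to = cc$to,
      type = ifelse(coexpr_edges$sign == "positive",
                    "coexpr_pos", "coexpr_neg"),
      stringsAsFactors = FALSE)
  }
  if (!is.null(ppi_edges) && nrow(ppi_edges) > 0) {
    cc <- canon(ppi_edges$protein_a, ppi_edges$protein_b)
    edges[[length(edges) + 1L]] <- data.frame(
      from = cc$from, to = cc$to, type = "ppi", stringsAsFactors = FALSE)
  }
  if (!is.null(mirna_edges) && nrow(mirna_edges) > 0) {
    edges[[length(edges) + 1L]] <- data.frame(
      from = mirna_edges$mirna, to = mirna_edges$target,
      type = "mirna_target", stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges)
           else data.frame(from = character(0), to = character(0),
                           type = character(0), stringsAsFactors = FALSE)
  if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")

  referenced <- unique(c(edges$from, edges$to))
  missing <- setdiff(referenced, node_table$gene)
  if (length(missing) > 0) {
    if (!permissive) {
      stop("edge(s) reference unknown node(s): ",
           paste(sort(missing), collapse = ", "))
    }
    node_table <- rbind(node_table, data.frame(
      gene = missing,
      biotype = ifelse(grepl("^miR", missing), "miRNA", "protein_coding"),
      direction = "unknown", log2_fc = NA_real_, stringsAsFactors = FALSE))
  }
  nodes <- node_table[node_table$gene %in% referenced, , drop = FALSE]
  rownames(nodes) <- NULL

  bt <- stats::setNames(nodes$biotype, nodes$gene)
  mt <- edges$type == "mirna_target"
  if (any(mt)) {
    one_mirna <- (bt[edges$from[mt]] == "miRNA") !=
      (bt[edges$to[mt]] == "miRNA")
    if (!all(one_mirna)) {
      stop("every mirna_target edge must have exactly one miRNA endpoint")
    }
  }
  co <- edges$type %in% c("coexpr_pos", "coexpr_neg")
  if (any(co) && any(bt[edges$from[co]] == "miRNA" |
                     bt[edges$to[co]] == "miRNA")) {
    stop("coexpression edges must not touch miRNA nodes")
  }

  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to, edges$type), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "integrated_network")
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf("integrated network: %d nodes, %d typed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$edges$type))
  invisible(x)
}

#' Link-type and overlap summary of an integrated network
#'
#' Counts edges per type; counts the PPI pairs that also carry a
#' coexpression edge (overlap), split by the coexpression edge's sign; and
#' counts miRNA-target links whose target is a lncRNA.
#'
#' @param network An `integrated_network`.
#' @return A list: `n_mirna_target`, `n_coexpr_pos`, `n_coexpr_neg`, `n_ppi`,
#'   `n_ppi_overlap_total`, `n_ppi_overlap_pos`, `n_ppi_overlap_neg`,
#'   `n_mirna_lncrna_links`. Always `overlap_total = overlap_pos +
#'   overlap_neg <= n_ppi`.
#' @export
summarize_network <- function(network) {
  e <- network$edges
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to), sep = "\r")
  ppi <- e[e$type == "ppi", , drop = FALSE]
  pos <- e[e$type == "coexpr_pos", , drop = FALSE]
  neg <- e[e$type == "coexpr_neg", , drop = FALSE]
  mt <- e[e$type == "mirna_target", , drop = FALSE]
  ov_pos <- sum(key(ppi) %in% key(pos))
  # a PPI pair overlapping both signs is counted once, as positive
  ov_neg <- sum(key(ppi) %in% key(neg) & !(key(ppi) %in% key(pos)))
  bt <- stats::setNames(network$nodes$biotype, network$nodes$gene)
  mirna_end <- ifelse(bt[mt$from] == "miRNA", mt$to, mt$from)
  list(
    n_mirna_target = nrow(mt),
    n_coexpr_pos = nrow(pos),
    n_coexpr_neg = nrow(neg),
    n_ppi = nrow(ppi),
    n_ppi_overlap_total = ov_pos + ov_neg,
    n_ppi_overlap_pos = ov_pos,
    n_ppi_overlap_neg = ov_neg,
    n_mirna_lncrna_links = sum(bt[mirna_end] == "lncRNA", na.rm = TRUE)
  )
}

#' Degree breakdown of one node in the integrated network
#'
#' @param network An `integrated_network`.
#' @param node Gene/miRNA symbol present in the network.
#' @return A list: `coexpr_pcg` (coexpressed protein-coding neighbors),
#'   `coexpr_lncrna` (coexpressed lncRNA neighbors), `mirna` (regulating
#'   miRNAs).
#' @export
node_profile <- function(network, node) {
  if (!node %in% network$nodes$gene) stop("node not in network: ", node)
  e <- network$edges
  bt <- stats::setNames(network$nodes$biotype, network$nodes$gene)
  co <- e[e$type %in% c("coexpr_pos", "coexpr_neg"), , drop = FALSE]
  nb <- unique(c(co$to[co$from == node], co$from[co$to == node]))
  mt <- e[e$type == "mirna_target", , drop = FALSE]
  regulators <- unique(c(mt$from[mt$to == node & bt[mt$from] == "miRNA"],
                         mt$to[mt$from == node & bt[mt$to] == "miRNA"]))
  list(coexpr_pcg = sum(bt[nb] == "protein_coding"),
       coexpr_lncrna = sum(bt[nb] == "lncRNA"),
       mirna = length(regulators))
}

#' Export an integrated network to SIF, GraphML or TSV
#'
#' GraphML (via igraph) and TSV round-trip the full network: nodes, typed
#' edges and node attributes are reproduced exactly by [import_network()].
#' SIF carries edges only (`from<TAB>type<TAB>to`). TSV export writes an edge
#' table and a `<path>.nodes.tsv` sidecar.
#'
#' @param network An `integrated_network`.
#' @param path Output file path.
#' @param format One of `"SIF"`, `"GraphML"`, `"TSV"`.
#' @return The path, invisibly.
#' @export
export_network <- function(network, path, format = c("GraphML", "SIF", "TSV")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format"))
  if (format == "SIF") {
    writeLines(paste(network$edges$from, network$edges$type,
                     network$edges$to, sep = "\t"), path)
  } else if (format == "TSV") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(network$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      network$edges,
      directed = FALSE,
      vertices = data.frame(name = network$nodes$gene,
                            biotype = network$nodes$biotype,
                            direction = network$nodes$direction,
                            log2_fc = network$nodes$log2_fc))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format One of `"GraphML"`, `"TSV"`, `"SIF"`. SIF restores edges and
#'   node names only (no attributes).
#' @return An `integrated_network`.
#' @export
import_network <- function(path, format = c("GraphML", "SIF", "TSV")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format"))
  if (format == "GraphML") {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    vd <- igraph::as_data_frame(g, what = "vertices")
    nodes <- data.frame(gene = vd$name, biotype = vd$biotype,
                        direction = vd$direction, log2_fc = vd$log2_fc,
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = ed$from, to = ed$to, type = ed$type,
                        stringsAsFactors = FALSE)
  } else if (format == "TSV") {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE)
    nodes <- utils::read.delim(paste0(path, ".nodes.tsv"),
                               stringsAsFactors = FALSE)
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    edges <- data.frame(from = vapply(lines, `[`, "", 1),
                        type = vapply(lines, `[`, "", 2),
                        to = vapply(lines, `[`, "", 3),
                        stringsAsFactors = FALSE)[, c("from", "to", "type")]
    nodes <- data.frame(gene = unique(c(edges$from, edges$to)),
                        biotype = NA_character_, direction = NA_character_,
                        log2_fc = NA_real_, stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$from, edges$to, edges$type), , drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "integrated_network")
}
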