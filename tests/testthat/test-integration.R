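test_that("opposite-direction filter keeps anti-regulated pairs only", {
  pairs <- data.frame(mirna = c("m1", "m2", "m3"),
                      target = c("gUp", "gUp", "gNew"))
  mdir <- data.frame(mirna = c("m1", "m2"), direction = c("down", "up"))
  gdir <- data.frame(gene = "gUp", direction = "up")
  expect_message(kept <- filter_mirna_targets(pairs, mdir, gdir), "unknown")
  expect_equal(kept$mirna, "m1")      # m2 same direction, m3 unknown
  # idempotent, output subset of input
  expect_equal(filter_mirna_targets(kept, mdir, gdir), kept)
  expect_error(
    filter_mirna_targets(pairs, data.frame(mirna = "m1",
                                           direction = "sideways"), gdir),
    "malformed")
})

test_that("integration builds a typed multigraph with validated nodes", {
  nodes <- data.frame(
    gene = c("L1", "P1", "P2", "P3", "miR-1"),
    biotype = c("lncRNA", rep("protein_coding", 3), "miRNA"),
    direction = c("up", "down", "up", "down", "down"),
    log2_fc = c(1.2, -0.8, 0.9, -1.1, NA))
  coexpr <- data.frame(gene_a = c("L1", "L1", "P1"),
                       gene_b = c("P1", "P2", "P2"),
                       sign = c("positive", "negative", "positive"))
  ppi <- data.frame(protein_a = c("P1", "P2"), protein_b = c("P2", "P3"))
  mt <- data.frame(mirna = "miR-1", target = "L1")
  net <- integrate_network(coexpr, ppi, mt, nodes)
  expect_s3_class(net, "integrated_network")
  expect_equal(nrow(net$edges), 6)   # 3 coexpr + 2 ppi + 1 mirna
  # shared pair P1-P2 carries two typed edges
  p12 <- net$edges[net$edges$from == "P1" & net$edges$to == "P2", ]
  expect_setequal(p12$type, c("coexpr_pos", "ppi"))

  s <- summarize_network(net)
  expect_equal(s$n_ppi, 2)
  expect_equal(s$n_ppi_overlap_total, 1)
  expect_equal(s$n_ppi_overlap_pos, 1)
  expect_equal(s$n_mirna_target, 1)
  expect_equal(s$n_mirna_lncrna_links, 1)

  empty <- integrate_network(coexpr[0, ], ppi[0, ], mt[0, ], nodes)
  expect_equal(nrow(empty$edges), 0)
  s0 <- summarize_network(empty)
  expect_equal(s0$n_ppi_overlap_total, 0)

  expect_error(integrate_network(coexpr, ppi,
                                 data.frame(mirna = "miR-9", target = "L1"),
                                 nodes), "unknown node")
  loop <- data.frame(gene_a = "P1", gene_b = "P1", sign = "positive")
  expect_error(integrate_network(loop, ppi[0, ], mt[0, ], nodes),
               "self-loop")
  # coexpression must not touch miRNA nodes
  badco <- data.frame(gene_a = "miR-1", gene_b = "P1", sign = "positive")
  expect_error(integrate_network(badco, ppi[0, ], mt[0, ], nodes), "miRNA")
  # permissive mode admits unknown endpoints with direction "unknown"
  perm <- integrate_network(coexpr, data.frame(protein_a = "P1",
                                               protein_b = "P9"),
                            mt, nodes, permissive = TRUE)
  expect_true("P9" %in% perm$nodes$gene)
  expect_equal(perm$nodes$direction[perm$nodes$gene == "P9"], "unknown")
})

test_that("summary counts equal brute-force recounts on random networks", {
  for (s in 1:100) {
    toy <- random_toy_network(n_edges = sample(5:40, 1), seed = s)
    gdir <- setNames(toy$nodes$direction, toy$nodes$gene)
    net <- integrate_network(toy$coexpr, toy$ppi, toy$mirna, toy$nodes)
    got <- summarize_network(net)

    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    co_pos <- toy$coexpr[toy$coexpr$sign == "positive", ]
    co_neg <- toy$coexpr[toy$coexpr$sign == "negative", ]
    ppik <- unique(key(toy$ppi$protein_a, toy$ppi$protein_b))
    posk <- key(co_pos$gene_a, co_pos$gene_b)
    negk <- key(co_neg$gene_a, co_neg$gene_b)
    expect_equal(got$n_coexpr_pos, nrow(co_pos))
    expect_equal(got$n_coexpr_neg, nrow(co_neg))
    expect_equal(got$n_ppi, length(ppik))
    expect_equal(got$n_ppi_overlap_pos, sum(ppik %in% posk))
    expect_equal(got$n_ppi_overlap_neg,
                 sum(ppik %in% negk & !(ppik %in% posk)))
    expect_equal(got$n_ppi_overlap_total,
                 got$n_ppi_overlap_pos + got$n_ppi_overlap_neg)
    expect_lte(got$n_ppi_overlap_total, got$n_ppi)
    bt <- setNames(toy$nodes$biotype, toy$nodes$gene)
    expect_equal(got$n_mirna_lncrna_links,
                 sum(bt[toy$mirna$target] == "lncRNA"))
  }
})

test_that("node profiles count typed neighbors", {
  toy <- random_toy_network(12, seed = 3)
  net <- integrate_network(toy$coexpr, toy$ppi, toy$mirna, toy$nodes)
  bt <- setNames(toy$nodes$biotype, toy$nodes$gene)
  node <- toy$coexpr$gene_a[1]
  prof <- node_profile(net, node)
  nb <- unique(c(toy$coexpr$gene_b[toy$coexpr$gene_a == node],
                 toy$coexpr$gene_a[toy$coexpr$gene_b == node]))
  expect_equal(prof$coexpr_pcg, sum(bt[nb] == "protein_coding"))
  expect_equal(prof$coexpr_lncrna, sum(bt[nb] == "lncRNA"))
  expect_equal(prof$mirna,
               length(unique(toy$mirna$mirna[toy$mirna$target == node])))
  # isolated node
  iso <- setdiff(toy$nodes$gene,
                 c(toy$coexpr$gene_a, toy$coexpr$gene_b,
                   toy$ppi$protein_a, toy$ppi$protein_b,
                   toy$mirna$mirna, toy$mirna$target))
  if (length(iso) > 0) {
    net2 <- net
    net2$nodes <- rbind(net2$nodes,
                        toy$nodes[toy$nodes$gene == iso[1], ])
    expect_equal(node_profile(net2, iso[1]),
                 list(coexpr_pcg = 0L, coexpr_lncrna = 0L, mirna = 0L))
  }
  expect_error(node_profile(net, "NOPE"), "not in network")
})

test_that("export/import round-trips preserve the network", {
  toy <- random_toy_network(15, seed = 8)
  net <- integrate_network(toy$coexpr, toy$ppi, toy$mirna, toy$nodes)

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "GraphML")
  back <- import_network(gml, "GraphML")
  expect_equal(summarize_network(back), summarize_network(net))
  expect_setequal(back$nodes$gene, net$nodes$gene)

  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "TSV")
  back2 <- import_network(tsv, "TSV")
  expect_equal(back2$edges, net$edges)
  expect_equal(summarize_network(back2), summarize_network(net))

  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "SIF")
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(net$edges))
  expect_match(lines[1], "^\\S+\t(coexpr_pos|coexpr_neg|ppi|mirna_target)\t\\S+$")
  back3 <- import_network(sif, "SIF")
  expect_equal(nrow(back3$edges), nrow(net$edges))

  expect_error(export_network(net, tempfile(), "XLSX"), "unknown format")
})
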