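# Integrate the coexpression links with synthetic PPI evidence and the
# opposite-direction-filtered miRNA-target regulations into one typed
# network; report the link-type and overlap summary.
source("analysis/00_common.R")

de_tab <- read.delim(file.path(OUT_DIR, "diffexpr.tsv"))
edges <- read_edges(file.path(OUT_DIR, "coexpr_edges.tsv"))
pairs <- read.delim(file.path(DATA_DIR, "mirna_pairs.tsv"))
mdir <- read.delim(file.path(DATA_DIR, "mirna_directions.tsv"))

gene_dir <- de_tab[de_tab$direction != "ns", c("gene", "direction")]
kept <- filter_mirna_targets(pairs, mdir, gene_dir)
cat(sprintf("miRNA-target pairs: %d of %d survive the opposite-direction filter\n",
            nrow(kept), nrow(pairs)))

# synthetic PPI table: half overlapping coexpression links between
# protein-coding genes, half random protein-coding pairs
set.seed(SEED)
pcg <- de_tab$gene[de_tab$biotype == "protein_coding"]
pe <- edges[edges$gene_a %in% pcg & edges$gene_b %in% pcg, ]
ov <- pe[sample.int(nrow(pe), min(40, nrow(pe))), c("gene_a", "gene_b")]
rnd <- t(replicate(40, sample(pcg, 2)))
ppi <- unique(data.frame(protein_a = c(ov$gene_a, rnd[, 1]),
                         protein_b = c(ov$gene_b, rnd[, 2])))

nodes <- rbind(
  data.frame(gene = de_tab$gene, biotype = de_tab$biotype,
             direction = de_tab$direction, log2_fc = de_tab$log2_fc),
  data.frame(gene = mdir$mirna, biotype = "miRNA",
             direction = mdir$direction, log2_fc = NA_real_))
net <- integrate_network(edges, ppi, kept, nodes)
export_network(net, file.path(OUT_DIR, "network.graphml"), "GraphML")
export_network(net, file.path(OUT_DIR, "network.sif"), "SIF")

s <- summarize_network(net)
jsonlite::write_json(s, file.path(OUT_DIR, "network_summary.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("network: %d miRNA-target, %d positive and %d negative coexpression, %d PPI links\n",
            s$n_mirna_target, s$n_coexpr_pos, s$n_coexpr_neg, s$n_ppi))
cat(sprintf("PPI/coexpression overlap: %d pairs (%d positive, %d negative); %d miRNA-lncRNA links\n",
            s$n_ppi_overlap_total, s$n_ppi_overlap_pos, s$n_ppi_overlap_neg,
            s$n_mirna_lncrna_links))

# degree profile of the best-connected lncRNA, HCP5-style
lnc <- nodes$gene[nodes$biotype == "lncRNA"]
lnc <- lnc[lnc %in% c(net$edges$from, net$edges$to)]
if (length(lnc) > 0) {
  deg <- sapply(lnc, function(g) sum(net$edges$from == g | net$edges$to == g))
  hub <- names(which.max(deg))
  pr <- node_profile(net, hub)
  cat(sprintf("hub %s: coexpressed with %d protein-coding genes and %d lncRNAs, regulated by %d miRNAs\n",
              hub, pr$coexpr_pcg, pr$coexpr_lncrna, pr$mirna))
}
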