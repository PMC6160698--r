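# Guilt-by-association GO annotation: lncRNA hubs (more than 3 coexpressed
# protein-coding neighbors) are annotated with the GO BP terms enriched in
# their neighborhoods (hypergeometric test, BH-adjusted p < 0.05 per lncRNA).
source("analysis/00_common.R")

dat <- read_expression(file.path(DATA_DIR, "matrix.tsv"),
                       file.path(DATA_DIR, "samples.tsv"),
                       file.path(DATA_DIR, "genes.tsv"))
bt <- setNames(dat$genes$biotype, dat$genes$gene)
mat <- quantile_normalize(dat$matrix)

# a 6-sample array is too small for a stable annotation network, so (as is
# standard) annotate over the multi-dataset consensus network built in the
# previous driver, with the array's gene space as the enrichment universe
edges <- read_edges(file.path(OUT_DIR, "consensus_edges.tsv"))
sets <- read_gmt(file.path(DATA_DIR, "go_bp.gmt"))
res <- annotate_lncrnas(edges, sets, biotype = bt, min_neighbors = 3,
                        alpha = 0.05, universe = dat$genes$gene)
write.table(res, file.path(OUT_DIR, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_hub <- length(unique(res$lncrna))
n_assigned <- length(unique(res$lncrna[res$assigned]))
cat(sprintf("%d lncRNA hubs tested, %d annotated at adjusted p < 0.05\n",
            n_hub, n_assigned))

mods <- read.delim(file.path(DATA_DIR, "truth_modules.tsv"))
hubs <- mods$gene[bt[mods$gene] == "lncRNA"]
for (h in intersect(hubs, res$lncrna)) {
  tt <- top_terms(res, h, k = 3)
  cat(sprintf("top terms for module hub %s: %s\n", h,
              paste(sprintf("%s (p=%.2g)", tt$term, tt$p), collapse = ", ")))
}
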