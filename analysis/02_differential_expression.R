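# Quantile-normalize, call differential lncRNAs / protein-coding genes at
# fold change > 1.5 and p < 0.05, intersect with the external list, and
# cluster the significant rows.
source("analysis/00_common.R")

dat <- read_expression(file.path(DATA_DIR, "matrix.tsv"),
                       file.path(DATA_DIR, "samples.tsv"),
                       file.path(DATA_DIR, "genes.tsv"))
bt <- setNames(dat$genes$biotype, dat$genes$gene)

mat <- quantile_normalize(dat$matrix)
tab <- differential_test(mat, dat$samples)
sel <- select_differential(tab, fc_threshold = 1.5, alpha = 0.05)

out <- sel$table
out$biotype <- unname(bt[out$gene])
write.table(out, file.path(OUT_DIR, "diffexpr.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("differential at FC>1.5, p<0.05: %d up / %d down lncRNAs, %d up / %d down protein-coding\n",
            sum(bt[sel$up] == "lncRNA"), sum(bt[sel$down] == "lncRNA"),
            sum(bt[sel$up] == "protein_coding"),
            sum(bt[sel$down] == "protein_coding")))

truth <- read.delim(file.path(DATA_DIR, "truth_de.tsv"))
called <- c(sel$up, sel$down)
cat(sprintf("planted-truth recovery: %.1f%% recall, %.3f empirical FDR\n",
            100 * mean(truth$gene %in% called),
            if (length(called)) mean(!(called %in% truth$gene)) else 0))

external <- read.delim(file.path(DATA_DIR, "external_de.tsv"))
flt <- suppressMessages(intersect_external(sel$up, sel$down, external, bt))
cat(sprintf("after external same-direction intersection: %d up, %d down retained\n",
            length(flt$up), length(flt$down)))
write.table(data.frame(gene = c(flt$up, flt$down),
                       direction = rep(c("up", "down"),
                                       c(length(flt$up), length(flt$down)))),
            file.path(OUT_DIR, "de_intersected.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cl <- hierarchical_cluster(mat, rows = called)
cat("sample dendrogram order:", paste(cl$col_order, collapse = " "), "\n")
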