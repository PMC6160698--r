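# Generate the synthetic study: expression matrix with planted differential
# genes and coexpression modules, GO annotation with planted signature terms,
# miRNA direction/target tables, and a synthetic external differential list.
# All downstream drivers read only the files written here.
source("analysis/00_common.R")

cfg <- study_config()
sim <- simulate_expression(cfg)

write_expression(sim$matrix, sim$samples,
                 file.path(DATA_DIR, "matrix.tsv"),
                 file.path(DATA_DIR, "samples.tsv"),
                 genes = sim$genes,
                 annotation_path = file.path(DATA_DIR, "genes.tsv"))
write_gmt(simulate_go(sim$truth, cfg, sim$genes$gene),
          file.path(DATA_DIR, "go_bp.gmt"))

mir <- simulate_mirna(sim$truth, cfg)
write.table(mir$pairs[, c("mirna", "target")],
            file.path(DATA_DIR, "mirna_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mir$mirna_directions, file.path(DATA_DIR, "mirna_directions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# synthetic stand-in for an external tumor-vs-normal differential list:
# the planted truth plus genes absent from the array
external <- rbind(sim$truth$de_genes,
                  data.frame(gene = sprintf("EXT%03d", 1:50),
                             direction = rep(c("up", "down"), 25)))
write.table(external, file.path(DATA_DIR, "external_de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# ground truth, kept for the recovery summaries in later drivers
write.table(sim$truth$de_genes, file.path(DATA_DIR, "truth_de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = names(sim$truth$module_membership),
                       module = unname(sim$truth$module_membership)),
            file.path(DATA_DIR, "truth_modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("wrote study inputs to %s: %d probes x %d samples, %d planted DE genes, %d module genes\n",
            DATA_DIR, nrow(sim$matrix), ncol(sim$matrix),
            nrow(sim$truth$de_genes), length(sim$truth$module_membership)))
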