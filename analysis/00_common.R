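# shared settings for the analysis drivers: run each script from the
# repository root with Rscript, in numeric order
library(lncmetnet)

SEED <- 1L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

# one emulated study everywhere: 965 lncRNA + 458 protein-coding probes on
# 3 tumor/normal pairs, 10% planted differential genes at |log2 FC| = 2,
# three 10-gene coexpression modules, 10 planted miRNA-target pairs
study_config <- function() sim_config(seed = SEED)
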