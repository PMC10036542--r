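#!/usr/bin/env Rscript
# Differential expression over the time course: per-timepoint log2 fold
# changes against the untreated control, DEG calls at |log2FC| >= 1, and
# average-linkage clustering of the DEG response profiles (dendrogram cut
# at height 3), mirroring the heatmap-style grouping of early up- and
# down-regulated genes.

source("analysis/00_common.R")

m <- run_pipeline("degs", analysis_config())
degs <- read.table(file.path(WORKDIR, "degs.tsv"), header = TRUE,
                   sep = "\t")
tab <- table(factor(degs$timepoint,
                    levels = c("5min", "1h", "3h", "12h")),
             degs$direction)
cat("DEG counts by timepoint (|log2FC| >= 1):\n")
print(tab)
cat(sprintf("%d unique DEGs; early response dominates and decays.\n",
            m$stages$degs$unique_deg_genes))
publish("degs.tsv", "log2fc.tsv", "deg_clusters.tsv")
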