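#!/usr/bin/env Rscript
# Homology-based GRN reconstruction: screen TF candidates against the
# reference prokaryotic TF database by exact Smith-Waterman (e-value <
# 0.05), transfer each hit's donor PWM, scan the genome on both strands
# at 80% of the maximal log-odds score, assign each site to its closest
# gene (<= 1 kb), and assemble the bipartite TF -> target network.

source("analysis/00_common.R")

m <- run_pipeline("grn", analysis_config())
g <- m$stages$grn
cat(sprintf("Screened %d TFs; %d binding sites -> %d unique edges.\n",
            g$tfs_screened, g$sites, g$edges))

truth <- read_truth(file.path(WORKDIR, "truth.json"))
edges <- read.table(file.path(WORKDIR, "edges.tsv"), header = TRUE,
                    sep = "\t")
pred <- paste(edges$tf, edges$target)
want <- paste(truth$true_edges$tf, truth$true_edges$target)
cat(sprintf("Edge recovery vs planted truth: precision %.3f, recall %.3f\n",
            mean(pred %in% want), mean(want %in% pred)))
publish("tf_screen.tsv", "edges.tsv", "sites.bed")
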