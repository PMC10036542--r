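#!/usr/bin/env Rscript
# Generate the synthetic radiation-response study: a ~360 kb toy
# bacterium with 300 genes, 40 operons, 10 planted TFs (one master
# regulator driving a two-layer cascade), promoter binding sites, and a
# 5-timepoint x 3-replicate count/coverage time course with full ground
# truth.

source("analysis/00_common.R")

m <- run_pipeline("simulate", analysis_config())
s <- m$stages$simulate
cat(sprintf(
  "Simulated %d genes on %d bp; planted %d TFs, %d regulatory edges, %d operons.\n",
  s$genes, s$genome_bp, s$planted_tfs, s$planted_edges,
  s$planted_operons))
publish("truth.json", "manifest.json")
cat("Inputs written under", WORKDIR, "\n")
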