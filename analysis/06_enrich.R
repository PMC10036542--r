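#!/usr/bin/env Rscript
# Pathway enrichment (hypergeometric upper tail, significant at raw
# p < 0.05) of the direction-split DEG sets and of the operon profile
# clusters, against the bundled pathway database whose planted "regulon
# pathway" collects the master regulator's full regulon.

source("analysis/00_common.R")

m <- run_pipeline("enrich", analysis_config())
enr <- read.table(file.path(WORKDIR, "enrichment.tsv"), header = TRUE,
                  sep = "\t")
cat(sprintf("%d tests, %d significant at p < 0.05.\n",
            m$stages$enrich$tests, m$stages$enrich$significant))
sig <- enr[enr$significant, c("query", "pathway", "k", "K", "p")]
sig <- sig[order(sig$p), ]
cat("Significant pathways:\n")
print(sig, row.names = FALSE, digits = 3)
publish("enrichment.tsv")
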