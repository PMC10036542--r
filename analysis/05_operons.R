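#!/usr/bin/env Rscript
# Operon detection and dynamics: six rule-based detectors vote on every
# adjacent same-strand gene pair from RNA-seq coverage (a pair needs >= 3
# votes), positive pairs chain into operons, each operon's time profile
# is the mean member z-score per timepoint, and profiles are grouped by
# k-means into six perturbation patterns.

source("analysis/00_common.R")

m <- run_pipeline("operons", analysis_config())
o <- m$stages$operons
cat(sprintf(
  "%d/%d candidate pairs voted operonic -> %d operons; %.0f%% of genes in operons.\n",
  o$operon_pairs, o$candidate_pairs, o$operons,
  100 * o$frac_genes_in_operons))

truth <- read_truth(file.path(WORKDIR, "truth.json"))
n_genes <- round(o$genes_in_operons / o$frac_genes_in_operons)
cat(sprintf("Planted: %d operons covering %.0f%% of genes.\n",
            length(truth$true_operons),
            100 * length(unlist(truth$true_operons)) / n_genes))
cl <- read.table(file.path(WORKDIR, "operon_clusters.tsv"),
                 header = TRUE, sep = "\t")
cat("Operons per profile cluster:\n")
print(table(cl$cluster))
publish("operon_pairs.tsv", "operons.tsv", "operon_profiles.tsv",
        "operon_clusters.tsv")
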