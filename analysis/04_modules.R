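#!/usr/bin/env Rscript
# Time-varying network modules: propagate each TF's unit seed over the
# GRN (restart 0.5), score its influence as the Pearson correlation of
# the propagated vector with |log2FC| over the timepoint's DEGs, then
# greedily select major TFs in influence order until every coverable DEG
# is covered.

source("analysis/00_common.R")

m <- run_pipeline("modules", analysis_config())
truth <- read_truth(file.path(WORKDIR, "truth.json"))
mods <- jsonlite::read_json(file.path(WORKDIR, "modules.json"),
                            simplifyVector = TRUE)
for (tp in names(mods)) {
  tfs <- mods[[tp]]$major_tfs$tf
  cat(sprintf("%-5s: %d major TF(s) [%s], %d covered targets\n", tp,
              length(tfs), paste(tfs, collapse = ", "),
              length(mods[[tp]]$targets)))
}
first <- names(mods)[1]
cat(sprintf("Master regulator %s %s selected at %s.\n",
            truth$master_tf,
            if (truth$master_tf %in% mods[[first]]$major_tfs$tf)
              "is" else "is NOT", first))
publish("modules.json", "tf_membership.tsv")
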