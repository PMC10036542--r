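# Shared setup for the analysis scripts. Each numbered script is a thin
# driver over the bacgrn package: it runs one pipeline stage against the
# working directory `scratch/pipeline` (large per-sample coverage tracks
# live there) and copies the small result tables into `results/`.

suppressMessages(library(bacgrn))

ANALYSIS_SEED <- as.integer(Sys.getenv("BACGRN_SEED", "0"))
WORKDIR <- "scratch/pipeline"
RESULTS <- "results"

analysis_config <- function() {
  pipeline_config(outdir = WORKDIR, seed = ANALYSIS_SEED)
}

publish <- function(...) {
  dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
  for (f in c(...)) {
    file.copy(file.path(WORKDIR, f), file.path(RESULTS, f),
              overwrite = TRUE)
  }
}
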