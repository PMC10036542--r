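#' Pipeline configuration
#'
#' Collects every stage's inputs and parameters. With the default
#' (synthetic) setup the `simulate` stage writes all input files into
#' `outdir` and later stages read them from there; for real data, point
#' the path fields at existing files and skip `simulate`.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Global integer seed; per-stage seeds are derived from it
#'   deterministically.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param deg_threshold |log2FC| threshold for DEG calls (default 1).
#' @param pseudocount Pseudocount for fold changes (default 1).
#' @param linkage_cut Dendrogram cut height for expression clustering
#'   (default 3).
#' @param e_threshold Homology-screen e-value threshold (default 0.05).
#' @param scan_threshold_frac Fraction-of-max motif scan threshold
#'   (default 0.8).
#' @param max_distance Site-to-gene assignment cap in bp (default 1000).
#' @param propagation A [propagation_config()].
#' @param operon An [operon_config()].
#' @param k_operon_clusters Operon profile clusters (default 6).
#' @param enrich_alpha Enrichment significance level (default 0.05).
#' @param use_candidates Feed the TF-candidate list (the TF-prediction
#'   step's output, `tf_candidates.txt`) to the homology screen when the
#'   file exists (default TRUE); with FALSE the whole proteome is
#'   screened.
#' @param paths Optional named list of input file overrides (`genome`,
#'   `gff`, `proteome`, `tfdb_proteins`, `tfdb_pwms`, `counts`,
#'   `coverage_dir`, `gmt`, `candidates`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 0L,
                            generator = generator_config(),
                            deg_threshold = 1, pseudocount = 1,
                            linkage_cut = 3, e_threshold = 0.05,
                            scan_threshold_frac = 0.8,
                            max_distance = 1000,
                            propagation = propagation_config(),
                            operon = operon_config(),
                            k_operon_clusters = 6, enrich_alpha = 0.05,
                            use_candidates = TRUE, paths = list()) {
  generator$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 generator = generator, deg_threshold = deg_threshold,
                 pseudocount = pseudocount, linkage_cut = linkage_cut,
                 e_threshold = e_threshold,
                 scan_threshold_frac = scan_threshold_frac,
                 max_distance = max_distance, propagation = propagation,
                 operon = operon,
                 k_operon_clusters = k_operon_clusters,
                 enrich_alpha = enrich_alpha,
                 use_candidates = use_candidates, paths = paths),
            class = "pipeline_config")
}

pc_path <- function(config, key, default) {
  p <- config$paths[[key]]
  if (is.null(p)) file.path(config$outdir, default) else p
}

require_artifact <- function(path, stage, produced_by) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' is missing its input '", basename(path),
         "'; run stage '", produced_by, "' first")
  }
  path
}

read_expression_inputs <- function(config, stage) {
  counts <- read_counts(require_artifact(
    pc_path(config, "counts", "counts.tsv"), stage, "simulate"))
  expression_matrix(counts, config$generator$timepoints)
}

#' Run the analysis pipeline
#'
#' Executes one stage (or `all`) and writes its artifacts into
#' `config$outdir`, plus a `manifest.json` recording the seed, parameter
#' hash and per-stage record counts. Stages read their inputs from the
#' files earlier stages wrote, so each stage is independently re-runnable;
#' a missing input names the stage that produces it.
#'
#' Stages: `simulate` (synthetic data + ground truth), `degs` (fold
#' changes, DEG calls, expression clusters), `grn` (TF screen, motif
#' scan, target assignment, network), `modules` (per-timepoint
#' propagation + influence maximization), `operons` (pair votes,
#' chaining, operon values, k-means), `enrich` (pathway enrichment of DEG
#' sets, module targets and operon clusters).
#'
#' @param stage One of `"simulate"`, `"degs"`, `"grn"`, `"modules"`,
#'   `"operons"`, `"enrich"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "degs", "grn",
                                   "modules", "operons", "enrich"),
                         config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "degs", "grn", "modules", "operons", "enrich")
  } else {
    stage
  }
  manifest <- read_manifest(config)
  for (s in stages) {
    counts <- switch(s,
      simulate = stage_simulate(config),
      degs = stage_degs(config),
      grn = stage_grn(config),
      modules = stage_modules(config),
      operons = stage_operons(config),
      enrich = stage_enrich(config))
    manifest$stages[[s]] <- counts
  }
  manifest$seed <- config$seed
  manifest$config_hash <- config_hash(config)
  manifest$package_version <-
    as.character(utils::packageVersion("bacgrn"))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(config) {
  p <- file.path(config$outdir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else list(stages = list())
}

config_hash <- function(config) {
  x <- config[setdiff(names(config), "outdir")]
  raw <- serialize(x, NULL, version = 2L)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

stage_simulate <- function(config) {
  sim <- simulate_experiment(config$generator)
  out <- config$outdir
  write_fasta(sim$genome, file.path(out, "genome.fasta"))
  write_gff3(sim$annotation, file.path(out, "genes.gff3"))
  write_fasta(sim$proteome, file.path(out, "proteome.fasta"))
  write_fasta(sim$tfdb$proteins, file.path(out, "tfdb_proteins.fasta"))
  write_pwms(sim$tfdb$pwms, file.path(out, "tfdb_pwms.txt"))
  write_counts(sim$counts, file.path(out, "counts.tsv"))
  covdir <- file.path(out, "coverage")
  dir.create(covdir, showWarnings = FALSE)
  write_coverage(sim$coverage, file.path(covdir, "sample"))
  write_gmt(sim$pathways, file.path(out, "pathways.gmt"))
  write_truth(sim$truth, file.path(out, "truth.json"))
  # stand-in for the output of a TF-prediction step run ahead of the
  # homology screen
  writeLines(sim$truth$true_tfs, file.path(out, "tf_candidates.txt"))
  list(genes = nrow(sim$annotation),
       genome_bp = nchar(sim$genome[[1L]]),
       planted_tfs = length(sim$truth$true_tfs),
       planted_edges = nrow(sim$truth$true_edges),
       planted_operons = length(sim$truth$true_operons))
}

stage_degs <- function(config) {
  mat <- read_expression_inputs(config, "degs")
  out <- config$outdir
  tps <- setdiff(mat$timepoints, mat$control)
  lfc <- sapply(tps, function(tp) {
    compute_log2fc(mat, tp, config$pseudocount)
  })
  utils::write.table(data.frame(gene = rownames(lfc), lfc,
                                check.names = FALSE),
                     file.path(out, "log2fc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  degs <- call_degs_all(mat, config$deg_threshold, config$pseudocount)
  utils::write.table(degs, file.path(out, "degs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  deg_genes <- unique(degs$gene)
  if (length(deg_genes) >= 2L) {
    cl <- cluster_expression(lfc[deg_genes, , drop = FALSE],
                             config$linkage_cut)
    utils::write.table(data.frame(gene = names(cl), cluster = cl),
                       file.path(out, "deg_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(degs = nrow(degs), unique_deg_genes = length(deg_genes))
}

stage_grn <- function(config) {
  out <- config$outdir
  proteome <- read_fasta(require_artifact(
    pc_path(config, "proteome", "proteome.fasta"), "grn", "simulate"))
  tfdb <- list(
    proteins = read_fasta(require_artifact(
      pc_path(config, "tfdb_proteins", "tfdb_proteins.fasta"),
      "grn", "simulate")),
    pwms = read_pwms(require_artifact(
      pc_path(config, "tfdb_pwms", "tfdb_pwms.txt"), "grn",
      "simulate")))
  genome <- read_fasta(require_artifact(
    pc_path(config, "genome", "genome.fasta"), "grn", "simulate"))
  annotation <- read_gff3(require_artifact(
    pc_path(config, "gff", "genes.gff3"), "grn", "simulate"))
  candidates <- NULL
  if (config$use_candidates) {
    cand_path <- pc_path(config, "candidates", "tf_candidates.txt")
    if (file.exists(cand_path)) candidates <- readLines(cand_path)
  }
  screen <- screen_tfs(proteome, tfdb, config$e_threshold,
                       candidates = candidates)
  utils::write.table(screen, file.path(out, "tf_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pwms <- transfer_pwm(screen, tfdb)
  loms <- lapply(pwms, pwm_log_odds)
  sites <- scan_genome(loms, genome, config$scan_threshold_frac)
  raw <- assign_targets(sites, annotation, config$max_distance)
  grn <- build_grn(raw, screen$tf)
  retained <- unique(raw[, c("tf", "contig", "site_start", "site_end",
                             "site_strand", "score")])
  names(retained) <- c("tf", "contig", "start", "end", "strand",
                       "score")
  write_bed(retained, file.path(out, "sites.bed"))
  utils::write.table(grn$edges, file.path(out, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(tfs_screened = nrow(screen), sites = nrow(sites),
       edges = nrow(grn$edges))
}

read_grn_inputs <- function(config, stage) {
  edges <- utils::read.table(
    require_artifact(file.path(config$outdir, "edges.tsv"), stage,
                     "grn"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  screen <- utils::read.table(
    require_artifact(file.path(config$outdir, "tf_screen.tsv"), stage,
                     "grn"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  build_grn(edges, screen$tf)
}

stage_modules <- function(config) {
  out <- config$outdir
  grn <- read_grn_inputs(config, "modules")
  degs <- utils::read.table(
    require_artifact(file.path(out, "degs.tsv"), "modules", "degs"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  mat <- read_expression_inputs(config, "modules")
  tps <- setdiff(mat$timepoints, mat$control)
  mods <- extract_modules(grn, degs, tps, config$propagation)
  json <- lapply(mods, function(m) {
    list(timepoint = m$timepoint, major_tfs = m$major_tfs,
         targets = m$targets, uncovered = m$uncovered,
         edges = m$edges)
  })
  jsonlite::write_json(json, file.path(out, "modules.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  tfs <- sort(unique(unlist(lapply(mods, function(m) m$major_tfs$tf))))
  member <- sapply(mods, function(m) {
    as.integer(tfs %in% m$major_tfs$tf)
  })
  if (length(tfs) > 0L) {
    utils::write.table(data.frame(tf = tfs, member,
                                  check.names = FALSE),
                       file.path(out, "tf_membership.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(modules = length(mods),
       major_tfs = sum(vapply(mods, function(m) nrow(m$major_tfs),
                              numeric(1))))
}

stage_operons <- function(config) {
  out <- config$outdir
  annotation <- read_gff3(require_artifact(
    pc_path(config, "gff", "genes.gff3"), "operons", "simulate"))
  mat <- read_expression_inputs(config, "operons")
  covdir <- pc_path(config, "coverage_dir", "coverage")
  files <- list.files(covdir, pattern = "\\.bedGraph$",
                      full.names = TRUE)
  if (length(files) == 0L) {
    stop("stage 'operons' is missing its input coverage bedGraphs; ",
         "run stage 'simulate' first")
  }
  names(files) <- sub("^sample\\.", "", sub("\\.bedGraph$", "",
                                            basename(files)))
  coverage <- read_coverage(files)
  pairs <- detect_operon_pairs(coverage, annotation, mat,
                               config$operon)
  utils::write.table(pairs, file.path(out, "operon_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ops <- chain_operons(pairs, annotation)
  op_df <- data.frame(
    operon = names(ops),
    members = vapply(ops, function(o) paste(o$members, collapse = ","),
                     character(1)),
    n = vapply(ops, function(o) length(o$members), numeric(1)),
    min_votes = vapply(ops, function(o) min(o$votes), numeric(1)))
  utils::write.table(op_df, file.path(out, "operons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  n_clustered <- 0L
  if (length(ops) >= config$k_operon_clusters) {
    z <- expression_zscores(mat)
    prof <- operon_values(ops, z)
    utils::write.table(data.frame(operon = rownames(prof), prof,
                                  check.names = FALSE),
                       file.path(out, "operon_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cl <- cluster_operons(prof, config$k_operon_clusters,
                          seed = stage_seed(config$seed, "operon_kmeans"))
    utils::write.table(data.frame(operon = names(cl$cluster),
                                  cluster = cl$cluster),
                       file.path(out, "operon_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_clustered <- length(cl$cluster)
  }
  genes_in <- length(unlist(lapply(ops, `[[`, "members")))
  list(candidate_pairs = nrow(pairs),
       operon_pairs = sum(pairs$call), operons = length(ops),
       genes_in_operons = genes_in,
       frac_genes_in_operons = genes_in / nrow(annotation),
       operons_clustered = n_clustered)
}

stage_enrich <- function(config) {
  out <- config$outdir
  db <- read_gmt(require_artifact(
    pc_path(config, "gmt", "pathways.gmt"), "enrich", "simulate"))
  degs <- utils::read.table(
    require_artifact(file.path(out, "degs.tsv"), "enrich", "degs"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  results <- list()
  for (tp in unique(degs$timepoint)) {
    for (dir in c("up", "down")) {
      q <- degs$gene[degs$timepoint == tp & degs$direction == dir]
      if (length(q) == 0L) next
      r <- suppressMessages(enrich(q, db, dir, config$enrich_alpha))
      if (nrow(r) > 0L) {
        r$query <- paste0("degs_", tp)
        results[[length(results) + 1L]] <- r
      }
    }
  }
  ocl <- file.path(out, "operon_clusters.tsv")
  ops <- file.path(out, "operons.tsv")
  if (file.exists(ocl) && file.exists(ops)) {
    cl <- utils::read.table(ocl, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    om <- utils::read.table(ops, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    for (k in sort(unique(cl$cluster))) {
      genes <- unlist(strsplit(
        om$members[om$operon %in% cl$operon[cl$cluster == k]], ","))
      r <- suppressMessages(enrich(genes, db, "none",
                                   config$enrich_alpha))
      if (nrow(r) > 0L) {
        r$query <- paste0("operon_cluster_", k)
        results[[length(results) + 1L]] <- r
      }
    }
  }
  res <- if (length(results) > 0L) do.call(rbind, results) else
    data.frame()
  utils::write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(tests = nrow(res),
       significant = if (nrow(res) > 0L) sum(res$significant) else 0L)
}
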