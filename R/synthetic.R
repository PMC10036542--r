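#' Configuration for the synthetic bacterium generator
#'
#' Defines the study conditions the generator emulates: a single-contig
#' toy bacterium, a reference prokaryotic TF database, a strain proteome
#' containing mutated copies of some reference TFs, planted promoter
#' binding sites wiring a two-layer master-regulator cascade, same-strand
#' operon blocks with continuous coverage, and a UVC-style time course
#' (control + 5 min, 1 h, 3 h, 12 h; 3 replicates) whose
#' differential-expression signal is strongest immediately after treatment
#' and decays.
#'
#' @param n_genes Number of genes (default 300).
#' @param n_ref_tfs Reference TFs in the database (default 20).
#' @param n_strain_tfs Strain proteins that are mutated copies of distinct
#'   reference TFs (default 10). The first is the master regulator, the
#'   second the intermediate TF of the cascade.
#' @param motif_length_range Motif length bounds in bp (default 8--14).
#' @param n_operons Number of operon blocks (default 40).
#' @param operon_size_range Genes per operon (default 2--5; minimum >= 2).
#' @param operon_gap_max Maximal intra-operon intergenic gap in bp
#'   (default 50).
#' @param timepoints Ordered labels, control first.
#' @param replicates Replicates per timepoint (default 3).
#' @param nb_dispersion Negative-binomial dispersion of counts
#'   (`variance = mu + dispersion * mu^2`; default 0.1).
#' @param master_effect_log2 log2 fold effect of the master regulator on
#'   its direct regulon at the first post-control timepoint (default 2).
#' @param effect_decay Per-timepoint multiplier of the effect, one value
#'   per post-control timepoint (default `c(1, 0.5, 0.2, 0.1)`).
#' @param indirect_attenuation Multiplier on the effect for genes regulated
#'   through the intermediate TF (default 0.7); signal attenuates along the
#'   cascade, which also makes direct and indirect targets distinguishable
#'   by effect size.
#' @param regulon_direct Genes directly regulated by the master (default
#'   15).
#' @param regulon_indirect Genes regulated via the intermediate TF
#'   (default 15).
#' @param other_regulon_size Targets per non-cascade TF (default 5).
#' @param gene_length_range Gene length bounds in bp (default 300--1500).
#' @param intergenic_range Non-operon intergenic gap bounds in bp (default
#'   300--600; the lower bound is also the promoter window).
#' @param promoter_window Strand-aware promoter length upstream of a gene
#'   start in which sites are planted (default 300).
#' @param site_offset_range Distance of a planted site's 3' edge from its
#'   target's start, in bp (default 5--100).
#' @param tf_mutation_rate Per-residue substitution rate applied to strain
#'   TF copies (default 0.05; must be <= 0.1).
#' @param depth_factor Per-base coverage depth per unit of expression mean
#'   (default 1/20).
#' @param background_coverage Poisson rate of intergenic background
#'   coverage (default 0.1).
#' @param baseline_mean_range Baseline expression-mean bounds (log-uniform;
#'   default 120--1200).
#' @param scan_threshold_frac Fraction-of-max log-odds threshold that the
#'   genome is scrubbed against so planted sites are the only sites
#'   (default 0.8, the scanner's default).
#' @param site_mode `"consensus"` (default) plants the argmax base at each
#'   motif position; `"sample"` draws each base from the PWM column.
#' @param seed Integer seed; every artifact is deterministic given it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 300, n_ref_tfs = 20,
                             n_strain_tfs = 10,
                             motif_length_range = c(8L, 14L),
                             n_operons = 40, operon_size_range = c(2L, 5L),
                             operon_gap_max = 50,
                             timepoints = c("control", "5min", "1h", "3h",
                                            "12h"),
                             replicates = 3, nb_dispersion = 0.1,
                             master_effect_log2 = 2,
                             effect_decay = c(1, 0.5, 0.2, 0.1),
                             indirect_attenuation = 0.7,
                             regulon_direct = 15, regulon_indirect = 15,
                             other_regulon_size = 5,
                             gene_length_range = c(300L, 1500L),
                             intergenic_range = c(300L, 600L),
                             promoter_window = 300,
                             site_offset_range = c(5L, 100L),
                             tf_mutation_rate = 0.05,
                             depth_factor = 1 / 20,
                             background_coverage = 0.1,
                             baseline_mean_range = c(120, 1200),
                             scan_threshold_frac = 0.8,
                             site_mode = c("consensus", "sample"),
                             seed = 0L) {
  site_mode <- match.arg(site_mode)
  cfg <- list(n_genes = as.integer(n_genes),
              n_ref_tfs = as.integer(n_ref_tfs),
              n_strain_tfs = as.integer(n_strain_tfs),
              motif_length_range = as.integer(motif_length_range),
              n_operons = as.integer(n_operons),
              operon_size_range = as.integer(operon_size_range),
              operon_gap_max = as.integer(operon_gap_max),
              timepoints = timepoints,
              replicates = as.integer(replicates),
              nb_dispersion = nb_dispersion,
              master_effect_log2 = master_effect_log2,
              effect_decay = effect_decay,
              indirect_attenuation = indirect_attenuation,
              regulon_direct = as.integer(regulon_direct),
              regulon_indirect = as.integer(regulon_indirect),
              other_regulon_size = as.integer(other_regulon_size),
              gene_length_range = as.integer(gene_length_range),
              intergenic_range = as.integer(intergenic_range),
              promoter_window = as.integer(promoter_window),
              site_offset_range = as.integer(site_offset_range),
              tf_mutation_rate = tf_mutation_rate,
              depth_factor = depth_factor,
              background_coverage = background_coverage,
              baseline_mean_range = baseline_mean_range,
              scan_threshold_frac = scan_threshold_frac,
              site_mode = site_mode,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_ref_tfs > 0, n_strain_tfs >= 0,
              n_operons >= 0, replicates > 0, nb_dispersion > 0,
              operon_size_range[1] >= 2,
              operon_size_range[2] >= operon_size_range[1],
              motif_length_range[1] >= 1,
              motif_length_range[2] >= motif_length_range[1],
              length(timepoints) >= 2,
              length(effect_decay) == length(timepoints) - 1L,
              tf_mutation_rate >= 0, tf_mutation_rate <= 0.1,
              promoter_window >= motif_length_range[2] +
                site_offset_range[2],
              intergenic_range[1] >= promoter_window)
  })
  if (cfg$n_operons * cfg$operon_size_range[2] > cfg$n_genes) {
    stop("sizing error: n_operons x maximal operon size exceeds n_genes")
  }
  structure(cfg, class = "generator_config")
}

# Derive a reproducible sub-seed for a named generator stage.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% 2147483647L
}

random_dna <- function(n) {
  paste(sample(DNA4, n, replace = TRUE), collapse = "")
}

#' Generate the toy genome and gene annotation
#'
#' Lays out `n_genes` non-overlapping genes on a single linear contig:
#' operon blocks (adjacent, same strand, intra-block gaps at most
#' `operon_gap_max`) interleaved with standalone genes, separated by
#' promoter-sized intergenic gaps. Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return List with `genome` (named character vector, one contig),
#'   `annotation` (`data.frame`: `gene`, `contig`, `start`, `end`,
#'   `strand`; 0-based half-open), and `truth` (partial ground truth:
#'   `true_operons`, a list of ordered gene-id vectors).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(stage_seed(config$seed, "genome"), {
    n <- config$n_genes
    sizes <- sample(seq(config$operon_size_range[1],
                        config$operon_size_range[2]),
                    config$n_operons, replace = TRUE)
    if (sum(sizes) > n) {
      stop("sizing error: sampled operon genes exceed n_genes")
    }
    n_standalone <- n - sum(sizes)
    # element list: operon blocks (multi-gene) and standalone genes
    elements <- c(as.list(sizes), as.list(rep(1L, n_standalone)))
    elements <- elements[sample(length(elements))]
    is_operon <- vapply(elements, function(k) k > 1L, logical(1))
    gene_id <- sprintf("g%04d", seq_len(n))
    ann <- vector("list", n)
    operons <- list()
    pos <- config$intergenic_range[2]  # leading margin
    gi <- 0L
    for (ei in seq_along(elements)) {
      k <- elements[[ei]]
      strand <- sample(c("+", "-"), 1L)
      members <- character(k)
      for (j in seq_len(k)) {
        len <- sample(seq(config$gene_length_range[1],
                          config$gene_length_range[2]), 1L)
        gi <- gi + 1L
        members[j] <- gene_id[gi]
        ann[[gi]] <- data.frame(gene = gene_id[gi], contig = "contig_1",
                                start = pos, end = pos + len,
                                strand = strand, stringsAsFactors = FALSE)
        pos <- pos + len
        if (j < k) {
          pos <- pos + sample(seq(2L, config$operon_gap_max), 1L)
        }
      }
      if (k > 1L) {
        if (strand == "-") members <- rev(members)  # transcription order
        operons[[length(operons) + 1L]] <- members
      }
      pos <- pos + sample(seq(config$intergenic_range[1],
                              config$intergenic_range[2]), 1L)
    }
    glen <- pos + config$intergenic_range[2]
    genome <- c(contig_1 = random_dna(glen))
    annotation <- do.call(rbind, ann)
    list(genome = genome, annotation = annotation,
         truth = list(true_operons = operons))
  })
}

#' Generate a reference prokaryotic TF database
#'
#' Each record couples a random protein sequence (100--300 aa) with an
#' informative PWM (per-column dominant base probability 0.85--0.97,
#' motif length within `motif_length_range`). Every PWM column sums to 1.
#'
#' @param config A [generator_config()].
#' @return List of class `tf_database`: `proteins` (named character
#'   vector), `pwms` (named list of 4 x L probability matrices).
#' @export
generate_tf_database <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(stage_seed(config$seed, "tfdb"), {
    ids <- sprintf("refTF%03d", seq_len(config$n_ref_tfs))
    proteins <- vapply(ids, function(id) {
      paste(sample(AA20, sample(100:300, 1L), replace = TRUE,
                   prob = AA_FREQ),
            collapse = "")
    }, character(1))
    pwms <- lapply(ids, function(id) {
      L <- sample(seq(config$motif_length_range[1],
                      config$motif_length_range[2]), 1L)
      m <- sapply(seq_len(L), function(j) {
        dom <- sample(4L, 1L)
        p <- stats::runif(1, 0.85, 0.97)
        rest <- stats::runif(3)
        rest <- rest / sum(rest) * (1 - p)
        col <- numeric(4)
        col[dom] <- p
        col[-dom] <- rest
        col
      })
      rownames(m) <- DNA4
      m
    })
    names(pwms) <- ids
    structure(list(proteins = proteins, pwms = pwms),
              class = "tf_database")
  })
}

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1L)
  paste(v, collapse = "")
}

#' Generate the strain proteome with planted TFs
#'
#' Assigns one protein per gene: `n_strain_tfs` genes receive point-mutated
#' copies (rate `tf_mutation_rate` <= 10%) of distinct reference TFs; all
#' other genes receive random sequences. TF genes are chosen among
#' standalone (non-operon) genes so regulatory and operonic structure stay
#' separable.
#'
#' @param config A [generator_config()].
#' @param genome_out Result of [generate_genome()].
#' @param tfdb Result of [generate_tf_database()].
#' @return List with `proteome` (named character vector, one entry per
#'   gene) and `truth` additions: `true_tfs`, `tf_donor` (named character
#'   vector strain TF -> reference TF), `master_tf`, `intermediate_tf`.
#' @export
generate_strain_proteome <- function(config, genome_out, tfdb) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_strain_tfs > config$n_ref_tfs) {
    stop("config error: n_strain_tfs exceeds n_ref_tfs")
  }
  withr::with_seed(stage_seed(config$seed, "proteome"), {
    ann <- genome_out$annotation
    operon_genes <- unlist(genome_out$truth$true_operons)
    standalone <- setdiff(ann$gene, operon_genes)
    if (length(standalone) < config$n_strain_tfs) {
      stop("sizing error: not enough standalone genes for strain TFs")
    }
    tf_genes <- sort(sample(standalone, config$n_strain_tfs))
    donors <- sample(names(tfdb$proteins), config$n_strain_tfs)
    proteome <- vapply(ann$gene, function(g) {
      paste(sample(AA20, sample(100:300, 1L), replace = TRUE,
                   prob = AA_FREQ),
            collapse = "")
    }, character(1))
    for (i in seq_along(tf_genes)) {
      proteome[[tf_genes[i]]] <-
        mutate_protein(tfdb$proteins[[donors[i]]], config$tf_mutation_rate)
    }
    truth <- list(true_tfs = tf_genes,
                  tf_donor = stats::setNames(donors, tf_genes),
                  master_tf = if (config$n_strain_tfs >= 1) tf_genes[1L]
                              else NA_character_,
                  intermediate_tf = if (config$n_strain_tfs >= 2)
                                      tf_genes[2L] else NA_character_)
    list(proteome = proteome, truth = truth)
  })
}
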