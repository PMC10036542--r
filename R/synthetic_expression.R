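consensus_seq <- function(pwm) {
  paste(DNA4[apply(pwm, 2L, which.max)], collapse = "")
}

sample_site_seq <- function(pwm) {
  paste(apply(pwm, 2L, function(col) sample(DNA4, 1L, prob = col)),
        collapse = "")
}

splice_seq <- function(seq, start0, piece) {
  # replace [start0, start0 + nchar(piece)) (0-based) of seq with piece
  paste0(substr(seq, 1L, start0), piece,
         substr(seq, start0 + nchar(piece) + 1L, nchar(seq)))
}

#' Plant binding sites and simulate the time-course experiment
#'
#' Completes the synthetic dataset: wires the regulatory cascade (master
#' TF -> direct regulon + intermediate TF; intermediate TF -> indirect
#' regulon; remaining TFs -> small unresponsive regulons), embeds one
#' motif occurrence per regulatory edge in the target's promoter window
#' (strand-aware, consensus-planted by default), scrubs the rest of the
#' genome of chance motif hits so planted sites are the only sites at the
#' default scan threshold, then simulates negative-binomial counts whose
#' means shift by `master_effect_log2 * effect_decay[t]` (attenuated for
#' indirect targets, sign split up/down within the regulon) and per-base
#' Poisson coverage that is continuous across operon members and their
#' gaps.
#'
#' @param config A [generator_config()].
#' @param genome_out Result of [generate_genome()].
#' @param tfdb Result of [generate_tf_database()].
#' @param proteome_out Result of [generate_strain_proteome()].
#' @return List with `genome` (edited), `counts` (genes x samples integer
#'   matrix, samples `<timepoint>_<rep>`), `coverage` (list: `contig`,
#'   `samples`, `depth` base x sample integer matrix), and the completed
#'   `truth` (`true_tfs`, `tf_donor`, `master_tf`, `intermediate_tf`,
#'   `true_edges`, `true_operons`, `true_degs`, `planted_sites`,
#'   `expected_log2fc`).
#' @export
plant_sites_and_expression <- function(config, genome_out, tfdb,
                                       proteome_out) {
  stopifnot(inherits(config, "generator_config"))
  ann <- genome_out$annotation
  truth <- c(genome_out$truth, proteome_out$truth)
  withr::with_seed(stage_seed(config$seed, "plant"), {
    tf_genes <- truth$true_tfs
    operon_genes <- unlist(truth$true_operons)
    pool <- setdiff(ann$gene, c(operon_genes, tf_genes))

    edges <- data.frame(tf = character(), target = character(),
                        type = character(), sign = numeric(),
                        stringsAsFactors = FALSE)
    sgn <- function(k) rep(c(1, -1), length.out = k)
    if (length(tf_genes) >= 1L) {
      master <- truth$master_tf
      n_dir <- min(config$regulon_direct, length(pool))
      direct <- sample(pool, n_dir)
      pool <- setdiff(pool, direct)
      edges <- rbind(edges, data.frame(tf = master, target = direct,
                                       type = "direct", sign = sgn(n_dir),
                                       stringsAsFactors = FALSE))
      if (length(tf_genes) >= 2L) {
        inter <- truth$intermediate_tf
        edges <- rbind(edges,
                       data.frame(tf = master, target = inter,
                                  type = "direct", sign = 1,
                                  stringsAsFactors = FALSE))
        n_ind <- min(config$regulon_indirect, length(pool))
        indirect <- sample(pool, n_ind)
        pool <- setdiff(pool, indirect)
        edges <- rbind(edges,
                       data.frame(tf = inter, target = indirect,
                                  type = "indirect", sign = sgn(n_ind),
                                  stringsAsFactors = FALSE))
        for (tf in tf_genes[-c(1L, 2L)]) {
          n_o <- min(config$other_regulon_size, length(pool))
          if (n_o == 0L) break
          tg <- sample(pool, n_o)
          pool <- setdiff(pool, tg)
          edges <- rbind(edges,
                         data.frame(tf = tf, target = tg, type = "other",
                                    sign = 0, stringsAsFactors = FALSE))
        }
      }
    }

    # --- plant one site per edge in the target's promoter window ---
    gseq <- genome_out$genome[[1L]]
    contig <- names(genome_out$genome)[1L]
    sites <- list()
    for (i in seq_len(nrow(edges))) {
      tf <- edges$tf[i]
      pwm <- tfdb$pwms[[truth$tf_donor[[tf]]]]
      L <- ncol(pwm)
      if (config$promoter_window < L + config$site_offset_range[1]) {
        stop("placement error: promoter window shorter than motif")
      }
      g <- ann[ann$gene == edges$target[i], ]
      off <- sample(seq(config$site_offset_range[1],
                        min(config$site_offset_range[2],
                            config$promoter_window - L)), 1L)
      core <- if (config$site_mode == "consensus") consensus_seq(pwm)
              else sample_site_seq(pwm)
      if (g$strand == "+") {
        start0 <- g$start - off - L
        piece <- core
      } else {
        start0 <- g$end + off
        piece <- revcomp(core)
      }
      if (start0 < 0L || start0 + L > nchar(gseq)) {
        stop("placement error: site outside contig bounds")
      }
      gseq <- splice_seq(gseq, start0, piece)
      sites[[i]] <- data.frame(tf = tf, contig = contig, start = start0,
                               end = start0 + L, strand = g$strand,
                               target = edges$target[i],
                               stringsAsFactors = FALSE)
    }
    planted <- if (length(sites) > 0L) do.call(rbind, sites) else
      data.frame(tf = character(), contig = character(), start = integer(),
                 end = integer(), strand = character(),
                 target = character(), stringsAsFactors = FALSE)

    # --- scrub chance motif hits anywhere outside planted intervals ---
    loms <- lapply(tfdb$pwms, pwm_log_odds)
    for (iter in seq_len(25L)) {
      hits <- scan_genome(loms, stats::setNames(c(gseq), contig),
                          threshold_frac = config$scan_threshold_frac)
      if (nrow(hits) > 0L && nrow(planted) > 0L) {
        chance <- !mapply(function(s, e) {
          any(s < planted$end & planted$start < e)
        }, hits$start, hits$end)
        hits <- hits[chance, , drop = FALSE]
      }
      if (nrow(hits) == 0L) break
      for (i in seq_len(nrow(hits))) {
        pos <- setdiff(seq(hits$start[i], hits$end[i] - 1L),
                       unlist(mapply(seq, planted$start,
                                     planted$end - 1L,
                                     SIMPLIFY = FALSE)))
        if (length(pos) == 0L) next
        p <- pos[ceiling(length(pos) / 2)]
        old <- substr(gseq, p + 1L, p + 1L)
        gseq <- splice_seq(gseq, p, sample(setdiff(DNA4, old), 1L))
      }
    }
    genome <- stats::setNames(c(gseq), contig)

    # --- expected expression means and true DEGs ---
    tps <- config$timepoints
    post <- tps[-1L]
    n_genes <- nrow(ann)
    baseline <- stats::setNames(
      10 ^ stats::runif(n_genes, log10(config$baseline_mean_range[1]),
                        log10(config$baseline_mean_range[2])),
      ann$gene)
    for (op in truth$true_operons) {       # co-transcription: shared level
      baseline[op] <- baseline[op[1L]]
    }
    effect <- matrix(0, n_genes, length(post),
                     dimnames = list(ann$gene, post))
    resp <- edges[edges$type %in% c("direct", "indirect"), , drop = FALSE]
    for (i in seq_len(nrow(resp))) {
      e0 <- config$master_effect_log2 *
        (if (resp$type[i] == "indirect") config$indirect_attenuation else 1)
      s <- if (resp$sign[i] < 0) -1 else 1
      effect[resp$target[i], ] <- s * e0 * config$effect_decay
    }
    true_degs <- lapply(post, function(tp) {
      e <- effect[, tp]
      list(up = names(e)[e >= 1], down = names(e)[e <= -1])
    })
    names(true_degs) <- post

    samples <- as.vector(t(outer(tps, seq_len(config$replicates),
                                 paste, sep = "_")))
    mu <- matrix(0, n_genes, length(samples),
                 dimnames = list(ann$gene, samples))
    for (s in samples) {
      tp <- sub("_[^_]+$", "", s)
      mu[, s] <- baseline *
        (if (tp == tps[1L]) 1 else 2 ^ effect[, tp])
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion),
                     n_genes, length(samples),
                     dimnames = dimnames(mu))

    # --- per-base coverage, continuous across operons ---
    glen <- nchar(gseq)
    depth <- matrix(0L, glen, length(samples),
                    dimnames = list(NULL, samples))
    # per-base expression template regions: gene bodies + operon gaps
    regions <- lapply(seq_len(n_genes), function(i) {
      list(pos = seq(ann$start[i] + 1L, ann$end[i]), gene = ann$gene[i])
    })
    gap_regions <- list()
    for (op in truth$true_operons) {
      idx <- match(op, ann$gene)
      idx <- idx[order(ann$start[idx])]
      for (j in seq_len(length(idx) - 1L)) {
        a <- ann$end[idx[j]]; b <- ann$start[idx[j + 1L]]
        if (b > a) {
          gap_regions[[length(gap_regions) + 1L]] <-
            list(pos = seq(a + 1L, b), gene = op[1L])
        }
      }
    }
    all_regions <- c(regions, gap_regions)
    for (s in samples) {
      lam <- rep(config$background_coverage, glen)
      for (r in all_regions) {
        lam[r$pos] <- mu[r$gene, s] * config$depth_factor
      }
      depth[, s] <- stats::rpois(glen, lam)
    }

    truth$true_edges <- edges
    truth$planted_sites <- planted
    truth$true_degs <- true_degs
    truth$expected_log2fc <- effect
    list(genome = genome, counts = counts,
         coverage = list(contig = contig, samples = samples,
                         depth = depth),
         truth = truth)
  })
}

#' Generate a toy pathway database with a planted regulon pathway
#'
#' One pathway collects the master regulator's full (direct + indirect)
#' regulon; the rest are random gene sets. The background universe is the
#' union of all pathway genes, an annotated-universe background.
#'
#' @param config A [generator_config()].
#' @param truth Completed truth from [plant_sites_and_expression()].
#' @param annotation Gene annotation from [generate_genome()].
#' @param n_random Number of random pathways (default 12).
#' @param size_range Random pathway sizes (default 15--40).
#' @return A `pathway_db` list (see [pathway_db()]).
#' @export
generate_pathways <- function(config, truth, annotation, n_random = 12,
                              size_range = c(15L, 40L)) {
  withr::with_seed(stage_seed(config$seed, "pathways"), {
    genes <- annotation$gene
    sets <- list()
    regulon <- unique(truth$true_edges$target[
      truth$true_edges$type %in% c("direct", "indirect")])
    if (length(regulon) > 0L) sets$path_regulon <- sort(regulon)
    for (i in seq_len(n_random)) {
      k <- sample(seq(size_range[1], size_range[2]), 1L)
      sets[[sprintf("path_rand%02d", i)]] <- sort(sample(genes, k))
    }
    pathway_db(sets)
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [generate_genome()],
#' [generate_tf_database()], [generate_strain_proteome()],
#' [plant_sites_and_expression()] and [generate_pathways()].
#'
#' @param config A [generator_config()] (default config, seed 0, if
#'   omitted).
#' @return List with `config`, `genome`, `annotation`, `tfdb`, `proteome`,
#'   `counts`, `coverage`, `pathways`, `truth`.
#' @export
simulate_experiment <- function(config = generator_config()) {
  g <- generate_genome(config)
  tfdb <- generate_tf_database(config)
  p <- generate_strain_proteome(config, g, tfdb)
  x <- plant_sites_and_expression(config, g, tfdb, p)
  pw <- generate_pathways(config, x$truth, g$annotation)
  list(config = config, genome = x$genome, annotation = g$annotation,
       tfdb = tfdb, proteome = p$proteome, counts = x$counts,
       coverage = x$coverage, pathways = pw, truth = x$truth)
}
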