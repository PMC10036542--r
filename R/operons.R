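#' Operon detector thresholds
#'
#' Thresholds for the six rule-based detectors that vote on whether an
#' adjacent same-strand gene pair is co-transcribed. A pair is called an
#' operon pair when at least `min_votes` detectors agree.
#'
#' @param gap_max Detector 1: maximal intergenic gap in bp (default 100).
#' @param kw_alpha Detector 2: Kruskal-Wallis significance level; coverage
#'   of gene1 / gap / gene2 counts as homogeneous when H stays below the
#'   chi-square(2) critical value at this alpha (default 0.05).
#' @param boundary_frac Detector 3: minimal mean intergenic coverage as a
#'   fraction of the smaller gene mean (default 0.5).
#' @param corr_min Detector 4: minimal Pearson correlation of the two
#'   genes' timepoint-mean expression profiles (default 0.8).
#' @param window Detector 5: sliding window width in bp (default 25).
#' @param window_frac Detector 5: minimal windowed-minimum intergenic
#'   coverage as a fraction of the smaller gene mean (default 0.3).
#' @param fold_max Detector 6: maximal fold difference of gene coverage
#'   means (default 4).
#' @param floor Detector 6: minimal coverage mean for both genes
#'   (default 5).
#' @param min_votes Votes needed to call an operon pair (default 3).
#' @return List of class `operon_config`.
#' @export
operon_config <- function(gap_max = 100, kw_alpha = 0.05,
                          boundary_frac = 0.5, corr_min = 0.8,
                          window = 25L, window_frac = 0.3, fold_max = 4,
                          floor = 5, min_votes = 3L) {
  structure(list(gap_max = gap_max, kw_alpha = kw_alpha,
                 boundary_frac = boundary_frac, corr_min = corr_min,
                 window = as.integer(window), window_frac = window_frac,
                 fold_max = fold_max, floor = floor,
                 min_votes = as.integer(min_votes)),
            class = "operon_config")
}

#' Vote on operon membership of adjacent same-strand gene pairs
#'
#' Candidates are pairs of genes adjacent in genome order and on the same
#' strand. Six detectors vote independently on each candidate from the
#' sample-averaged per-base coverage and the expression matrix: (1) short
#' intergenic gap; (2) Kruskal-Wallis homogeneity of per-base coverage
#' across gene1 / gap / gene2; (3) intergenic mean coverage keeping up
#' with the genes; (4) correlated timepoint expression profiles; (5) no
#' coverage trough in any sliding window of the gap; (6) similar coverage
#' levels with both genes expressed. A zero-length gap delegates the gap
#' detectors to the two boundary bases.
#'
#' @param coverage Coverage list (`contig`, `samples`, `depth` base x
#'   sample matrix) as produced by [plant_sites_and_expression()] or
#'   [read_coverage()].
#' @param annotation Gene table (0-based half-open, single contig).
#' @param mat An [expression_matrix()] for detector 4.
#' @param config An [operon_config()].
#' @return `data.frame` with one row per candidate pair: `gene1`, `gene2`,
#'   `strand`, `gap`, `d1`..`d6` (logical votes), `votes`, `call`.
#' @export
detect_operon_pairs <- function(coverage, annotation, mat,
                                config = operon_config()) {
  stopifnot(inherits(config, "operon_config"))
  depth <- rowMeans(coverage$depth)
  if (nrow(annotation) > 0L &&
      max(annotation$end) > length(depth)) {
    stop("input error: coverage shorter than the annotated genome")
  }
  ann <- annotation[order(annotation$start), , drop = FALSE]
  tm <- timepoint_means(mat)
  kw_crit <- stats::qchisq(1 - config$kw_alpha, df = 2)
  rows <- list()
  for (i in seq_len(nrow(ann) - 1L)) {
    g1 <- ann[i, ]; g2 <- ann[i + 1L, ]
    if (g1$strand != g2$strand) next
    gap_len <- g2$start - g1$end
    cov1 <- depth[(g1$start + 1L):g1$end]
    cov2 <- depth[(g2$start + 1L):g2$end]
    covg <- if (gap_len > 0L) depth[(g1$end + 1L):g2$start] else
      depth[c(g1$end, g2$start + 1L)]  # boundary bases
    m1 <- mean(cov1); m2 <- mean(cov2); mg <- mean(covg)
    mmin <- min(m1, m2)
    d1 <- gap_len <= config$gap_max
    if (length(unique(c(cov1, covg, cov2))) == 1L) {
      d2 <- TRUE  # perfectly flat coverage is trivially homogeneous
    } else {
      kw <- stats::kruskal.test(list(cov1, covg, cov2))$statistic
      d2 <- is.finite(kw) && kw < kw_crit
    }
    d3 <- mg >= config$boundary_frac * mmin
    e1 <- tm[g1$gene, ]; e2 <- tm[g2$gene, ]
    d4 <- stats::sd(e1) > 0 && stats::sd(e2) > 0 &&
      stats::cor(e1, e2) >= config$corr_min
    wmin <- if (length(covg) <= config$window) mean(covg) else
      min(vapply(seq_len(length(covg) - config$window + 1L),
                 function(k) mean(covg[k:(k + config$window - 1L)]),
                 numeric(1)))
    d5 <- wmin >= config$window_frac * mmin
    d6 <- m1 >= config$floor && m2 >= config$floor &&
      max(m1, m2) / max(mmin, 1e-12) <= config$fold_max
    votes <- sum(d1, d2, d3, d4, d5, d6)
    rows[[length(rows) + 1L]] <- data.frame(
      gene1 = g1$gene, gene2 = g2$gene, strand = g1$strand,
      gap = gap_len, d1 = d1, d2 = d2, d3 = d3, d4 = d4, d5 = d5,
      d6 = d6, votes = votes, call = votes >= config$min_votes,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      strand = character(), gap = integer(),
                      d1 = logical(), d2 = logical(), d3 = logical(),
                      d4 = logical(), d5 = logical(), d6 = logical(),
                      votes = integer(), call = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chain positive operon pairs into operons
#'
#' Maximal runs of consecutive positive pairs merge transitively into one
#' operon; genes in no positive pair form no operon. Members are reported
#' in transcription order (genome order, reversed for minus-strand
#' operons).
#'
#' @param pair_calls Output of [detect_operon_pairs()].
#' @param annotation Gene table (for genome order and strand).
#' @return List of class `operon_calls`: each element has `members`
#'   (ordered gene ids) and `votes` (per internal pair).
#' @export
chain_operons <- function(pair_calls, annotation) {
  ann <- annotation[order(annotation$start), , drop = FALSE]
  pos <- pair_calls[pair_calls$call, , drop = FALSE]
  out <- list()
  if (nrow(pos) > 0L) {
    idx1 <- match(pos$gene1, ann$gene)
    pos <- pos[order(idx1), , drop = FALSE]
    idx1 <- sort(idx1)
    run_start <- 1L
    flush <- function(a, b) {
      rows <- pos[a:b, , drop = FALSE]
      members <- c(rows$gene1[1L], rows$gene2)
      if (rows$strand[1L] == "-") members <- rev(members)
      list(members = members, votes = rows$votes)
    }
    for (k in seq_len(nrow(pos))) {
      if (k == nrow(pos) || idx1[k + 1L] != idx1[k] + 1L ||
          pos$gene2[k] != pos$gene1[k + 1L]) {
        out[[length(out) + 1L]] <- flush(run_start, k)
        run_start <- k + 1L
      }
    }
  }
  names(out) <- if (length(out) > 0L)
    sprintf("operon%04d", seq_along(out)) else character(0)
  structure(out, class = "operon_calls")
}

#' Operon-value profiles
#'
#' The operon value at a timepoint is the arithmetic mean of the member
#' genes' expression z-scores at that timepoint; the profile lists the
#' values in time order (control first).
#'
#' @param operons An `operon_calls` list (or any list with `$members`),
#'   or a plain list of gene-id vectors.
#' @param zscores Genes x timepoints z-score matrix from
#'   [expression_zscores()].
#' @return Operons x timepoints numeric matrix of operon values.
#' @export
operon_values <- function(operons, zscores) {
  members <- lapply(operons, function(op) {
    if (is.list(op)) op$members else op
  })
  missing <- setdiff(unlist(members), rownames(zscores))
  if (length(missing) > 0L) {
    stop("consistency error: operon member(s) missing from the ",
         "expression matrix: ", paste(missing, collapse = ", "))
  }
  prof <- t(vapply(members, function(m) {
    colMeans(zscores[m, , drop = FALSE])
  }, numeric(ncol(zscores))))
  if (is.null(names(operons))) {
    rownames(prof) <- sprintf("operon%04d", seq_along(members))
  }
  colnames(prof) <- colnames(zscores)
  prof
}

# k-means++ seeding: D^2-weighted sequential center choice.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x),
                            byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    dn <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  x[centers, , drop = FALSE]
}

#' Cluster operon profiles with k-means
#'
#' k-means on the time-ordered operon-value profiles, k-means++ seeding
#' with 10 restarts, best solution by total within-cluster sum of squares.
#' Deterministic for a fixed seed.
#'
#' @param profiles Operons x timepoints matrix from [operon_values()].
#' @param k Number of clusters (default 6).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return List with `cluster` (named integer labels) and `centers`
#'   (k x timepoints mean profiles).
#' @export
cluster_operons <- function(profiles, k = 6, seed = 0L, restarts = 10L) {
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < k) {
    stop("sizing error: fewer profiles (", nrow(profiles),
         ") than clusters (", k, ")")
  }
  if (nrow(profiles) == k) {  # each profile is its own cluster
    return(list(cluster = stats::setNames(seq_len(k),
                                          rownames(profiles)),
                centers = profiles))
  }
  withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(profiles, k)
      fit <- suppressWarnings(
        stats::kmeans(profiles, centers = centers, iter.max = 100L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
        best <- fit
      }
    }
    list(cluster = stats::setNames(best$cluster, rownames(profiles)),
         centers = best$centers)
  })
}
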