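#' Construct an expression matrix with timepoint design
#'
#' Wraps a genes x samples count matrix together with its time-course
#' design. Sample names must be `<timepoint>_<replicate>`; exactly one
#' timepoint is the control and every timepoint needs at least one
#' replicate.
#'
#' @param counts Non-negative integer matrix, rows = genes, columns =
#'   samples named `<timepoint>_<rep>`.
#' @param timepoints Ordered character vector of timepoint labels, control
#'   first (default `c("control", "5min", "1h", "3h", "12h")`).
#' @param control Label of the control timepoint (default the first).
#' @return A list of class `expression_matrix` with elements `counts`,
#'   `timepoints`, `control`, `sample_tp` (timepoint of each column).
#' @export
expression_matrix <- function(counts,
                              timepoints = c("control", "5min", "1h",
                                             "3h", "12h"),
                              control = timepoints[1L]) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  sample_tp <- sub("_[^_]+$", "", colnames(counts))
  bad <- setdiff(sample_tp, timepoints)
  if (length(bad) > 0L) {
    stop("sample timepoint label(s) not in design: ",
         paste(unique(bad), collapse = ", "))
  }
  stopifnot(control %in% timepoints, sum(timepoints == control) == 1L)
  missing_tp <- setdiff(timepoints, sample_tp)
  if (length(missing_tp) > 0L) {
    stop("timepoint(s) with no replicate: ",
         paste(missing_tp, collapse = ", "))
  }
  structure(list(counts = counts, timepoints = timepoints,
                 control = control, sample_tp = sample_tp),
            class = "expression_matrix")
}

#' Per-gene mean counts at each timepoint
#'
#' @param mat An [expression_matrix()].
#' @return Genes x timepoints matrix of replicate-mean counts, columns in
#'   design order.
#' @export
timepoint_means <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  sapply(mat$timepoints, function(tp) {
    rowMeans(mat$counts[, mat$sample_tp == tp, drop = FALSE])
  })
}

#' Per-gene z-scores across timepoint means
#'
#' Standardizes each gene's timepoint-mean profile to mean 0 and unit
#' (sample) standard deviation. Zero-variance genes get an all-zero row.
#' With `axis = "samples"` the standardization is instead computed across
#' the individual samples (and then averaged back to timepoints), the
#' alternative reading of a per-timepoint z-score.
#'
#' @param mat An [expression_matrix()].
#' @param axis `"time"` (default): z across the timepoint means;
#'   `"samples"`: z across samples, then averaged per timepoint.
#' @return Genes x timepoints matrix of z-scores.
#' @export
expression_zscores <- function(mat, axis = c("time", "samples")) {
  axis <- match.arg(axis)
  tm <- timepoint_means(mat)
  if (axis == "time") {
    z <- t(apply(tm, 1L, zscore_row))
  } else {
    zs <- t(apply(mat$counts, 1L, zscore_row))
    z <- sapply(mat$timepoints, function(tp) {
      rowMeans(zs[, mat$sample_tp == tp, drop = FALSE])
    })
  }
  dimnames(z) <- dimnames(tm)
  z
}

zscore_row <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Log2 fold change of a timepoint against control
#'
#' `log2((mean_treated + c) / (mean_control + c))` per gene, with
#' pseudocount `c` keeping every value finite (an all-zero gene maps to 0).
#'
#' @param mat An [expression_matrix()].
#' @param timepoint A non-control timepoint label present in the design.
#' @param pseudocount Pseudocount added to both means (default 1).
#' @return Named numeric vector of log2 fold changes per gene.
#' @export
compute_log2fc <- function(mat, timepoint, pseudocount = 1) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!timepoint %in% mat$timepoints) {
    stop("unknown timepoint: ", timepoint)
  }
  if (timepoint == mat$control) stop("timepoint must differ from control")
  tm <- timepoint_means(mat)
  log2((tm[, timepoint] + pseudocount) / (tm[, mat$control] + pseudocount))
}

#' Call differentially expressed genes by fold-change threshold
#'
#' A gene is a DEG iff `|log2fc| >= threshold` (boundary inclusive);
#' direction is the sign of the fold change.
#'
#' @param log2fc Named numeric vector from [compute_log2fc()].
#' @param timepoint Label stored in the output records.
#' @param threshold Positive fold-change threshold (default 1).
#' @return `data.frame` with columns `gene`, `timepoint`, `log2fc`,
#'   `direction` (`"up"`/`"down"`).
#' @export
call_degs <- function(log2fc, timepoint = NA_character_, threshold = 1) {
  stopifnot(threshold > 0, !is.null(names(log2fc)))
  keep <- which(abs(log2fc) >= threshold)
  data.frame(gene = names(log2fc)[keep],
             timepoint = rep(timepoint, length(keep)),
             log2fc = unname(log2fc[keep]),
             direction = ifelse(log2fc[keep] > 0, "up", "down")[
               seq_along(keep)],
             stringsAsFactors = FALSE)
}

#' DEG table across all post-control timepoints
#'
#' @param mat An [expression_matrix()].
#' @param threshold Fold-change threshold (default 1).
#' @param pseudocount Pseudocount for [compute_log2fc()].
#' @return Row-bound DEG records for every non-control timepoint, in design
#'   order.
#' @export
call_degs_all <- function(mat, threshold = 1, pseudocount = 1) {
  tps <- setdiff(mat$timepoints, mat$control)
  do.call(rbind, lapply(tps, function(tp) {
    call_degs(compute_log2fc(mat, tp, pseudocount), tp, threshold)
  }))
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of
#' z-scored per-gene profiles, cut at a fixed cophenetic distance -- the
#' heatmap-style grouping of response patterns.
#'
#' @param profiles Genes x timepoints numeric matrix (e.g. log2fc or
#'   z-scores); rows are z-scored internally before clustering.
#' @param linkage_cut Height at which the dendrogram is cut (default 3).
#' @return Named integer vector of cluster labels (a single gene gets
#'   cluster 1).
#' @export
cluster_expression <- function(profiles, linkage_cut = 3) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  if (nrow(profiles) == 1L) {
    return(stats::setNames(1L, rownames(profiles)))
  }
  z <- t(apply(profiles, 1L, zscore_row))
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "average")
  stats::cutree(hc, h = linkage_cut)
}
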