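#' Propagation settings
#'
#' @param restart Restart probability in (0, 1] (default 0.5). Higher
#'   values keep influence near the seed; 1 disables diffusion entirely.
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return List of class `propagation_config`.
#' @export
propagation_config <- function(restart = 0.5, tol = 1e-6,
                               max_iter = 1000) {
  stopifnot(restart > 0, restart <= 1, tol > 0, max_iter >= 1)
  structure(list(restart = restart, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "propagation_config")
}

#' Column-normalized propagation operator of a GRN
#'
#' Nodes are all TFs and targets; entry (target, tf) of the operator is
#' `1 / outdegree(tf)` for each TF->target edge, so every column with
#' out-edges sums to 1 and dangling columns are zero (their mass decays to
#' the restart term during propagation). Normalizing an already-normalized
#' network is a no-op.
#'
#' @param grn A [build_grn()] result.
#' @return Sparse `dgCMatrix` with dimnames = node ids.
#' @export
normalize_adjacency <- function(grn) {
  stopifnot(inherits(grn, "grn"))
  if (nrow(grn$edges) == 0L) stop("structure error: GRN has no edges")
  nodes <- sort(unique(c(grn$tfs, grn$targets)))
  outdeg <- table(grn$edges$tf)
  w <- 1 / as.numeric(outdeg[grn$edges$tf])
  Matrix::sparseMatrix(i = match(grn$edges$target, nodes),
                       j = match(grn$edges$tf, nodes),
                       x = w, dims = c(length(nodes), length(nodes)),
                       dimnames = list(nodes, nodes))
}

#' Network propagation with restart
#'
#' Iterates `p <- (1 - r) W p + r p0` from the normalized seed `p0` until
#' the L1 change drops below `tol`. The returned vector satisfies the
#' fixed-point equation within `tol`.
#'
#' @param seed Named non-negative vector over (a subset of) the operator's
#'   nodes; normalized to sum 1 internally. Must not be all zero.
#' @param W Operator from [normalize_adjacency()].
#' @param config A [propagation_config()].
#' @return Named influence vector over all nodes.
#' @export
propagate <- function(seed, W, config = propagation_config()) {
  stopifnot(inherits(config, "propagation_config"))
  nodes <- rownames(W)
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  if (is.null(names(seed))) {
    stopifnot(length(seed) == length(nodes))
    p0[] <- seed
  } else {
    stopifnot(all(names(seed) %in% nodes))
    p0[names(seed)] <- seed
  }
  if (any(p0 < 0)) stop("seed must be non-negative")
  s <- sum(p0)
  if (s == 0) stop("input error: all-zero seed")
  p0 <- p0 / s
  r <- config$restart
  if (r == 1) return(p0)
  p <- p0
  converged <- FALSE
  for (i in seq_len(config$max_iter)) {
    p_new <- as.numeric((1 - r) * (W %*% p)) + r * p0
    delta <- sum(abs(p_new - p))
    p <- stats::setNames(p_new, nodes)
    if (delta < config$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("propagation did not converge within max_iter; ",
            "returning last iterate")
  }
  p
}

#' Influence of one TF on the DEG response
#'
#' Propagates a unit seed at the TF over the network and scores the Pearson
#' correlation between the propagated vector and `|log2fc|`, restricted to
#' the DEG genes of the timepoint. Degenerate cases (constant vectors,
#' e.g. a TF with no path to any DEG) score 0.
#'
#' @param tf TF id (must be a GRN source node).
#' @param grn A [build_grn()] result.
#' @param deg_log2fc Named vector of log2 fold changes over the DEG genes
#'   at this timepoint.
#' @param W Operator from [normalize_adjacency()].
#' @param config A [propagation_config()].
#' @return Scalar influence score.
#' @export
score_tf_influence <- function(tf, grn, deg_log2fc, W,
                               config = propagation_config()) {
  stopifnot(tf %in% grn$tfs)
  degs <- names(deg_log2fc)
  if (length(degs) < 2L) return(0)
  p <- propagate(stats::setNames(1, tf), W, config)
  x <- ifelse(degs %in% names(p), p[degs], 0)  # genes off-network get 0
  y <- abs(deg_log2fc[degs])
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15) return(0)
  stats::cor(x, y)
}

#' Select the major TFs of a timepoint (greedy influence maximization)
#'
#' Ranks TFs by influence score (ties broken by id), then makes one greedy
#' pass in rank order: a TF is selected iff it covers at least one
#' not-yet-covered DEG via a direct GRN edge. The pass stops when every
#' coverable DEG is covered or the ranking is exhausted. The module is the
#' selected TFs, the covered DEG targets, and the induced TF->target
#' edges; DEGs targeted by no TF are reported as `uncovered`.
#'
#' @param grn A [build_grn()] result.
#' @param deg_records DEG table (columns `gene`, `timepoint`, `log2fc`)
#'   from [call_degs_all()].
#' @param timepoint Timepoint label to extract.
#' @param config A [propagation_config()].
#' @param W Optional precomputed operator (saves recomputation across
#'   timepoints).
#' @return List of class `network_module`: `timepoint`, `major_tfs`
#'   (`data.frame` tf / influence / rank, in greedy selection order),
#'   `targets`, `edges`, `uncovered`, `scores` (all TF influence scores).
#' @export
select_major_tfs <- function(grn, deg_records, timepoint,
                             config = propagation_config(), W = NULL) {
  degs <- deg_records[deg_records$timepoint == timepoint, , drop = FALSE]
  if (nrow(degs) == 0L) {
    return(structure(list(timepoint = timepoint,
                          major_tfs = data.frame(tf = character(),
                                                 influence = numeric(),
                                                 rank = integer()),
                          targets = character(), edges = grn$edges[0, ],
                          uncovered = character(),
                          scores = stats::setNames(numeric(0),
                                                   character(0)),
                          empty = TRUE),
                     class = "network_module"))
  }
  if (nrow(grn$edges) == 0L) {
    return(structure(list(timepoint = timepoint,
                          major_tfs = data.frame(tf = character(),
                                                 influence = numeric(),
                                                 rank = integer()),
                          targets = character(), edges = grn$edges,
                          uncovered = sort(degs$gene),
                          scores = stats::setNames(
                            numeric(length(grn$tfs)), grn$tfs),
                          empty = FALSE),
                     class = "network_module"))
  }
  if (is.null(W)) W <- normalize_adjacency(grn)
  deg_lfc <- stats::setNames(degs$log2fc, degs$gene)
  scores <- vapply(grn$tfs, function(tf) {
    score_tf_influence(tf, grn, deg_lfc, W, config)
  }, numeric(1))
  ranking <- grn$tfs[order(-scores, grn$tfs)]
  deg_set <- degs$gene
  covered <- character(0)
  selected <- character(0)
  targets_of <- split(grn$edges$target, grn$edges$tf)
  coverable <- intersect(deg_set, grn$edges$target)
  for (tf in ranking) {
    new <- setdiff(intersect(targets_of[[tf]], deg_set), covered)
    if (length(new) > 0L) {
      selected <- c(selected, tf)
      covered <- union(covered, new)
    }
    if (setequal(covered, coverable)) break
  }
  edges <- grn$edges[grn$edges$tf %in% selected &
                       grn$edges$target %in% covered, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(timepoint = timepoint,
                 major_tfs = data.frame(tf = selected,
                                        influence = unname(
                                          scores[selected]),
                                        rank = seq_along(selected),
                                        stringsAsFactors = FALSE),
                 targets = sort(covered), edges = edges,
                 uncovered = sort(setdiff(deg_set, coverable)),
                 scores = scores, empty = FALSE),
            class = "network_module")
}

#' Extract network modules for every post-control timepoint
#'
#' @param grn A [build_grn()] result.
#' @param deg_records DEG table from [call_degs_all()].
#' @param timepoints Ordered post-control timepoint labels.
#' @param config A [propagation_config()].
#' @return Named list of [select_major_tfs()] modules.
#' @export
extract_modules <- function(grn, deg_records, timepoints,
                            config = propagation_config()) {
  W <- if (nrow(grn$edges) > 0L) normalize_adjacency(grn) else NULL
  mods <- lapply(timepoints, function(tp) {
    select_major_tfs(grn, deg_records, tp, config, W)
  })
  names(mods) <- timepoints
  mods
}

#' @export
print.network_module <- function(x, ...) {
  cat("Network module [", x$timepoint, "]: ", nrow(x$major_tfs),
      " major TFs, ", length(x$targets), " covered DEG targets, ",
      length(x$uncovered), " uncovered\n", sep = "")
  invisible(x)
}
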