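#' Pathway database
#'
#' @param sets Named list of gene-id vectors (no empty pathways).
#' @param background Optional gene universe; defaults to the union of all
#'   pathway genes (an annotated-universe background). Every pathway gene
#'   must lie inside it.
#' @return List of class `pathway_db` with `sets` and `background`.
#' @export
pathway_db <- function(sets, background = NULL) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (any(lengths(sets) == 0L)) stop("empty pathway gene set")
  if (is.null(background)) {
    background <- sort(unique(unlist(sets)))
  } else {
    background <- sort(unique(as.character(background)))
    out <- setdiff(unlist(sets), background)
    if (length(out) > 0L) {
      stop("pathway gene(s) outside the background universe: ",
           paste(utils::head(out, 5L), collapse = ", "))
    }
  }
  structure(list(sets = sets, background = background),
            class = "pathway_db")
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for X hypergeometric with `N` background genes of which
#' `K` are in the pathway and `n` are drawn (the query). `k = 0` gives
#' exactly 1.
#'
#' @param k Overlap between query and pathway.
#' @param K Pathway size.
#' @param n Query size.
#' @param N Background size.
#' @return The p-value in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1,
            length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N ||
      k > min(n, K)) {
    stop("input error: inconsistent hypergeometric counts")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric pathway enrichment of a gene set
#'
#' Tests every pathway with at least one query overlap; significance is
#' raw p < 0.05 (matching a fixed-threshold criterion); Benjamini-Hochberg
#' q-values are reported alongside for transparency but do not drive the
#' flag. Query genes outside the background are dropped (with a message);
#' duplicates are ignored.
#'
#' @param query Character vector of gene ids.
#' @param db A [pathway_db()].
#' @param direction Label stored in the output (`"up"`, `"down"` or
#'   `"none"`).
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return `data.frame` sorted by ascending p: `pathway`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, `direction`, `significant`.
#' @export
enrich <- function(query, db, direction = "none", alpha = 0.05) {
  stopifnot(inherits(db, "pathway_db"))
  if (length(db$background) == 0L) stop("input error: empty background")
  query <- unique(as.character(query))
  dropped <- setdiff(query, db$background)
  query <- intersect(query, db$background)
  if (length(dropped) > 0L) {
    message(length(dropped), " query gene(s) outside the background ",
            "were dropped")
  }
  N <- length(db$background)
  n <- length(query)
  rows <- lapply(names(db$sets), function(pw) {
    genes <- db$sets[[pw]]
    k <- length(intersect(query, genes))
    if (k == 0L) return(NULL)
    data.frame(pathway = pw, k = k, K = length(genes), n = n, N = N,
               p = hypergeom_p(k, length(genes), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(pathway = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p = numeric(), q = numeric(),
                      direction = character(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$direction <- direction
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
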