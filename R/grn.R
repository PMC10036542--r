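#' Assign each binding site to its closest gene
#'
#' For every site the gene minimizing interval distance (0 when
#' overlapping) within `max_distance` becomes its target, the
#' closest-feature rule of genomic interval tools. Exact-tie distances are
#' broken by (a) preferring the gene whose start lies downstream of the
#' site on the site's strand, then (b) the smaller gene start coordinate.
#' Sites with no gene within range yield no edge.
#'
#' @param sites Site table from [scan_genome()] (`tf`, `contig`, `start`,
#'   `end`, `strand`, `score`; 0-based half-open).
#' @param annotation Gene table (`gene`, `contig`, `start`, `end`,
#'   `strand`; 0-based half-open) as from [generate_genome()].
#' @param max_distance Maximal site-to-gene distance in bp (default 1000);
#'   `Inf` for unbounded closest-gene assignment.
#' @return `data.frame` of raw edges: `tf`, `target`, `score`, `distance`,
#'   plus the site coordinates (`contig`, `site_start`, `site_end`,
#'   `site_strand`).
#' @export
assign_targets <- function(sites, annotation, max_distance = 1000) {
  stopifnot(nrow(annotation) > 0L)
  empty <- data.frame(tf = character(), target = character(),
                      score = numeric(), distance = numeric(),
                      contig = character(), site_start = integer(),
                      site_end = integer(), site_strand = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(empty)
  bad <- setdiff(sites$contig, annotation$contig)
  if (length(bad) > 0L) {
    stop("site(s) on contig(s) absent from the annotation: ",
         paste(bad, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    g <- annotation[annotation$contig == s$contig, , drop = FALSE]
    # interval distance, 0 if overlapping (half-open intervals)
    d <- pmax(0, pmax(g$start - s$end + 1L, s$start - g$end + 1L))
    d <- ifelse(g$start < s$end & s$start < g$end, 0L, d)
    ok <- which(d <= max_distance)
    if (length(ok) == 0L) return(NULL)
    dmin <- min(d[ok])
    cand <- ok[d[ok] == dmin]
    if (length(cand) > 1L) {
      downstream <- if (s$strand == "+") {
        g$start[cand] >= s$end
      } else {
        g$end[cand] <= s$start
      }
      if (any(downstream)) cand <- cand[downstream]
      cand <- cand[order(g$start[cand])][1L]
    }
    data.frame(tf = s$tf, target = g$gene[cand], score = s$score,
               distance = dmin, contig = s$contig, site_start = s$start,
               site_end = s$end, site_strand = s$strand,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the bipartite gene regulatory network
#'
#' Collapses raw site-to-gene edges into unique (TF, target) pairs, keeping
#' the best site score and its distance per pair. Source nodes are exactly
#' the screened TFs; autoregulatory self-edges are retained.
#'
#' @param raw_edges Output of [assign_targets()].
#' @param tfs Character vector of screened TF ids (every edge source must
#'   be one of them).
#' @return A list of class `grn` with `edges` (`tf`, `target`, `score`,
#'   `distance`), `tfs`, and `targets`.
#' @export
build_grn <- function(raw_edges, tfs) {
  bad <- setdiff(unique(raw_edges$tf), tfs)
  if (length(bad) > 0L) {
    stop("edge source(s) not in the screened TF set: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(raw_edges) == 0L) {
    edges <- data.frame(tf = character(), target = character(),
                        score = numeric(), distance = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    key <- paste(raw_edges$tf, raw_edges$target, sep = "\r")
    ord <- order(key, -raw_edges$score, raw_edges$distance)
    e <- raw_edges[ord, , drop = FALSE]
    e <- e[!duplicated(paste(e$tf, e$target, sep = "\r")), , drop = FALSE]
    edges <- e[order(e$tf, e$target),
               c("tf", "target", "score", "distance"), drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, tfs = sort(unique(tfs)),
                 targets = sort(unique(edges$target))),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("Gene regulatory network: ", length(x$tfs), " TFs, ",
      length(x$targets), " targets, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}
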