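#' @useDynLib bacgrn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson & Robinson background amino-acid frequencies, the composition
# the BLOSUM62 Karlin-Altschul constants are calibrated for; used when
# sampling random protein sequences.
AA_FREQ <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364,
             C = 0.01925, Q = 0.04264, E = 0.06295, G = 0.07377,
             H = 0.02199, I = 0.05142, L = 0.09019, K = 0.05744,
             M = 0.02243, F = 0.03856, P = 0.05203, S = 0.07120,
             T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Alignment scoring parameters with Karlin-Altschul constants
#'
#' Bundles the substitution matrix name, affine gap penalties and the
#' Karlin-Altschul constants used to convert raw local-alignment scores into
#' e-values (`E = K * m * n * exp(-lambda * S)`). Defaults are the standard
#' gapped BLOSUM62 11/1 pair (lambda = 0.267, K = 0.041). These are fixed
#' constants, not database-calibrated estimates.
#'
#' @param lambda Positive scale of the score distribution (nats per score
#'   unit).
#' @param K Positive search-space prefactor.
#' @param matrix Substitution matrix name; only `"BLOSUM62"` is shipped.
#' @param gap_open Gap-open penalty (a gap of length k costs
#'   `gap_open + k * gap_ext`).
#' @param gap_ext Per-residue gap-extension penalty.
#' @return A list of class `karlin_params`.
#' @export
karlin_params <- function(lambda = 0.267, K = 0.041, matrix = "BLOSUM62",
                          gap_open = 11, gap_ext = 1) {
  stopifnot(lambda > 0, K > 0, gap_open >= 0, gap_ext >= 0)
  if (!identical(matrix, "BLOSUM62")) {
    stop("only the BLOSUM62 substitution matrix is available")
  }
  structure(list(lambda = lambda, K = K, matrix = matrix,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "karlin_params")
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA20, AA20]
    }
    cache
  }
})

encode_protein <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) stop("empty ", what)
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  idx <- match(v, AA20)
  if (anyNA(idx)) {
    stop("unknown residue(s) in ", what, ": ",
         paste(unique(v[is.na(idx)]), collapse = ", "))
  }
  idx - 1L  # 0-based for C++
}

#' Exact local protein alignment (Smith-Waterman, affine gaps)
#'
#' Computes the maximal local alignment score of two protein sequences under
#' BLOSUM62 with affine gap penalties (a gap of length k costs
#' `gap_open + k * gap_ext`). Exact dynamic programming, no heuristic
#' seeding. Identity is the fraction of identical aligned positions over the
#' traceback length of one optimal alignment.
#'
#' @param query,subject Protein sequences (single strings over the 20
#'   standard amino acids; anything else, including `X`, is an error).
#' @param params A [karlin_params()] object.
#' @return A one-row `data.frame` with columns `query`, `subject` (the
#'   sequences), `score`, `evalue` (computed against the subject alone, i.e.
#'   `n = nchar(subject)`), and `identity`.
#' @examples
#' smith_waterman("HEAGAWGHEE", "PAWHEAE")
#' @export
smith_waterman <- function(query, subject, params = karlin_params()) {
  q <- encode_protein(query, "query")
  s <- encode_protein(subject, "subject")
  res <- .sw_align(q, s, blosum62_matrix(), params$gap_open, params$gap_ext)
  data.frame(query = query, subject = subject, score = res$score,
             evalue = evalue(res$score, length(q), length(s), params),
             identity = res$identity, stringsAsFactors = FALSE)
}

#' Karlin-Altschul e-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a
#' search space of `n` residues.
#'
#' @param S Raw alignment score (non-negative).
#' @param m Query length in residues.
#' @param n Search-space length in residues (for a database search, the
#'   total residue count of the database).
#' @param params A [karlin_params()] object.
#' @return The e-value (positive real; monotonically decreasing in `S`).
#' @export
evalue <- function(S, m, n, params = karlin_params()) {
  stopifnot(m > 0, n > 0, all(S >= 0))
  params$K * m * n * exp(-params$lambda * S)
}

#' Homology screen for transcription factors
#'
#' Aligns each strain protein (or each supplied candidate) against every
#' reference TF and keeps proteins whose best hit clears the e-value
#' threshold. The best hit -- maximal score, ties broken by minimal e-value
#' and then lexicographic subject id -- becomes the protein's PWM donor.
#' The e-value search space is the whole database (total residues), the
#' BLAST convention.
#'
#' @param proteome Named character vector of strain protein sequences.
#' @param tfdb Reference TF database as returned by
#'   [generate_tf_database()], or any list with a named character vector
#'   `$proteins`.
#' @param e_threshold Keep proteins with best-hit e-value strictly below
#'   this (default 0.05).
#' @param candidates Optional character vector of protein ids to restrict
#'   the screen to (a slot for an external TF predictor); `NULL` screens
#'   everything. An explicitly empty vector yields an empty result.
#' @param params A [karlin_params()] object.
#' @return A `data.frame` with one row per retained protein: `tf` (strain
#'   protein id), `donor` (reference TF id), `score`, `evalue`, `identity`.
#' @export
screen_tfs <- function(proteome, tfdb, e_threshold = 0.05,
                       candidates = NULL, params = karlin_params()) {
  ref <- tfdb$proteins
  stopifnot(length(ref) > 0, !is.null(names(ref)))
  empty <- data.frame(tf = character(), donor = character(),
                      score = numeric(), evalue = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (length(proteome) == 0L) return(empty)
  stopifnot(!is.null(names(proteome)))
  ids <- names(proteome)
  if (!is.null(candidates)) {
    ids <- intersect(ids, candidates)
    if (length(ids) == 0L) return(empty)
  }
  sub <- blosum62_matrix()
  ref_enc <- lapply(ref, encode_protein, what = "reference protein")
  ref_ids <- names(ref)
  n_db <- sum(lengths(ref_enc))
  rows <- lapply(ids, function(id) {
    q <- encode_protein(proteome[[id]], "strain protein")
    scores <- vapply(ref_enc, function(s) {
      .sw_score(q, s, sub, params$gap_open, params$gap_ext)
    }, numeric(1))
    ev <- evalue(scores, length(q), n_db, params)
    ord <- order(-scores, ev, ref_ids)
    best <- ord[1L]
    if (ev[best] >= e_threshold) return(NULL)
    aln <- .sw_align(q, ref_enc[[best]], sub, params$gap_open, params$gap_ext)
    data.frame(tf = id, donor = ref_ids[best], score = scores[best],
               evalue = ev[best], identity = aln$identity,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
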