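DNA4 <- c("A", "C", "G", "T")

#' Validate a position probability matrix
#'
#' A PWM here is a 4 x L matrix of per-position base probabilities with rows
#' named A, C, G, T; every column must sum to 1 (within 1e-9) and all
#' entries must be non-negative.
#'
#' @param pwm Matrix to validate.
#' @return The matrix, invisibly, with rows coerced to A/C/G/T order.
#' @export
validate_pwm <- function(pwm) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L, ncol(pwm) >= 1L)
  if (!is.null(rownames(pwm))) {
    stopifnot(setequal(rownames(pwm), DNA4))
    pwm <- pwm[DNA4, , drop = FALSE]
  } else {
    rownames(pwm) <- DNA4
  }
  if (any(pwm < 0)) stop("PWM entries must be non-negative")
  if (any(abs(colSums(pwm) - 1) > 1e-9)) {
    stop("every PWM column must sum to 1")
  }
  invisible(pwm)
}

#' Transfer donor PWMs to screened strain TFs
#'
#' Each strain TF that passed the homology screen receives an exact copy of
#' its donor reference TF's position weight matrix, re-labelled with the
#' strain TF's id. Two strain TFs sharing a donor receive identical
#' matrices under their own ids.
#'
#' @param screen A screen result from [screen_tfs()] (columns `tf`,
#'   `donor`).
#' @param tfdb Reference TF database with a named list `$pwms`.
#' @return Named list of PWMs, one per screened strain TF.
#' @export
transfer_pwm <- function(screen, tfdb) {
  if (nrow(screen) == 0L) return(stats::setNames(list(), character()))
  missing <- setdiff(screen$donor, names(tfdb$pwms))
  if (length(missing) > 0L) {
    stop("donor TF(s) without a PWM in the database: ",
         paste(missing, collapse = ", "))
  }
  out <- lapply(screen$donor, function(d) validate_pwm(tfdb$pwms[[d]]))
  names(out) <- screen$tf
  out
}

#' Background-corrected log-odds form of a PWM
#'
#' Entry (b, j) is `log2((p(b,j) + pc * q(b)) / ((1 + pc) * q(b)))` where
#' `q` is the background distribution and `pc` a small pseudocount that
#' keeps zero probabilities finite. With a uniform column and uniform
#' background every entry is 0 bits.
#'
#' @param pwm A position probability matrix (see [validate_pwm()]).
#' @param background Base composition (A, C, G, T); must be strictly
#'   positive and sum to 1. Default uniform.
#' @param pseudocount Non-negative pseudocount weight (default 0.01).
#' @return 4 x L matrix of log-odds scores in bits, with attribute
#'   `max_score` = sum of column maxima (the maximal attainable window
#'   score).
#' @export
pwm_log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  pwm <- validate_pwm(pwm)
  stopifnot(length(background) == 4L, pseudocount >= 0)
  if (any(background <= 0)) stop("background entries must be strictly positive")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  lom <- log2((pwm + pseudocount * background) /
                ((1 + pseudocount) * background))
  attr(lom, "max_score") <- sum(apply(lom, 2L, max))
  lom
}

# Encode a DNA string as integers 1..4 (A,C,G,T); N and any other IUPAC
# ambiguity code become 5 and score 0 at every motif position.
encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  code <- match(v, DNA4)
  code[is.na(code)] <- 5L
  code
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Score every window of length L against a log-odds matrix; returns a
# numeric vector of length G - L + 1. Vectorized over window starts.
score_windows <- function(code, lom) {
  L <- ncol(lom)
  G <- length(code)
  n_win <- G - L + 1L
  if (n_win < 1L) return(numeric(0))
  lom5 <- rbind(lom, 0)  # row 5: ambiguous base scores 0
  scores <- numeric(n_win)
  for (j in seq_len(L)) {
    scores <- scores + lom5[cbind(code[j:(j + n_win - 1L)], j)]
  }
  scores
}

#' Scan a genome for PWM binding sites (both strands)
#'
#' Exhaustively scores every window of the motif length on the forward
#' strand and on the reverse complement, and reports all windows whose
#' log-odds score reaches `threshold_frac` times the maximal attainable
#' score. Minus-strand hits are reported in plus-strand coordinates.
#' Coordinates are 0-based half-open.
#'
#' @param lom Log-odds matrix from [pwm_log_odds()] (or a list of them,
#'   named by TF id, scanned jointly).
#' @param genome Named character vector of contig sequences (or a single
#'   string, taken as contig `"contig_1"`).
#' @param threshold_frac Fraction of the maximal attainable score required
#'   to report a site (default 0.8). Lowering it never removes a site.
#' @param tf Id used in the output when `lom` is a single matrix.
#' @return `data.frame` with columns `tf`, `contig`, `start`, `end`,
#'   `strand`, `score`, sorted by (contig, start, strand, tf).
#' @export
scan_genome <- function(lom, genome, threshold_frac = 0.8, tf = "tf") {
  if (is.matrix(lom)) {
    loms <- stats::setNames(list(lom), tf)
  } else {
    loms <- lom
    stopifnot(!is.null(names(loms)))
  }
  if (is.character(genome) && is.null(names(genome))) {
    stopifnot(length(genome) == 1L)
    genome <- c(contig_1 = genome)
  }
  out <- list()
  for (contig in names(genome)) {
    fwd <- encode_dna(genome[[contig]])
    rev <- encode_dna(revcomp(genome[[contig]]))
    G <- length(fwd)
    for (id in names(loms)) {
      m <- loms[[id]]
      L <- ncol(m)
      if (L > G) next
      maxs <- attr(m, "max_score")
      if (is.null(maxs)) maxs <- sum(apply(m, 2L, max))
      thr <- threshold_frac * maxs - 1e-9  # guard float accumulation
      sf <- score_windows(fwd, m)
      sr <- score_windows(rev, m)
      hf <- which(sf >= thr)
      hr <- which(sr >= thr)
      if (length(hf) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          tf = id, contig = contig, start = hf - 1L, end = hf - 1L + L,
          strand = "+", score = sf[hf], stringsAsFactors = FALSE)
      }
      if (length(hr) > 0L) {
        # window k (1-based) on the reverse strand covers plus coordinates
        # [G - k + 1 - L, G - k + 1) in 0-based half-open terms
        st <- G - hr + 1L - L
        out[[length(out) + 1L]] <- data.frame(
          tf = id, contig = contig, start = st, end = st + L,
          strand = "-", score = sr[hr], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(tf = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand, res$tf), , drop = FALSE]
  rownames(res) <- NULL
  res
}
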