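# File formats at the pipeline boundary: FASTA via Biostrings, GFF3/BED/
# bedGraph via rtracklayer + GenomicRanges, counts and result tables as
# TSV, ground truth as JSON, PWMs as JASPAR-style 4-row text, pathways as
# GMT. Internally the package uses 0-based half-open coordinates; GFF3's
# 1-based inclusive convention is converted at this boundary.

#' Write sequences to FASTA
#' @param seqs Named character vector (DNA or protein).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand,
    type = "gene", ID = annotation$gene, Name = annotation$gene)
}

#' Write a gene annotation as GFF3
#' @param annotation Gene table (`gene`, `contig`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  rtracklayer::export(annotation_granges(annotation), path,
                      format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene annotation
#' @param path GFF3 file.
#' @return Gene table in the package's 0-based half-open convention.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene = gr$ID,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write binding sites as BED6
#' @param sites Site table from [scan_genome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  df <- data.frame(sites$contig, sites$start, sites$end, sites$tf,
                   round(sites$score, 4), sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-sample coverage as bedGraph files
#'
#' One `<prefix>.<sample>.bedGraph` per sample, 0-based half-open, with
#' equal-coverage runs merged.
#'
#' @param coverage Coverage list (`contig`, `samples`, `depth`).
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_coverage <- function(coverage, prefix) {
  paths <- vapply(coverage$samples, function(s) {
    r <- S4Vectors::Rle(coverage$depth[, s])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    df <- data.frame(coverage$contig, starts, ends,
                     S4Vectors::runValue(r))
    path <- paste0(prefix, ".", s, ".bedGraph")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Read bedGraph coverage tracks into a depth matrix
#' @param paths Named character vector of bedGraph files (names = sample
#'   ids).
#' @param length Genome length in bases; `NULL` (default) infers it from
#'   the largest end coordinate across the tracks.
#' @return Coverage list (`contig`, `samples`, `depth`).
#' @export
read_coverage <- function(paths, length = NULL) {
  stopifnot(!is.null(names(paths)))
  contig <- NULL
  tabs <- lapply(paths, function(p) {
    utils::read.table(p, sep = "\t",
                      colClasses = c("character", "integer", "integer",
                                     "numeric"),
                      stringsAsFactors = FALSE)
  })
  if (is.null(length)) {
    length <- max(vapply(tabs, function(df) max(df[[3L]]), numeric(1)))
  }
  depth <- matrix(0L, length, base::length(paths),
                  dimnames = list(NULL, names(paths)))
  for (s in names(paths)) {
    df <- tabs[[s]]
    contig <- df[[1L]][1L]
    lens <- df[[3L]] - df[[2L]]
    pos <- sequence(lens) + rep(df[[2L]], lens)  # 1-based positions
    depth[pos, s] <- rep(df[[4L]], lens)
  }
  list(contig = contig, samples = names(paths), depth = depth)
}

#' Write a counts matrix as TSV
#' @param counts Genes x samples matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV (genes x samples, first column = gene id)
#' @param path TSV file.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write PWMs in JASPAR-style 4-row text
#'
#' `>id` header followed by `A [ ... ]`, `C [ ... ]`, `G [ ... ]`,
#' `T [ ... ]` rows of per-position probabilities.
#'
#' @param pwms Named list of 4 x L probability matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  lines <- unlist(lapply(names(pwms), function(id) {
    m <- validate_pwm(pwms[[id]])
    c(paste0(">", id),
      vapply(DNA4, function(b) {
        paste0(b, " [ ", paste(sprintf("%.12g", m[b, ]),
                               collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read JASPAR-style PWMs
#' @param path File written by [write_pwms()].
#' @return Named list of 4 x L probability matrices.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- lapply(heads, function(h) {
    rows <- lapply(1:4, function(i) {
      row <- sub("^[ACGT] \\[ ", "", sub(" \\]$", "", lines[h + i]))
      as.numeric(strsplit(trimws(row), "[[:space:]]+")[[1L]])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- DNA4
    m
  })
  names(out) <- sub("^>", "", lines[heads])
  out
}

#' Read a GMT pathway file
#' @param path GMT file (`pathway<TAB>description<TAB>gene...` per line).
#' @param background Optional universe (see [pathway_db()]).
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-c(1L, 2L)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  pathway_db(sets, background)
}

#' Write a pathway database as GMT
#' @param db A [pathway_db()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  writeLines(vapply(names(db$sets), function(pw) {
    paste(c(pw, "synthetic", db$sets[[pw]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Write the synthetic ground truth as JSON
#' @param truth Truth list from [plant_sites_and_expression()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read ground truth JSON written by [write_truth()]
#' @param path JSON file.
#' @return Truth list (data frames restored column-wise).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("true_edges", "planted_sites")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.data.frame(x[[nm]])
  }
  x
}
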