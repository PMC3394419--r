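## Transcript annotation: tab-separated house dialect
## (txId geneId chrom strand exonStarts exonEnds), 0-based half-open
## exon coordinates, comma-separated. A GFF-style reader could be layered
## on top of the same constructor.

#' Construct TranscriptModels
#'
#' Exons are canonicalized (sorted by genomic start) before validation,
#' so callers may supply them in any order.
#'
#' @param txId,geneId,chrom,strand Per-transcript vectors.
#' @param exonStarts,exonEnds Lists of integer vectors, or comma-separated
#'   strings, of 0-based half-open exon coordinates.
#' @return A [TranscriptModels-class].
#' @export
TranscriptModels <- function(txId, geneId, chrom, strand,
                             exonStarts, exonEnds) {
  if (is.character(exonStarts)) exonStarts <- .splitInts(exonStarts)
  if (is.character(exonEnds)) exonEnds <- .splitInts(exonEnds)
  n <- length(txId)
  stopifnot(length(exonStarts) == n, length(exonEnds) == n)
  ss <- character(n); ee <- character(n); len <- integer(n)
  for (i in seq_len(n)) {
    s <- as.integer(exonStarts[[i]])
    e <- as.integer(exonEnds[[i]])
    if (length(s) != length(e) || !length(s)) {
      stop("transcript ", txId[i], ": malformed exon lists")
    }
    o <- order(s)
    s <- s[o]; e <- e[o]
    ss[i] <- paste(s, collapse = ",")
    ee[i] <- paste(e, collapse = ",")
    len[i] <- sum(e - s)
  }
  tx <- data.frame(
    txId = as.character(txId), geneId = rep_len(as.character(geneId), n),
    chrom = rep_len(as.character(chrom), n),
    strand = rep_len(as.character(strand), n),
    exonStarts = ss, exonEnds = ee, txLength = len,
    stringsAsFactors = FALSE
  )
  new("TranscriptModels", tx = tx)
}

#' Read a transcript annotation table
#'
#' Tab-separated columns: transcript id, gene id, chromosome, strand,
#' comma-separated exon starts, comma-separated exon ends (0-based
#' half-open). Lines starting with "#" are comments. Exon order in the
#' file is irrelevant; models are canonicalized and validated
#' (non-overlap, end > start) with errors naming the offending
#' transcript.
#'
#' @param file Path to the annotation file.
#' @return A [TranscriptModels-class].
#' @export
readTranscriptModels <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(new("TranscriptModels"))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6L)) {
    stop("annotation line with fewer than 6 fields: line ",
         which(lengths(f) < 6L)[1L])
  }
  TranscriptModels(
    txId = vapply(f, `[[`, character(1), 1L),
    geneId = vapply(f, `[[`, character(1), 2L),
    chrom = vapply(f, `[[`, character(1), 3L),
    strand = vapply(f, `[[`, character(1), 4L),
    exonStarts = vapply(f, `[[`, character(1), 5L),
    exonEnds = vapply(f, `[[`, character(1), 6L)
  )
}

#' Write a transcript annotation table
#'
#' @param x A [TranscriptModels-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeTranscriptModels <- function(x, file) {
  t <- x@tx
  lines <- paste(t$txId, t$geneId, t$chrom, t$strand, t$exonStarts,
                 t$exonEnds, sep = "\t")
  writeLines(c("#txId\tgeneId\tchrom\tstrand\texonStarts\texonEnds", lines),
             file)
  invisible(file)
}

#' Transcript length accessor
#'
#' @param x A [TranscriptModels-class].
#' @param txId Optional transcript ids to select.
#' @return Named integer vector of transcript (spliced) lengths.
#' @export
txLength <- function(x, txId = NULL) {
  t <- x@tx
  len <- setNames(t$txLength, t$txId)
  if (is.null(txId)) len else len[txId]
}

#' Exon blocks of one transcript
#'
#' @param x A [TranscriptModels-class].
#' @param txId A single transcript id.
#' @return Two-column integer matrix (start, end), 0-based half-open,
#'   sorted by genomic coordinate.
#' @export
exonBlocks <- function(x, txId) {
  i <- match(txId, x@tx$txId)
  if (is.na(i)) stop("unknown transcript: ", txId)
  cbind(start = .splitInts(x@tx$exonStarts[i])[[1]],
        end = .splitInts(x@tx$exonEnds[i])[[1]])
}
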