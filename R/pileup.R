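## Pileup construction: vertical slicing of coordinate-space alignments
## into per-locus base observations, plus the text pileup dialect.

.asReference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  stopifnot(methods::is(reference, "DNAStringSet"))
  reference
}

## Explode mapped alignments into one row per aligned base.
## Returns a data.table with rname, pos, base, qual, maskOk, laneId,
## readPos (5'->3'), readStart, strand. Ordering: input read order,
## bases sequential within read.
.explodeBases <- function(reads) {
  r <- reads[reads$status != "unmapped" & nzchar(reads$blockWidths), ,
             drop = FALSE]
  if (!nrow(r)) {
    return(data.table::data.table(
      rname = character(), pos = integer(), base = character(),
      qual = integer(), maskOk = logical(), laneId = character(),
      readPos = integer(), readStart = integer(), strand = character()
    ))
  }
  bs <- .splitInts(r$blockStarts)
  bw <- .splitInts(r$blockWidths)
  nb <- lengths(bw)
  blockStart <- unlist(bs, use.names = FALSE)
  blockWidth <- unlist(bw, use.names = FALSE)
  pos <- rep.int(blockStart, blockWidth) + sequence(blockWidth) - 1L
  readLen <- nchar(r$seq)
  refOffset <- sequence(readLen) - 1L
  idx <- rep.int(seq_len(nrow(r)), readLen)
  base <- .charsOf(r$seq)
  qual <- .phredOf(r$qual)
  maskOk <- utf8ToInt(paste(r$mask, collapse = "")) == 49L  # '1'
  strand <- r$strand[idx]
  lenRep <- readLen[idx]
  data.table::data.table(
    rname = r$rname[idx],
    pos = pos,
    base = base,
    qual = qual,
    maskOk = maskOk,
    laneId = r$laneId[idx],
    readPos = ifelse(strand == "+", refOffset, lenRep - 1L - refOffset),
    readStart = r$start[idx],
    strand = strand
  )
}

## Reference base lookup for (chrom, pos) vectors; positions outside the
## reference yield "N" with a warning.
.refBaseAt <- function(reference, chrom, pos) {
  out <- rep("N", length(chrom))
  missing <- FALSE
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (!ch %in% names(reference)) {
      missing <- TRUE
      next
    }
    chars <- strsplit(as.character(reference[[ch]]), "", fixed = TRUE)[[1]]
    p <- pos[sel]
    ok <- p >= 0L & p < length(chars)
    if (!all(ok)) missing <- TRUE
    val <- rep("N", sum(sel))
    val[ok] <- chars[p[ok] + 1L]
    out[sel] <- val
  }
  if (missing) {
    warning("reference base unavailable for some loci; using N")
  }
  out
}

#' Build a pileup from aligned reads
#'
#' Slices coordinate-sorted alignments into per-locus base observations.
#' Masked (trimmed) bases and bases with Phred quality below
#' `minBaseQuality` (default 2: quality-0 and quality-1 calls are
#' discarded) never enter the pileup. Each observation carries its base,
#' quality, lane, read offset (5' to 3') and the genomic start of its
#' source read, which is everything the genotyper and the curation
#' filters need.
#'
#' @param x An [AlignmentSet-class] in genomic coordinates.
#' @param reference A `DNAStringSet` or path to a FASTA file. Loci whose
#'   reference base is unavailable get reference "N" (with a warning) and
#'   are later skipped by the genotyper.
#' @param minBaseQuality Minimum Phred quality for an observation
#'   (default 2).
#' @return A [PileupTable-class], sorted by (chrom, pos).
#' @export
buildPileup <- function(x, reference, minBaseQuality = 2L) {
  reference <- .asReference(reference)
  b <- .explodeBases(x@reads)
  b <- b[b$maskOk & b$qual >= minBaseQuality, ]
  if (!nrow(b)) {
    return(new("PileupTable", observations = data.frame(
      chrom = character(), pos = integer(), ref = character(),
      base = character(), qual = integer(), laneId = character(),
      readPos = integer(), readStart = integer()
    )))
  }
  data.table::setorder(b, rname, pos)
  loci <- unique(b[, c("rname", "pos")])
  loci$ref <- .refBaseAt(reference, loci$rname, loci$pos)
  b <- merge(b, loci, by = c("rname", "pos"), sort = FALSE)
  obs <- data.frame(
    chrom = b$rname, pos = b$pos, ref = b$ref, base = b$base,
    qual = b$qual, laneId = b$laneId, readPos = b$readPos,
    readStart = b$readStart, stringsAsFactors = FALSE
  )
  new("PileupTable", observations = obs)
}

#' Write a pileup in the text dialect
#'
#' One line per locus: chromosome, 1-based position, reference base, then
#' one field per observation formatted
#' `base:quality:lane:readPos:readStart` with `readPos` a 0-based 5'-to-3'
#' offset and `readStart` a 1-based genomic position. Fields are
#' tab-separated.
#'
#' @param x A [PileupTable-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writePileup <- function(x, file) {
  o <- data.table::as.data.table(x@observations)
  if (!nrow(o)) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  o$fieldStr <- paste(o$base, o$qual, o$laneId, o$readPos,
                      o$readStart + 1L, sep = ":")
  grp <- o[, list(line = paste(fieldStr, collapse = "\t"),
                  ref = ref[1L]),
           by = c("chrom", "pos")]
  data.table::setorder(grp, chrom, pos)
  writeLines(paste(grp$chrom, grp$pos + 1L, grp$ref, grp$line, sep = "\t"),
             file)
  invisible(file)
}

#' Read a pileup in the text dialect
#'
#' Inverse of [writePileup()].
#'
#' @param file Path to a pileup file.
#' @return A [PileupTable-class].
#' @export
readPileup <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(new("PileupTable", observations = data.frame(
      chrom = character(), pos = integer(), ref = character(),
      base = character(), qual = integer(), laneId = character(),
      readPos = integer(), readStart = integer()
    )))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4L)) {
    stop("malformed pileup line: line ", which(lengths(f) < 4L)[1L])
  }
  nobs <- lengths(f) - 3L
  chrom <- rep.int(vapply(f, `[[`, character(1), 1L), nobs)
  pos <- rep.int(as.integer(vapply(f, `[[`, character(1), 2L)) - 1L, nobs)
  ref <- rep.int(vapply(f, `[[`, character(1), 3L), nobs)
  obsStr <- unlist(lapply(f, function(v) v[-(1:3)]), use.names = FALSE)
  parts <- strsplit(obsStr, ":", fixed = TRUE)
  if (any(lengths(parts) != 5L)) stop("malformed pileup observation field")
  obs <- data.frame(
    chrom = chrom, pos = pos, ref = ref,
    base = vapply(parts, `[[`, character(1), 1L),
    qual = as.integer(vapply(parts, `[[`, character(1), 2L)),
    laneId = vapply(parts, `[[`, character(1), 3L),
    readPos = as.integer(vapply(parts, `[[`, character(1), 4L)),
    readStart = as.integer(vapply(parts, `[[`, character(1), 5L)) - 1L,
    stringsAsFactors = FALSE
  )
  new("PileupTable", observations = obs)
}
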