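## Dual-reference merging: spliced transfer of transcript-space
## alignments to genomic coordinates, collapsing of multi-isoform hits,
## and the hard/soft decision rules combining genome-space and
## transcript-space mapping results.
##
## Decision rules (by genome status / transcript status):
##   unique/unique + agree -> keep (genome record);
##   unique/unmapped, unmapped/unique -> keep the unique side;
##   soft merge additionally keeps unique/multiple and multiple/unique
##   (the unique side); every other combination is discarded.

.MERGE_CATEGORIES <- c(
  "unique_unique_agree", "unique_unique_disagree", "unique_multiple",
  "unique_unmapped", "multiple_unique", "multiple_multiple",
  "multiple_unmapped", "unmapped_unique", "unmapped_multiple",
  "unmapped_unmapped"
)

#' Transfer transcript-space alignments to genomic coordinates
#'
#' Projects each alignment interval through its transcript's exon map,
#' splicing into multiple blocks when the interval spans exon junctions.
#' For reverse-strand transcripts the alignment strand is flipped and
#' bases/qualities/mask are reverse-complemented/reversed into genome
#' orientation. Total aligned length is preserved. Unmapped records pass
#' through unchanged.
#'
#' @param x An [AlignmentSet-class] whose `rname` values are transcript
#'   ids and coordinates are transcript-space.
#' @param models A [TranscriptModels-class].
#' @return An [AlignmentSet-class] in genomic coordinates.
#' @export
transferToGenome <- function(x, models) {
  r <- x@reads
  if (!nrow(r)) return(x)
  mapped <- which(r$status != "unmapped")
  if (!length(mapped)) return(x)
  t <- models@tx
  ti <- match(r$rname[mapped], t$txId)
  if (anyNA(ti)) {
    stop("alignment to unknown transcript: ",
         r$rname[mapped][which(is.na(ti))[1L]])
  }
  readLen <- nchar(r$seq[mapped])
  s <- r$start[mapped]
  e <- s + readLen
  L <- t$txLength[ti]
  if (any(s < 0L | e > L)) {
    bad <- which(s < 0L | e > L)[1L]
    stop("alignment interval exceeds transcript length: read ",
         r$readId[mapped][bad], " on ", r$rname[mapped][bad])
  }
  minus <- t$strand[ti] == "-"
  # map everything in forward-concatenation coordinates
  fs <- ifelse(minus, L - e, s)
  fe <- ifelse(minus, L - s, e)

  exS <- .splitInts(t$exonStarts)
  exE <- .splitInts(t$exonEnds)
  cumStart <- lapply(seq_len(nrow(t)), function(i) {
    w <- exE[[i]] - exS[[i]]
    c(0L, cumsum(w))[seq_along(w)]
  })

  n <- length(mapped)
  gStarts <- character(n)
  gWidths <- character(n)
  firstStart <- integer(n)
  for (k in seq_len(n)) {
    i <- ti[k]
    cs <- cumStart[[i]]
    es <- exS[[i]]
    ee <- exE[[i]]
    j1 <- findInterval(fs[k], cs)
    j2 <- findInterval(fe[k] - 1L, cs)
    jj <- j1:j2
    txA <- pmax(fs[k], cs[jj])
    txB <- pmin(fe[k], cs[jj] + (ee[jj] - es[jj]))
    gs <- es[jj] + (txA - cs[jj])
    gStarts[k] <- paste(gs, collapse = ",")
    gWidths[k] <- paste(txB - txA, collapse = ",")
    firstStart[k] <- gs[1L]
  }

  out <- r
  out$rname[mapped] <- t$chrom[ti]
  out$start[mapped] <- firstStart
  out$blockStarts[mapped] <- gStarts
  out$blockWidths[mapped] <- gWidths
  flip <- mapped[minus]
  if (length(flip)) {
    out$seq[flip] <- .revCompStrings(out$seq[flip])
    out$qual[flip] <- .revStrings(out$qual[flip])
    out$mask[flip] <- .revStrings(out$mask[flip])
    out$strand[flip] <- ifelse(out$strand[flip] == "+", "-", "+")
  }
  new("AlignmentSet", reads = out, metadata = x@metadata)
}

## location signature used for isoform collapsing: chromosome + strand +
## identical block structure
.locationSignature <- function(reads) {
  paste(reads$rname, reads$strand, reads$blockStarts, reads$blockWidths,
        sep = "|")
}

#' Collapse multi-isoform hits of one read
#'
#' A read aligned to several transcripts of the same gene transfers to
#' the same genomic location; such multi-hits are not true ambiguity. If
#' all
#' genomic alignments of the read share chromosome, strand and identical
#' block structure, one of them is kept as unique; otherwise the read is
#' genuinely multi-mapped.
#'
#' @param reads data.frame of genomic-coordinate alignment records, all
#'   for the same read.
#' @return list with `status` ("unique" or "multiple") and `alignment`
#'   (a one-row data.frame, or NULL when multiple).
#' @export
collapseIsoformHits <- function(reads) {
  if (!nrow(reads)) stop("empty alignment list")
  if (length(unique(reads$readId)) != 1L) {
    stop("collapseIsoformHits expects alignments of a single read")
  }
  sig <- .locationSignature(reads)
  if (length(unique(sig)) == 1L) {
    aln <- reads[1L, , drop = FALSE]
    aln$status <- "unique"
    list(status = "unique", alignment = aln)
  } else {
    list(status = "multiple", alignment = NULL)
  }
}

#' Do two genomic alignments agree?
#'
#' Agreement = same chromosome, same strand and same leftmost genomic
#' position (strict equality; block structures may legitimately differ).
#'
#' @param a,b One-row data.frames (or lists) with rname, strand, start.
#' @return TRUE or FALSE.
#' @export
alignmentsAgree <- function(a, b) {
  isTRUE(a$rname == b$rname && a$strand == b$strand && a$start == b$start)
}

#' Merge decision for one read
#'
#' Pure decision function over the (genome status, transcript status,
#' agreement) triple. Hard merging keeps dual-unique agreeing reads and
#' one-sided unique reads with the other side unmapped; soft merging
#' additionally keeps one-sided unique reads with the other side
#' multi-mapped. When both sides are unique and agree the genome
#' alignment is kept; otherwise the unique side is kept.
#'
#' @param genomeStatus,transcriptStatus "unique"/"multiple"/"unmapped".
#' @param agree Logical; only consulted for the unique/unique case.
#' @param mode "hard" or "soft".
#' @return "keep_genome", "keep_transcript" or "throw".
#' @export
mergeDecision <- function(genomeStatus, transcriptStatus, agree = NA,
                          mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  stopifnot(genomeStatus %in% c("unique", "multiple", "unmapped"),
            transcriptStatus %in% c("unique", "multiple", "unmapped"))
  if (genomeStatus == "unique" && transcriptStatus == "unique") {
    return(if (isTRUE(agree)) "keep_genome" else "throw")
  }
  if (genomeStatus == "unique" && transcriptStatus == "unmapped") {
    return("keep_genome")
  }
  if (genomeStatus == "unmapped" && transcriptStatus == "unique") {
    return("keep_transcript")
  }
  if (mode == "soft") {
    if (genomeStatus == "unique" && transcriptStatus == "multiple") {
      return("keep_genome")
    }
    if (genomeStatus == "multiple" && transcriptStatus == "unique") {
      return("keep_transcript")
    }
  }
  "throw"
}

## Classify one side's records per read: returns a data.table with
## readId, status and (for unique reads) the row index of the
## representative record in `reads`.
.classifySide <- function(reads, collapse = FALSE) {
  dt <- data.table::data.table(
    row = seq_len(nrow(reads)),
    readId = reads$readId,
    status = reads$status,
    sig = .locationSignature(reads)
  )
  per <- dt[, {
    mappedRows <- row[status != "unmapped"]
    if (!length(mappedRows)) {
      list(status = "unmapped", row = NA_integer_)
    } else if (length(mappedRows) == 1L) {
      st <- status[status != "unmapped"][1L]
      list(status = if (st == "multiple") "multiple" else "unique",
           row = if (st == "multiple") NA_integer_ else mappedRows)
    } else if (collapse &&
               length(unique(sig[status != "unmapped"])) == 1L) {
      list(status = "unique", row = mappedRows[1L])
    } else {
      list(status = "multiple", row = NA_integer_)
    }
  }, by = "readId"]
  per
}

#' Merge genome-space and transcript-space alignments
#'
#' Full merging pipeline for one read set: transcript alignments are
#' transferred to genomic coordinates and isoform hits collapsed, each
#' read is classified on both sides (a read absent from one input is
#' unmapped on that side), the hard/soft decision rules are applied, and
#' the kept alignments are returned coordinate-sorted. Per-category
#' counts for all ten decision rows are recorded in the result's
#' metadata (`mergeCounts()`).
#'
#' @param genomeAln [AlignmentSet-class] of genome-space alignments.
#' @param transcriptAln [AlignmentSet-class] of transcript-space
#'   alignments.
#' @param models [TranscriptModels-class] for the spliced transfer.
#' @param mode "hard" or "soft".
#' @return An [AlignmentSet-class] of kept reads (status "unique"),
#'   sorted by chromosome and position, with metadata `mergeCounts` and
#'   `mode`.
#' @export
mergeAlignments <- function(genomeAln, transcriptAln, models,
                            mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  txGenomic <- transferToGenome(transcriptAln, models)
  g <- .classifySide(genomeAln@reads, collapse = FALSE)
  t <- .classifySide(txGenomic@reads, collapse = TRUE)
  data.table::setnames(g, c("status", "row"), c("gStatus", "gRow"))
  data.table::setnames(t, c("status", "row"), c("tStatus", "tRow"))
  pair <- merge(g, t, by = "readId", all = TRUE)
  pair$gStatus[is.na(pair$gStatus)] <- "unmapped"
  pair$tStatus[is.na(pair$tStatus)] <- "unmapped"

  gr <- genomeAln@reads
  tr <- txGenomic@reads
  uu <- pair$gStatus == "unique" & pair$tStatus == "unique"
  agree <- rep(NA, nrow(pair))
  if (any(uu)) {
    agree[uu] <- gr$rname[pair$gRow[uu]] == tr$rname[pair$tRow[uu]] &
      gr$strand[pair$gRow[uu]] == tr$strand[pair$tRow[uu]] &
      gr$start[pair$gRow[uu]] == tr$start[pair$tRow[uu]]
  }
  category <- paste(pair$gStatus, pair$tStatus, sep = "_")
  category[uu & agree %in% TRUE] <- "unique_unique_agree"
  category[uu & agree %in% FALSE] <- "unique_unique_disagree"
  counts <- setNames(integer(length(.MERGE_CATEGORIES)),
                     .MERGE_CATEGORIES)
  tab <- table(category)
  counts[names(tab)] <- as.integer(tab)

  keepGenome <- category == "unique_unique_agree" |
    category == "unique_unmapped" |
    (mode == "soft" & category == "unique_multiple")
  keepTx <- category == "unmapped_unique" |
    (mode == "soft" & category == "multiple_unique")

  kept <- rbind(gr[pair$gRow[keepGenome], , drop = FALSE],
                tr[pair$tRow[keepTx], , drop = FALSE])
  if (nrow(kept)) kept$status <- "unique"
  out <- new("AlignmentSet", reads = kept,
             metadata = list(mergeCounts = counts, mode = mode))
  sortAlignments(out)
}

#' Per-category merge counts
#'
#' @param x An [AlignmentSet-class] produced by [mergeAlignments()].
#' @return Named integer vector over the ten decision categories.
#' @export
mergeCounts <- function(x) {
  x@metadata$mergeCounts
}
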