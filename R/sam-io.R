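## SAM text input/output for the minimal dialect the toolkit uses
## (single-end records; QNAME FLAG RNAME POS CIGAR SEQ QUAL + NH/XT/RG/XU
## tags). Coordinates convert between SAM 1-based and internal 0-based
## half-open at this boundary.

#' Construct an AlignmentSet
#'
#' Builds an [AlignmentSet-class] from per-record vectors. `blockStarts`
#' and `blockWidths` are comma-separated 0-based block descriptors;
#' `mask` defaults to all-usable.
#'
#' @param readId,laneId,rname,strand,start,blockStarts,blockWidths,seq,qual,mask,status
#'   Per-record vectors, recycled where scalar. See [AlignmentSet-class].
#' @param metadata Optional metadata list.
#' @return An [AlignmentSet-class].
#' @export
AlignmentSet <- function(readId = character(), laneId = "lane1",
                         rname = NA_character_, strand = NA_character_,
                         start = NA_integer_, blockStarts = "",
                         blockWidths = "", seq = "", qual = "",
                         mask = NULL, status = "unique",
                         metadata = list()) {
  n <- length(readId)
  if (is.null(mask)) mask <- strrep("1", nchar(seq))
  reads <- data.frame(
    readId = readId,
    laneId = rep_len(as.character(laneId), n),
    rname = rep_len(as.character(rname), n),
    strand = rep_len(as.character(strand), n),
    start = rep_len(as.integer(start), n),
    blockStarts = rep_len(as.character(blockStarts), n),
    blockWidths = rep_len(as.character(blockWidths), n),
    seq = rep_len(as.character(seq), n),
    qual = rep_len(as.character(qual), n),
    mask = rep_len(as.character(mask), n),
    status = rep_len(as.character(status), n),
    stringsAsFactors = FALSE
  )
  new("AlignmentSet", reads = reads, metadata = metadata)
}

## Parse CIGAR strings into aligned-block descriptors relative to a
## 0-based alignment start. Returns blockStarts/blockWidths strings plus,
## for each record, the indices of SEQ bases that are reference-aligned
## (M/=/X); soft-clipped and inserted bases are excluded so that total
## block width always equals the retained read length.
.parseCigar <- function(cigar, start0) {
  n <- length(cigar)
  blockStarts <- character(n)
  blockWidths <- character(n)
  keep <- vector("list", n)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  for (k in seq_len(n)) {
    tk <- toks[[k]]
    if (!length(tk) || sum(nchar(tk)) != nchar(cigar[k])) {
      stop("malformed CIGAR: ", cigar[k])
    }
    len <- as.integer(substr(tk, 1L, nchar(tk) - 1L))
    op <- substr(tk, nchar(tk), nchar(tk))
    refPos <- start0[k]
    readPos <- 0L
    bs <- integer(0); bw <- integer(0); kp <- integer(0)
    open <- FALSE
    for (j in seq_along(op)) {
      L <- len[j]
      switch(op[j],
        "M" = , "=" = , "X" = {
          if (open && bs[length(bs)] + bw[length(bw)] == refPos) {
            bw[length(bw)] <- bw[length(bw)] + L
          } else {
            bs <- c(bs, refPos); bw <- c(bw, L)
          }
          kp <- c(kp, seq.int(readPos + 1L, readPos + L))
          refPos <- refPos + L
          readPos <- readPos + L
          open <- TRUE
        },
        "I" = { readPos <- readPos + L },
        "S" = { readPos <- readPos + L },
        "D" = { refPos <- refPos + L; open <- FALSE },
        "N" = { refPos <- refPos + L; open <- FALSE },
        "H" = NULL, "P" = NULL
      )
    }
    blockStarts[k] <- paste(bs, collapse = ",")
    blockWidths[k] <- paste(bw, collapse = ",")
    keep[[k]] <- kp
  }
  list(blockStarts = blockStarts, blockWidths = blockWidths, keep = keep)
}

## Inverse: blocks -> CIGAR (M segments separated by N gaps).
.blocksToCigar <- function(blockStarts, blockWidths) {
  ss <- .splitInts(blockStarts)
  ww <- .splitInts(blockWidths)
  mapply(function(s, w) {
    if (!length(s)) return("*")
    parts <- paste0(w, "M")
    if (length(s) > 1L) {
      gaps <- s[-1L] - (s + w)[-length(s)]
      parts <- c(parts[1L], paste0(gaps, "N", parts[-1L]))
    }
    paste(parts, collapse = "")
  }, ss, ww)
}

.extractTag <- function(tagFields, tag) {
  prefix <- paste0(tag, ":")
  vapply(tagFields, function(f) {
    hit <- f[startsWith(f, prefix)]
    if (length(hit)) sub("^[A-Za-z0-9]+:[AifZHB]:", "", hit[1]) else
      NA_character_
  }, character(1))
}

#' Read a SAM file into an AlignmentSet
#'
#' Parses the fields the toolkit uses (QNAME, FLAG, RNAME, POS, CIGAR,
#' SEQ, QUAL and the NH/XT/RG/XU optional tags). Soft-clipped and
#' inserted bases are dropped so every retained base is
#' reference-aligned. Mapping status is "unmapped" for flag-0x4 records,
#' "multiple" for records with NH > 1, XT:A:R, or a read id occurring on
#' more than one record, and "unique" otherwise.
#'
#' @param file Path to a SAM file (or a character vector of SAM lines).
#' @param laneId Lane label for every record. When `NULL`, the RG tag is
#'   used where present, else "lane1" (per-file label takes priority over
#'   read groups).
#' @param qualityOffset ASCII offset of the quality encoding: 33
#'   (Sanger/modern Illumina, default) or 64 (Illumina 1.3-1.7 era).
#'   Qualities are stored internally at +33.
#' @return An [AlignmentSet-class].
#' @export
readSAM <- function(file, laneId = NULL, qualityOffset = 33L) {
  if (!qualityOffset %in% c(33L, 64L)) {
    stop("unknown quality encoding offset: ", qualityOffset,
         " (expected 33 or 64)")
  }
  lines <- if (length(file) == 1L && file.exists(file)) {
    readLines(file)
  } else {
    as.character(file)
  }
  lineNo <- seq_along(lines)
  rec <- !startsWith(lines, "@") & nzchar(lines)
  lines <- lines[rec]
  lineNo <- lineNo[rec]
  if (!length(lines)) {
    return(AlignmentSet(metadata = list(source = "sam")))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1L]
    stop("malformed SAM record at line ", lineNo[bad],
         ": expected >= 11 fields, found ", nf[bad])
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  qname <- getf(1L)
  flag <- suppressWarnings(as.integer(getf(2L)))
  if (anyNA(flag)) {
    bad <- which(is.na(flag))[1L]
    stop("malformed SAM record at line ", lineNo[bad], ": bad FLAG")
  }
  rname <- getf(3L)
  pos1 <- suppressWarnings(as.integer(getf(4L)))
  cigar <- getf(6L)
  seq <- toupper(getf(10L))
  qual <- getf(11L)
  tagFields <- lapply(fields, function(f) if (length(f) > 11L) f[-(1:11)]
                      else character(0))

  unmapped <- bitwAnd(flag, 4L) > 0L | rname == "*" | cigar == "*"
  minus <- bitwAnd(flag, 16L) > 0L

  # quality decoding sanity + internal +33 re-encoding
  qchars <- utf8ToInt(paste(qual[qual != "*"], collapse = ""))
  if (length(qchars) && any(qchars < qualityOffset)) {
    stop("quality characters below the configured encoding offset (",
         qualityOffset, "); wrong --quality-offset?")
  }
  if (qualityOffset != 33L) {
    qual <- vapply(qual, function(q) {
      if (q == "*") return(q)
      intToUtf8(utf8ToInt(q) - (qualityOffset - 33L))
    }, character(1), USE.NAMES = FALSE)
  }
  qual[qual == "*"] <- ""
  seq[seq == "*"] <- ""

  blockStarts <- character(length(lines))
  blockWidths <- character(length(lines))
  mseq <- seq
  mqual <- qual
  mapIdx <- which(!unmapped)
  if (length(mapIdx)) {
    if (anyNA(pos1[mapIdx]) || any(pos1[mapIdx] < 1L)) {
      bad <- mapIdx[which(is.na(pos1[mapIdx]) | pos1[mapIdx] < 1L)[1L]]
      stop("malformed SAM record at line ", lineNo[bad], ": bad POS")
    }
    parsed <- .parseCigar(cigar[mapIdx], pos1[mapIdx] - 1L)
    blockStarts[mapIdx] <- parsed$blockStarts
    blockWidths[mapIdx] <- parsed$blockWidths
    for (j in seq_along(mapIdx)) {
      i <- mapIdx[j]
      kp <- parsed$keep[[j]]
      if (length(kp) != nchar(seq[i])) {
        ch <- strsplit(seq[i], "", fixed = TRUE)[[1]]
        qh <- strsplit(qual[i], "", fixed = TRUE)[[1]]
        if (length(ch) < max(kp, 0L)) {
          stop("malformed SAM record at line ", lineNo[i],
               ": SEQ shorter than CIGAR implies")
        }
        mseq[i] <- paste(ch[kp], collapse = "")
        mqual[i] <- paste(qh[kp], collapse = "")
      }
    }
  }

  nh <- suppressWarnings(as.integer(.extractTag(tagFields, "NH")))
  xt <- .extractTag(tagFields, "XT")
  rg <- .extractTag(tagFields, "RG")
  xu <- .extractTag(tagFields, "XU")

  status <- rep("unique", length(lines))
  status[!is.na(nh) & nh > 1L] <- "multiple"
  status[!is.na(xt) & xt == "R"] <- "multiple"
  dup <- qname %in% qname[duplicated(qname)]
  status[dup] <- "multiple"
  status[unmapped] <- "unmapped"

  lane <- if (!is.null(laneId)) rep(as.character(laneId), length(lines)) else
    ifelse(is.na(rg), "lane1", rg)

  mask <- ifelse(is.na(xu), strrep("1", nchar(mseq)), xu)
  badMask <- nchar(mask) != nchar(mseq)
  mask[badMask] <- strrep("1", nchar(mseq[badMask]))

  reads <- data.frame(
    readId = qname, laneId = lane,
    rname = ifelse(unmapped, NA_character_, rname),
    strand = ifelse(unmapped, NA_character_, ifelse(minus, "-", "+")),
    start = ifelse(unmapped, NA_integer_, pos1 - 1L),
    blockStarts = blockStarts, blockWidths = blockWidths,
    seq = mseq, qual = mqual, mask = mask, status = status,
    stringsAsFactors = FALSE
  )
  new("AlignmentSet", reads = reads, metadata = list(source = "sam"))
}

#' Sort alignments by chromosome and position
#'
#' Mapped records are ordered by (reference name, start, read id);
#' unmapped records go last.
#'
#' @param x An [AlignmentSet-class].
#' @return A sorted [AlignmentSet-class].
#' @export
sortAlignments <- function(x) {
  r <- x@reads
  if (!nrow(r)) return(x)
  o <- order(is.na(r$rname), r$rname, r$start, r$readId, method = "radix")
  x@reads <- r[o, , drop = FALSE]
  rownames(x@reads) <- NULL
  x
}

#' Write an AlignmentSet to a SAM file
#'
#' Input must already be sorted by chromosome and position (use
#' [sortAlignments()]); an unsorted input is an error naming the first
#' out-of-order record. Blocks are rendered as M segments separated by N
#' gaps; lane ids become RG tags, "multiple" status an NH:i:2 tag, and a
#' non-trivial trimming mask an XU:Z tag, so that a round trip through
#' [readSAM()] preserves blocks, bases, qualities, status and mask.
#'
#' @param x An [AlignmentSet-class], coordinate-sorted.
#' @param file Output path (or connection).
#' @return Invisibly, the file path.
#' @export
writeSAM <- function(x, file) {
  r <- x@reads
  mapped <- r[r$status != "unmapped", , drop = FALSE]
  if (nrow(mapped) > 1L) {
    prevName <- mapped$rname[-nrow(mapped)]
    curName <- mapped$rname[-1L]
    outOfOrder <- curName < prevName |
      (curName == prevName & mapped$start[-1L] < mapped$start[-nrow(mapped)])
    if (any(outOfOrder)) {
      bad <- which(outOfOrder)[1L] + 1L
      stop("alignments not sorted by chromosome and position; first ",
           "out-of-order record: ", mapped$readId[bad])
    }
  }
  header <- "@HD\tVN:1.6\tSO:coordinate"
  if (nrow(mapped)) {
    ends <- vapply(seq_len(nrow(mapped)), function(i) {
      s <- .splitInts(mapped$blockStarts[i])[[1]]
      w <- .splitInts(mapped$blockWidths[i])[[1]]
      max(s + w)
    }, integer(1))
    sq <- tapply(ends, mapped$rname, max)
    header <- c(header,
                paste0("@SQ\tSN:", names(sq), "\tLN:", as.integer(sq)))
  }
  lanes <- unique(r$laneId)
  header <- c(header, paste0("@RG\tID:", lanes))
  if (!nrow(r)) {
    writeLines(header, file)
    return(invisible(file))
  }
  unmapped <- r$status == "unmapped"
  flag <- ifelse(unmapped, 4L, ifelse(r$strand == "-", 16L, 0L))
  cig <- rep("*", nrow(r))
  cig[!unmapped] <- .blocksToCigar(r$blockStarts[!unmapped],
                                   r$blockWidths[!unmapped])
  tags <- paste0("RG:Z:", r$laneId)
  mult <- r$status == "multiple"
  tags[mult] <- paste0(tags[mult], "\tNH:i:2")
  masked <- grepl("0", r$mask, fixed = TRUE)
  tags[masked] <- paste0(tags[masked], "\tXU:Z:", r$mask[masked])
  lines <- paste(
    r$readId, flag,
    ifelse(unmapped, "*", r$rname),
    ifelse(unmapped, 0L, r$start + 1L),
    ifelse(unmapped, 0L, 255L), cig, "*", 0L, 0L,
    ifelse(nzchar(r$seq), r$seq, "*"),
    ifelse(nzchar(r$qual), r$qual, "*"),
    tags, sep = "\t"
  )
  writeLines(c(header, lines), file)
  invisible(file)
}
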