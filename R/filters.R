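## Data-curation strategies: aligned-read trimming, start-locus read
## caps, lane-support and minimum allele-count call vetoes, and the
## per-cycle mismatch diagnostic.

#' Trim aligned reads by masking cycle extremes
#'
#' Masks the first `trimLeading` and last `trimTrailing` bases of every
#' mapped read, counted in read orientation (5' to 3', i.e. in
#' sequencing-cycle order), so that 3'-end de-phasing errors stop feeding
#' the genotyper. Alignment coordinates and blocks are unchanged:
#' trimming aligned reads rather than raw reads keeps the (correctly
#' sampled) trimmed bases available for placing the read. The defaults
#' (1, 10) discard 11 of 33 bases of a 33 bp read.
#'
#' @param x An [AlignmentSet-class].
#' @param trimLeading Number of 5'-end bases to mask (default 1).
#' @param trimTrailing Number of 3'-end bases to mask (default 10).
#' @return An [AlignmentSet-class] with updated masks. Reads whose whole
#'   length is masked trigger a warning.
#' @export
trimAlignments <- function(x, trimLeading = 1L, trimTrailing = 10L) {
  stopifnot(trimLeading >= 0L, trimTrailing >= 0L)
  if (trimLeading == 0L && trimTrailing == 0L) return(x)
  r <- x@reads
  mapped <- which(r$status != "unmapped")
  if (!length(mapped)) return(x)
  L <- nchar(r$seq[mapped])
  plus <- r$strand[mapped] == "+"
  # usable window [a, b] in storage (reference-orientation) coordinates;
  # for reverse-strand reads the 5' end sits at the genomic right.
  a <- ifelse(plus, trimLeading + 1L, trimTrailing + 1L)
  b <- ifelse(plus, L - trimTrailing, L - trimLeading)
  full <- a > b
  if (any(full)) {
    warning(sum(full), " read(s) fully masked by trimming")
  }
  old <- r$mask[mapped]
  newMask <- ifelse(full, strrep("0", L),
                    paste0(strrep("0", a - 1L),
                           substr(old, pmin(a, L), pmax(b, 0L)),
                           strrep("0", L - b)))
  r$mask[mapped] <- newMask
  new("AlignmentSet", reads = r, metadata = x@metadata)
}

#' Cap the number of reads per start locus
#'
#' Retains at most `maxPerStart` reads per (chromosome, start position,
#' strand) key, suppressing PCR amplification artifacts and flattening
#' coverage spikes from highly expressed transcripts. The retained reads
#' are the `maxPerStart` with the highest mean base quality, ties broken
#' by read id, so the outcome is independent of input ordering. Unmapped
#' records pass through.
#'
#' @param x An [AlignmentSet-class].
#' @param maxPerStart Positive integer cap, or `Inf`/`NULL` to disable.
#' @return A coordinate-sorted [AlignmentSet-class].
#' @export
startLocusFilter <- function(x, maxPerStart) {
  if (is.null(maxPerStart) || is.infinite(maxPerStart)) {
    return(sortAlignments(x))
  }
  stopifnot(maxPerStart >= 1L)
  r <- x@reads
  mapped <- r$status != "unmapped"
  m <- r[mapped, , drop = FALSE]
  if (!nrow(m)) return(sortAlignments(x))
  L <- nchar(m$qual)
  q <- .phredOf(m$qual)
  meanQual <- as.numeric(rowsum(q, rep.int(seq_len(nrow(m)), L))) / L
  dt <- data.table::data.table(
    row = seq_len(nrow(m)), rname = m$rname, start = m$start,
    strand = m$strand, meanQual = meanQual, readId = m$readId
  )
  data.table::setorder(dt, rname, start, strand, -meanQual, readId)
  dt[, rank := seq_len(.N), by = c("rname", "start", "strand")]
  keep <- sort(dt$row[dt$rank <= maxPerStart])
  out <- rbind(m[keep, , drop = FALSE],
               r[!mapped, , drop = FALSE])
  sortAlignments(new("AlignmentSet", reads = out, metadata = x@metadata))
}

## distinct-lane and observation counts of a given base at given loci
.alleleSupport <- function(pileup, chrom, pos, base) {
  o <- data.table::as.data.table(pileup@observations)
  want <- data.table::data.table(chrom = chrom, pos = pos, base = base,
                                 id = seq_along(chrom))
  hit <- merge(want, o, by = c("chrom", "pos", "base"),
               allow.cartesian = TRUE)
  if (!nrow(hit)) {
    return(data.frame(id = seq_along(chrom),
                      nLanes = 0L, nObs = 0L))
  }
  sup <- hit[, list(nLanes = length(unique(laneId)), nObs = .N),
             by = "id"]
  out <- merge(data.table::data.table(id = seq_along(chrom)), sup,
               by = "id", all.x = TRUE)
  out$nLanes[is.na(out$nLanes)] <- 0L
  out$nObs[is.na(out$nObs)] <- 0L
  as.data.frame(out)
}

.filterVariantCalls <- function(x, pileup, predicate) {
  cl <- x@calls
  if (!nrow(cl)) return(x)
  var <- which(cl$isVariant)
  if (!length(var)) return(x)
  a1 <- substr(cl$genotype[var], 1L, 1L)
  a2 <- substr(cl$genotype[var], 2L, 2L)
  altList <- mapply(function(r, x1, x2) setdiff(unique(c(x1, x2)), r),
                    cl$ref[var], a1, a2, SIMPLIFY = FALSE)
  nAlt <- lengths(altList)
  chrom <- rep.int(cl$chrom[var], nAlt)
  pos <- rep.int(cl$pos[var], nAlt)
  base <- unlist(altList, use.names = FALSE)
  sup <- .alleleSupport(pileup, chrom, pos, base)
  ok <- predicate(sup)
  keepVar <- as.logical(tapply(ok, rep.int(seq_along(var), nAlt), all))
  drop <- var[!keepVar]
  if (length(drop)) {
    cl <- cl[-drop, , drop = FALSE]
    rownames(cl) <- NULL
  }
  new("GenotypeCalls", calls = cl, h = x@h)
}

#' Lane-support filter on variant calls
#'
#' Vetoes a variant call unless every called non-reference allele is
#' observed in at least `minLanes` distinct lanes. Applied after
#' genotyping as a call-level veto; homozygous-reference calls always
#' pass.
#'
#' @param x A [GenotypeCalls-class].
#' @param pileup The [PileupTable-class] the calls were made from.
#' @param minLanes Required number of distinct supporting lanes, or
#'   `NULL`/0 to disable.
#' @return A filtered [GenotypeCalls-class].
#' @export
laneSupportFilter <- function(x, pileup, minLanes) {
  if (is.null(minLanes) || minLanes <= 0L) return(x)
  .filterVariantCalls(x, pileup, function(sup) sup$nLanes >= minLanes)
}

#' Minimum allele-count filter on variant calls
#'
#' Vetoes a variant call unless every called non-reference allele has at
#' least `minAltObservations` supporting observations, regardless of
#' lane.
#'
#' @param x A [GenotypeCalls-class].
#' @param pileup The [PileupTable-class] the calls were made from.
#' @param minAltObservations Required observation count, or `NULL`/0 to
#'   disable.
#' @return A filtered [GenotypeCalls-class].
#' @export
minAltCountFilter <- function(x, pileup, minAltObservations) {
  if (is.null(minAltObservations) || minAltObservations <= 0L) return(x)
  .filterVariantCalls(x, pileup,
                      function(sup) sup$nObs >= minAltObservations)
}

#' Per-cycle mismatch profile
#'
#' For each read offset (5' to 3'), the fraction of aligned reads whose
#' base at that offset mismatches the reference. In the absence of
#' systematic error the profile is flat; a rise toward the 3' end is the
#' de-phasing signature that motivates aligned-read trimming. The
#' diagnostic precedes trimming, so masked bases are included.
#'
#' @param x An [AlignmentSet-class] in genomic coordinates.
#' @param reference A `DNAStringSet` or FASTA path.
#' @return A [MismatchProfile-class].
#' @export
mismatchProfile <- function(x, reference) {
  reference <- .asReference(reference)
  b <- .explodeBases(x@reads)
  if (!nrow(b)) {
    return(new("MismatchProfile", fraction = numeric(0),
               counts = integer(0)))
  }
  b$ref <- .refBaseAt(reference, b$rname, b$pos)
  maxLen <- max(b$readPos) + 1L
  mm <- b$base != b$ref
  counts <- tabulate(b$readPos + 1L, nbins = maxLen)
  mmCounts <- tabulate((b$readPos + 1L)[mm], nbins = maxLen)
  frac <- ifelse(counts > 0L, mmCounts / counts, 0)
  new("MismatchProfile", fraction = frac, counts = as.integer(counts))
}

#' Mismatch profile as a data.frame
#'
#' @param x A [MismatchProfile-class].
#' @return data.frame with cycle (1-based), mismatchFraction, reads.
#' @export
profileTable <- function(x) {
  data.frame(cycle = seq_along(x@fraction),
             mismatchFraction = x@fraction,
             reads = x@counts)
}
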