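## Accuracy framework: detection vs genotyping TP/FP classification
## against a gold standard, threshold sweep curves, per-exon coverage and
## coverage-binned accuracy.
##
## Genotyping: a true positive is a correctly called heterozygous or
## homozygous non-reference variant; a false positive is a call asserting
## an allele the gold genotype does not carry; a heterozygous gold locus
## called homozygous-within-gold, or not called, is neutral (possibly
## just lack of coverage of one allele). Detection: a true positive is
## any variant call at a non-reference gold locus regardless of the exact
## genotype; a false positive is a variant call at a homozygous-reference
## gold locus.

#' Classify one call against the gold standard (genotyping mode)
#'
#' @param gold Gold genotype (two-letter string).
#' @param call Called genotype, or `NA` when the locus was not called.
#' @param ref Reference base at the locus.
#' @return "true_positive", "false_positive" or "neutral".
#' @export
classifyGenotypingCall <- function(gold, call, ref) {
  gold <- canonicalGenotype(gold)
  refref <- paste0(ref, ref)
  if (is.na(call)) return("neutral")
  call <- canonicalGenotype(call)
  if (call == gold && gold != refref) return("true_positive")
  goldAlleles <- genotypeAlleles(gold)
  callAlleles <- genotypeAlleles(call)
  if (length(setdiff(callAlleles, goldAlleles))) return("false_positive")
  "neutral"
}

#' Classify one call against the gold standard (detection mode)
#'
#' @param gold Gold genotype.
#' @param call Called genotype or `NA`.
#' @param ref Reference base.
#' @return "true_positive", "false_positive" or "neutral".
#' @export
classifyDetectionCall <- function(gold, call, ref) {
  gold <- canonicalGenotype(gold)
  refref <- paste0(ref, ref)
  isVariantCall <- !is.na(call) && canonicalGenotype(call) != refref
  if (gold != refref) {
    if (isVariantCall) return("true_positive")
    return("neutral")
  }
  if (isVariantCall) return("false_positive")
  "neutral"
}

## reference bases for a set of gold loci, from a DNAStringSet/path
.goldWithRef <- function(gold, reference) {
  if (!"ref" %in% names(gold)) {
    reference <- .asReference(reference)
    gold$ref <- .refBaseAt(reference, gold$chrom, gold$pos)
  }
  gold
}

#' Evaluate calls against a gold standard
#'
#' Joins calls to gold-standard loci and classifies every gold locus as
#' true positive, false positive or neutral under the chosen mode.
#' Classification is defined only at gold loci; calls elsewhere are
#' ignored here.
#'
#' @param x A [GenotypeCalls-class].
#' @param gold data.frame with chrom, pos (0-based), genotype, and
#'   optionally ref; see [readGoldStandard()].
#' @param reference `DNAStringSet` or FASTA path (used when `gold` lacks
#'   a ref column).
#' @param mode "genotyping" or "detection".
#' @return data.frame of gold loci with call, ref and status columns;
#'   attribute "counts" holds the TP/FP/neutral totals.
#' @export
evaluateCalls <- function(x, gold, reference = NULL,
                          mode = c("genotyping", "detection")) {
  mode <- match.arg(mode)
  gold <- .goldWithRef(gold, reference)
  cl <- x@calls
  key <- function(c, p) paste(c, p, sep = "\r")
  idx <- match(key(gold$chrom, gold$pos), key(cl$chrom, cl$pos))
  gold$call <- ifelse(is.na(idx), NA_character_, cl$genotype[idx])
  classify <- if (mode == "genotyping") classifyGenotypingCall else
    classifyDetectionCall
  gold$status <- vapply(seq_len(nrow(gold)), function(i) {
    classify(gold$genotype[i], gold$call[i], gold$ref[i])
  }, character(1))
  counts <- c(
    true_positive = sum(gold$status == "true_positive"),
    false_positive = sum(gold$status == "false_positive"),
    neutral = sum(gold$status == "neutral")
  )
  attr(gold, "counts") <- counts
  gold
}

#' Sensitivity/specificity sweep curve
#'
#' Recomputes TP and FP counts while sweeping the minimum variant
#' posterior required to keep a call. Both counts are non-increasing in
#' the threshold.
#'
#' @param x A [GenotypeCalls-class].
#' @param gold Gold-standard data.frame (chrom, pos, genotype, optional
#'   ref).
#' @param reference `DNAStringSet` or FASTA path.
#' @param thresholds Ascending numeric vector of variant-posterior
#'   thresholds.
#' @param mode "genotyping" or "detection".
#' @return data.frame with threshold, truePositives, falsePositives.
#' @export
accuracyCurve <- function(x, gold, reference = NULL,
                          thresholds = seq(0, 0.99, by = 0.01),
                          mode = c("genotyping", "detection")) {
  mode <- match.arg(mode)
  if (is.null(gold) || !nrow(gold)) stop("empty gold standard")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  gold <- .goldWithRef(gold, reference)
  out <- lapply(thresholds, function(th) {
    keep <- x@calls$variantPosterior >= th
    sub <- new("GenotypeCalls",
               calls = x@calls[keep, , drop = FALSE], h = x@h)
    cnt <- attr(evaluateCalls(sub, gold, mode = mode), "counts")
    data.frame(threshold = th,
               truePositives = unname(cnt["true_positive"]),
               falsePositives = unname(cnt["false_positive"]))
  })
  do.call(rbind, out)
}

#' Average per-exon coverage
#'
#' Average coverage of an exon = (aligned bases overlapping the exon) /
#' (exon length), computed over the aligned blocks of the reads.
#'
#' @param x An [AlignmentSet-class] in genomic coordinates.
#' @param models A [TranscriptModels-class] (each transcript's exons are
#'   evaluated) or a data.frame with exonId, chrom, start, end.
#' @return data.frame with exonId, txId, chrom, start, end,
#'   averageCoverage.
#' @export
exonCoverage <- function(x, models) {
  if (methods::is(models, "TranscriptModels")) {
    t <- models@tx
    ss <- .splitInts(t$exonStarts)
    ee <- .splitInts(t$exonEnds)
    nEx <- lengths(ss)
    exons <- data.frame(
      exonId = paste0(rep.int(t$txId, nEx), ":",
                      unlist(lapply(nEx, seq_len))),
      txId = rep.int(t$txId, nEx),
      chrom = rep.int(t$chrom, nEx),
      start = unlist(ss, use.names = FALSE),
      end = unlist(ee, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  } else {
    exons <- models
    if (!"txId" %in% names(exons)) exons$txId <- NA_character_
  }
  if (any(exons$end <= exons$start)) stop("zero-length exon")
  r <- x@reads[x@reads$status != "unmapped", , drop = FALSE]
  exons$averageCoverage <- 0
  if (nrow(r)) {
    bs <- .splitInts(r$blockStarts)
    bw <- .splitInts(r$blockWidths)
    nb <- lengths(bw)
    blocks <- GenomicRanges::GRanges(
      seqnames = rep.int(r$rname, nb),
      ranges = IRanges::IRanges(
        start = unlist(bs, use.names = FALSE) + 1L,
        width = unlist(bw, use.names = FALSE))
    )
    exGR <- GenomicRanges::GRanges(
      seqnames = exons$chrom,
      ranges = IRanges::IRanges(start = exons$start + 1L,
                                end = exons$end)
    )
    ov <- GenomicRanges::findOverlaps(blocks, exGR)
    if (length(ov)) {
      q <- blocks[S4Vectors::queryHits(ov)]
      s <- exGR[S4Vectors::subjectHits(ov)]
      w <- pmin(GenomicRanges::end(q), GenomicRanges::end(s)) -
        pmax(GenomicRanges::start(q), GenomicRanges::start(s)) + 1L
      basesPerExon <- rowsum(as.numeric(w), S4Vectors::subjectHits(ov))
      i <- as.integer(rownames(basesPerExon))
      exons$averageCoverage[i] <-
        basesPerExon[, 1L] / (exons$end[i] - exons$start[i])
    }
  }
  exons
}

#' Convert RPKM to average per-base coverage
#'
#' Average exon coverage = RPKM x totalMappedReads x readLength x 1e-9
#' (reads per kilobase of exon per million mapped reads, times read
#' length, with the kilo and million factors folded into 1e-9).
#'
#' @param rpkm Numeric RPKM value(s).
#' @param totalMappedReads Total mapped reads in the dataset.
#' @param readLength Read length in bp.
#' @return Numeric average coverage.
#' @export
rpkmToCoverage <- function(rpkm, totalMappedReads, readLength) {
  rpkm * totalMappedReads * readLength * 1e-9
}

#' Coverage-binned accuracy
#'
#' Groups gold-standard loci by the average coverage of the exon
#' containing them (first containing exon in sorted order; loci in no
#' exon fall into an "unassigned" bin) and reports per-bin percentages of
#' true positives, false positives and false negatives. False negatives
#' are gold variant loci that were not correctly genotyped (uncalled or
#' miscalled). TP and FN percentages are relative to the gold variant
#' loci of the bin; FP percentage is relative to all gold loci of the
#' bin.
#'
#' @param x A [GenotypeCalls-class].
#' @param gold Gold-standard data.frame (chrom, pos, genotype, optional
#'   ref).
#' @param reference `DNAStringSet` or FASTA path.
#' @param exonCov data.frame from [exonCoverage()].
#' @param binEdges Ascending numeric vector of coverage bin edges.
#' @return data.frame with bin, nGold, nGoldVariant, tpPct, fpPct,
#'   fnPct.
#' @export
coverageBinnedAccuracy <- function(x, gold, reference = NULL, exonCov,
                                   binEdges) {
  if (is.unsorted(binEdges, strictly = TRUE)) {
    stop("binEdges must be strictly ascending")
  }
  gold <- .goldWithRef(gold, reference)
  ev <- evaluateCalls(x, gold, mode = "genotyping")
  # first containing exon in sorted order
  eo <- exonCov[order(exonCov$chrom, exonCov$start, exonCov$end), ,
                drop = FALSE]
  cov <- rep(NA_real_, nrow(ev))
  for (ch in unique(ev$chrom)) {
    gi <- which(ev$chrom == ch)
    ei <- which(eo$chrom == ch)
    if (!length(ei)) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(start = ev$pos[gi] + 1L, width = 1L),
      IRanges::IRanges(start = eo$start[ei] + 1L, end = eo$end[ei]),
      select = "first"
    )
    cov[gi] <- eo$averageCoverage[ei][hit]
  }
  lab <- c(paste0("[", head(binEdges, -1), ",", binEdges[-1], ")"))
  bin <- as.character(cut(cov, binEdges, labels = lab, right = FALSE))
  bin[is.na(bin) & !is.na(cov)] <- "out_of_range"
  bin[is.na(cov)] <- "unassigned"
  levels <- c(lab, "out_of_range", "unassigned")
  res <- lapply(levels, function(b) {
    sel <- bin == b
    nGold <- sum(sel)
    nVar <- sum(sel & ev$genotype != paste0(ev$ref, ev$ref))
    tp <- sum(sel & ev$status == "true_positive")
    fp <- sum(sel & ev$status == "false_positive")
    fn <- nVar - tp
    data.frame(
      bin = b, nGold = nGold, nGoldVariant = nVar,
      tpPct = if (nVar) 100 * tp / nVar else 0,
      fpPct = if (nGold) 100 * fp / nGold else 0,
      fnPct = if (nVar) 100 * fn / nVar else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out[out$nGold > 0L | out$bin %in% lab, , drop = FALSE]
}
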