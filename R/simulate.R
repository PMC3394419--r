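## Deterministic RNA-Seq read simulator: diploid genomes with planted
## SNVs, multi-exon transcripts with uneven expression, per-cycle
## quality/error structure, lanes, PCR duplicates and pooling — so that
## merging, genotyping, curation and evaluation can all be exercised
## end to end without external data.

#' Construct a SimulationConfig
#'
#' See [SimulationConfig-class] for the meaning of every field. Defaults
#' emulate a 33 bp, 7-lane Illumina transcriptome run with planted
#' heterozygosity 0.001.
#'
#' @param seed Integer seed (mandatory).
#' @param genomeLength,nTranscripts,exonsPerTranscript,exonLength,intronLength
#'   Genome/annotation geometry; the three range arguments are
#'   length-2 (min, max) integer vectors.
#' @param hetRate,homAltFraction Planted variant rates.
#' @param expressionSdLog sdlog of lognormal expression weights (0 =
#'   even per-base coverage).
#' @param readLength,readsPerLane,nLanes Read sampling geometry.
#' @param perCycleQuality Reported Phred per cycle (recycled).
#' @param perCycleTrueError True per-cycle error rate; NA = use the
#'   Phred-implied rate of the reported quality.
#' @param duplicateRate Probability a read emits one PCR-duplicate copy.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(seed,
                             genomeLength = 200000L,
                             nTranscripts = 20L,
                             exonsPerTranscript = c(1L, 10L),
                             exonLength = c(100L, 300L),
                             intronLength = c(50L, 500L),
                             hetRate = 0.001,
                             homAltFraction = 1 / 3,
                             expressionSdLog = 1,
                             readLength = 33L,
                             readsPerLane = 10000L,
                             nLanes = 7L,
                             perCycleQuality = 30L,
                             perCycleTrueError = NA_real_,
                             duplicateRate = 0) {
  new("SimulationConfig",
      seed = as.integer(seed),
      genomeLength = as.integer(genomeLength),
      nTranscripts = as.integer(nTranscripts),
      exonsPerTranscript = as.integer(rep_len(exonsPerTranscript, 2L)),
      exonLength = as.integer(rep_len(exonLength, 2L)),
      intronLength = as.integer(rep_len(intronLength, 2L)),
      hetRate = hetRate,
      homAltFraction = homAltFraction,
      expressionSdLog = expressionSdLog,
      readLength = as.integer(readLength),
      readsPerLane = as.integer(readsPerLane),
      nLanes = as.integer(nLanes),
      perCycleQuality = as.integer(rep_len(perCycleQuality, readLength)),
      perCycleTrueError = as.numeric(rep_len(perCycleTrueError,
                                             readLength)),
      duplicateRate = duplicateRate)
}

.runifInt <- function(n, lo, hi) {
  if (lo == hi) rep.int(as.integer(lo), n) else
    as.integer(lo + floor(runif(n) * (hi - lo + 1L)))
}

#' Simulate a genome and transcript annotation
#'
#' Generates one random chromosome and packs non-overlapping genes onto
#' it left to right, each with 1-10 exons (configurable) on a random
#' strand, separated by random intergenic gaps.
#'
#' @param config A [SimulationConfig-class].
#' @return list with `genome` (DNAStringSet, one chromosome "chr1") and
#'   `models` ([TranscriptModels-class]).
#' @export
simulateGenomeAndTranscripts <- function(config) {
  set.seed(config@seed)
  genomeStr <- paste(sample(.BASES, config@genomeLength, replace = TRUE),
                     collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(genomeStr, "chr1"))
  n <- config@nTranscripts
  exonStarts <- vector("list", n)
  exonEnds <- vector("list", n)
  strand <- character(n)
  cursor <- 200L
  for (i in seq_len(n)) {
    nEx <- .runifInt(1L, config@exonsPerTranscript[1L],
                     config@exonsPerTranscript[2L])
    exLen <- .runifInt(nEx, config@exonLength[1L], config@exonLength[2L])
    inLen <- if (nEx > 1L) {
      .runifInt(nEx - 1L, config@intronLength[1L],
                config@intronLength[2L])
    } else integer(0)
    span <- sum(exLen) + sum(inLen)
    if (cursor + span + 200L > config@genomeLength) {
      stop("cannot pack ", n, " transcripts into ", config@genomeLength,
           " bp; increase genomeLength")
    }
    s <- cursor + c(0L, cumsum(exLen[-nEx] + inLen))
    exonStarts[[i]] <- s
    exonEnds[[i]] <- s + exLen
    strand[i] <- sample(c("+", "-"), 1L)
    cursor <- cursor + span + .runifInt(1L, 200L, 500L)
  }
  ids <- sprintf("tx%04d", seq_len(n))
  models <- TranscriptModels(
    txId = ids, geneId = sub("^tx", "g", ids), chrom = "chr1",
    strand = strand, exonStarts = exonStarts, exonEnds = exonEnds
  )
  list(genome = genome, models = models)
}

## union of exonic positions (0-based) per chromosome
.exonicPositions <- function(models) {
  t <- models@tx
  out <- list()
  for (ch in unique(t$chrom)) {
    sel <- t$chrom == ch
    ss <- unlist(.splitInts(t$exonStarts[sel]), use.names = FALSE)
    ee <- unlist(.splitInts(t$exonEnds[sel]), use.names = FALSE)
    ir <- IRanges::reduce(IRanges::IRanges(start = ss + 1L, end = ee))
    w <- IRanges::width(ir)
    out[[ch]] <- rep.int(IRanges::start(ir), w) + sequence(w) - 2L
  }
  out
}

#' Plant variants into exons
#'
#' Every exonic site independently becomes a variant with probability
#' `hetRate`; a fraction `homAltFraction` of planted variants are
#' homozygous non-reference, the rest heterozygous with the alternative
#' allele assigned to a random haplotype. Planted genotypes never equal
#' homozygous reference.
#'
#' @param genome DNAStringSet.
#' @param models [TranscriptModels-class] (variants restricted to the
#'   exon union).
#' @param hetRate Per-site variant probability (0 <= h < 0.1).
#' @param homAltFraction Fraction of variants that are homozygous
#'   non-reference.
#' @param seed Integer seed.
#' @return A [TruthSet-class].
#' @export
plantVariants <- function(genome, models, hetRate = 0.001,
                          homAltFraction = 1 / 3, seed) {
  stopifnot(hetRate >= 0, hetRate < 0.1)
  set.seed(seed)
  emptyTruth <- new("TruthSet", variants = data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), genotype = character(), zygosity = character(),
    phase = integer(), stringsAsFactors = FALSE))
  if (hetRate == 0) return(emptyTruth)
  byChrom <- .exonicPositions(models)
  out <- lapply(names(byChrom), function(ch) {
    pos <- byChrom[[ch]]
    hit <- pos[runif(length(pos)) < hetRate]
    if (!length(hit)) return(NULL)
    chars <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    ref <- chars[hit + 1L]
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    hom <- runif(length(hit)) < homAltFraction
    genotype <- ifelse(hom, paste0(alt, alt),
                       canonicalGenotype(paste0(ref, alt)))
    data.frame(
      chrom = ch, pos = hit, ref = ref, alt = alt, genotype = genotype,
      zygosity = ifelse(hom, "hom", "het"),
      phase = ifelse(hom, 0L, sample(1:2, length(hit), replace = TRUE)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(emptyTruth)
  rownames(out) <- NULL
  new("TruthSet", variants = out)
}

## Spliced transcript sequence (transcript orientation) from the genome.
.transcriptSequence <- function(genome, models, txId) {
  t <- models@tx
  i <- match(txId, t$txId)
  ss <- .splitInts(t$exonStarts[i])[[1]]
  ee <- .splitInts(t$exonEnds[i])[[1]]
  parts <- substring(as.character(genome[[t$chrom[i]]]), ss + 1L, ee)
  s <- paste(parts, collapse = "")
  if (t$strand[i] == "-") s <- .revCompStrings(s)
  s
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Two haplotype sequences per transcript, in transcript orientation,
## with planted variants applied. Returns character vector of length
## 2 * nTx: hap1 of tx1, hap2 of tx1, hap1 of tx2, ...
.haplotypeSequences <- function(genome, models, truth) {
  t <- models@tx
  v <- truth@variants
  out <- character(2L * nrow(t))
  for (i in seq_len(nrow(t))) {
    base <- .transcriptSequence(genome, models, t$txId[i])
    h1 <- base; h2 <- base
    ss <- .splitInts(t$exonStarts[i])[[1]]
    ee <- .splitInts(t$exonEnds[i])[[1]]
    cum <- c(0L, cumsum(ee - ss))
    L <- t$txLength[i]
    vv <- v[v$chrom == t$chrom[i], , drop = FALSE]
    if (nrow(vv)) {
      ex <- findInterval(vv$pos, ss)
      inEx <- ex >= 1L & vv$pos < ee[pmax(ex, 1L)]
      vv <- vv[inEx, , drop = FALSE]
      ex <- ex[inEx]
      if (nrow(vv)) {
        txPos <- cum[ex] + (vv$pos - ss[ex])  # forward-concatenation
        altTx <- vv$alt
        if (t$strand[i] == "-") {
          txPos <- L - 1L - txPos
          altTx <- unname(.COMP[altTx])
        }
        for (k in seq_len(nrow(vv))) {
          p <- txPos[k] + 1L
          if (vv$phase[k] %in% c(0L, 1L)) {
            substr(h1, p, p) <- altTx[k]
          }
          if (vv$phase[k] %in% c(0L, 2L)) {
            substr(h2, p, p) <- altTx[k]
          }
        }
      }
    }
    out[2L * i - 1L] <- h1
    out[2L * i] <- h2
  }
  out
}

## Vectorized projection of transcript intervals [s, s+L) to genomic
## block strings. Returns list(blockStarts, blockWidths, firstStart).
.intervalsToGenomicBlocks <- function(models, txIdx, s, width) {
  t <- models@tx
  ss <- .splitInts(t$exonStarts)
  ee <- .splitInts(t$exonEnds)
  nEx <- lengths(ss)
  exTx <- rep.int(seq_len(nrow(t)), nEx)
  exGStart <- unlist(ss, use.names = FALSE)
  exW <- unlist(ee, use.names = FALSE) - exGStart
  exCum <- unlist(lapply(seq_len(nrow(t)), function(i) {
    w <- ee[[i]] - ss[[i]]
    c(0L, cumsum(w))[seq_along(w)]
  }), use.names = FALSE)
  # forward-concatenation coords; reverse-strand handled by caller
  BIG <- max(t$txLength) + 1L
  off <- (seq_len(nrow(t)) - 1L) * BIG
  bounds <- off[exTx] + exCum
  gs0 <- off[txIdx] + s
  ge0 <- gs0 + width
  j1 <- findInterval(gs0, bounds)
  j2 <- findInterval(ge0 - 1L, bounds)
  nb <- j2 - j1 + 1L
  exRow <- sequence(nb, from = j1)
  rdRow <- rep.int(seq_along(txIdx), nb)
  cumA <- pmax(gs0[rdRow], bounds[exRow])
  cumB <- pmin(ge0[rdRow], bounds[exRow] + exW[exRow])
  g <- exGStart[exRow] + (cumA - bounds[exRow])
  w <- cumB - cumA
  one <- nb == 1L
  blockStarts <- character(length(txIdx))
  blockWidths <- character(length(txIdx))
  firstIdx <- cumsum(c(1L, nb[-length(nb)]))
  blockStarts[one] <- as.character(g[firstIdx[one]])
  blockWidths[one] <- as.character(w[firstIdx[one]])
  if (any(!one)) {
    multi <- which(!one)
    dt <- data.table::data.table(rd = rdRow, g = g, w = w)
    dt <- dt[rd %in% multi]
    agg <- dt[, list(bs = paste(g, collapse = ","),
                     bw = paste(w, collapse = ",")), by = "rd"]
    blockStarts[agg$rd] <- agg$bs
    blockWidths[agg$rd] <- agg$bw
  }
  list(blockStarts = blockStarts, blockWidths = blockWidths,
       firstStart = g[firstIdx])
}

#' Sample sequencing reads from transcripts
#'
#' Draws reads from the two transcript haplotypes: the source transcript
#' is chosen proportionally to expression weights (lognormal with
#' `expressionSdLog`, scaled by the number of start positions so that
#' `expressionSdLog = 0` gives even per-base coverage), the start
#' position uniformly, and the haplotype uniformly. Sequencing errors
#' are injected per cycle at the true per-cycle error rate, each error
#' replacing the base with one of the other three uniformly; the
#' reported quality string is the configured per-cycle profile. PCR
#' duplicates are exact copies (same alignment and bases) under fresh
#' read ids. Reads are returned with their truth alignments in both
#' transcript coordinates and spliced genomic coordinates.
#'
#' @param genome DNAStringSet.
#' @param models [TranscriptModels-class].
#' @param truth [TruthSet-class] of planted variants.
#' @param config [SimulationConfig-class].
#' @param seed Integer seed (defaults to `config@seed + 2`).
#' @return list with `genomeReads` and `transcriptReads`
#'   ([AlignmentSet-class]), plus `expressionWeights`.
#' @export
sampleReads <- function(genome, models, truth, config,
                        seed = config@seed + 2L) {
  set.seed(seed)
  t <- models@tx
  L <- config@readLength
  nTx <- nrow(t)
  slots <- t$txLength - L + 1L
  if (any(slots < 1L)) {
    stop("transcript(s) shorter than the read length")
  }
  wExpr <- if (config@expressionSdLog > 0) {
    rlnorm(nTx, meanlog = 0, sdlog = config@expressionSdLog)
  } else rep(1, nTx)
  w <- wExpr * slots
  if (all(w == 0)) stop("all transcripts have zero expression")
  n <- config@readsPerLane * config@nLanes
  txIdx <- sample.int(nTx, n, replace = TRUE, prob = w)
  start <- as.integer(floor(runif(n) * slots[txIdx]))
  hap <- sample.int(2L, n, replace = TRUE)

  hapSeqs <- .haplotypeSequences(genome, models, truth)
  readSeq <- substring(hapSeqs[2L * (txIdx - 1L) + hap], start + 1L,
                       start + L)

  # per-cycle error injection
  q <- config@perCycleQuality
  e <- ifelse(is.na(config@perCycleTrueError), 10^(-q / 10),
              config@perCycleTrueError)
  big <- utf8ToInt(paste(readSeq, collapse = ""))
  cyc <- rep.int(seq_len(L), n)
  err <- runif(n * L) < e[cyc]
  if (any(err)) {
    cur <- match(big[err], utf8ToInt(paste(.BASES, collapse = "")))
    shift <- sample.int(3L, sum(err), replace = TRUE)
    big[err] <- utf8ToInt(paste(.BASES, collapse = ""))[
      ((cur - 1L + shift) %% 4L) + 1L]
  }
  bigStr <- intToUtf8(big)
  readSeq <- substring(bigStr, (seq_len(n) - 1L) * L + 1L,
                       seq_len(n) * L)

  lane <- paste0("L", rep(seq_len(config@nLanes),
                          each = config@readsPerLane))
  readId <- paste0("r", seq_len(n))

  # PCR duplicates: exact copies, fresh ids, same lane
  if (config@duplicateRate > 0) {
    dup <- which(runif(n) < config@duplicateRate)
    if (length(dup)) {
      txIdx <- c(txIdx, txIdx[dup])
      start <- c(start, start[dup])
      hap <- c(hap, hap[dup])
      readSeq <- c(readSeq, readSeq[dup])
      lane <- c(lane, lane[dup])
      readId <- c(readId, paste0(readId[dup], "dup"))
      n <- length(readId)
    }
  }

  qStr <- intToUtf8(q + 33L)
  qualFwd <- rep(qStr, n)

  transcriptReads <- AlignmentSet(
    readId = readId, laneId = lane, rname = t$txId[txIdx], strand = "+",
    start = start, blockStarts = as.character(start),
    blockWidths = as.character(L), seq = readSeq, qual = qualFwd,
    status = "unique"
  )

  # genomic truth alignments: reverse-strand transcripts flip everything
  minus <- t$strand[txIdx] == "-"
  fs <- ifelse(minus, t$txLength[txIdx] - (start + L), start)
  blocks <- .intervalsToGenomicBlocks(models, txIdx, fs, L)
  gSeq <- readSeq
  gQual <- qualFwd
  if (any(minus)) {
    gSeq[minus] <- .revCompStrings(readSeq[minus])
    gQual[minus] <- .revStrings(qualFwd[minus])
  }
  genomeReads <- AlignmentSet(
    readId = readId, laneId = lane, rname = t$chrom[txIdx],
    strand = ifelse(minus, "-", "+"), start = blocks$firstStart,
    blockStarts = blocks$blockStarts, blockWidths = blocks$blockWidths,
    seq = gSeq, qual = gQual, status = "unique"
  )

  list(genomeReads = genomeReads, transcriptReads = transcriptReads,
       expressionWeights = setNames(w / sum(w), t$txId))
}

#' Simulate a complete dataset
#'
#' Orchestrates [simulateGenomeAndTranscripts()], [plantVariants()] and
#' [sampleReads()] under seeds derived from the config seed, and bundles
#' the results. Fully deterministic for a fixed config.
#'
#' @param config A [SimulationConfig-class].
#' @return A [SimulatedDataset-class].
#' @export
simulateDataset <- function(config) {
  gt <- simulateGenomeAndTranscripts(config)
  truth <- plantVariants(gt$genome, gt$models, hetRate = config@hetRate,
                         homAltFraction = config@homAltFraction,
                         seed = config@seed + 1L)
  reads <- sampleReads(gt$genome, gt$models, truth, config)
  new("SimulatedDataset",
      genome = gt$genome, models = gt$models, truth = truth,
      genomeReads = reads$genomeReads,
      transcriptReads = reads$transcriptReads,
      config = config)
}

#' Pool reads from several simulated individuals
#'
#' Concatenates the read sets of `k` individuals simulated on the same
#' genome and annotation, tagging reads and lanes with their individual
#' of origin, and returns the union truth table (one row per planted
#' variant per individual). With a single individual the reads pass
#' through untouched.
#'
#' @param datasets list of [SimulatedDataset-class] objects sharing
#'   genome and models.
#' @return list with `genomeReads` (pooled [AlignmentSet-class]),
#'   `truth` (data.frame with an `individual` column) and `unionLoci`
#'   (data.frame of distinct variant loci).
#' @export
poolIndividuals <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  g1 <- as.character(datasets[[1L]]@genome)
  for (d in datasets[-1L]) {
    if (!identical(as.character(d@genome), g1)) {
      stop("individuals were simulated on different references")
    }
  }
  if (length(datasets) == 1L) {
    truth <- datasets[[1L]]@truth@variants
    truth$individual <- "ind1"
    return(list(genomeReads = datasets[[1L]]@genomeReads, truth = truth,
                unionLoci = unique(truth[, c("chrom", "pos", "ref")])))
  }
  readsList <- lapply(seq_along(datasets), function(i) {
    r <- datasets[[i]]@genomeReads@reads
    r$readId <- paste0("ind", i, ".", r$readId)
    r$laneId <- paste0("ind", i, ".", r$laneId)
    r
  })
  truthList <- lapply(seq_along(datasets), function(i) {
    v <- datasets[[i]]@truth@variants
    if (nrow(v)) v$individual <- paste0("ind", i)
    v
  })
  truth <- do.call(rbind, truthList)
  pooled <- new("AlignmentSet", reads = do.call(rbind, readsList),
                metadata = list(pooledFrom = length(datasets)))
  list(genomeReads = pooled, truth = truth,
       unionLoci = unique(truth[, c("chrom", "pos", "ref")]))
}

#' Perturb mapping statuses
#'
#' Randomly downgrades a fraction of records to "multiple" or "unmapped"
#' (clearing coordinates for unmapped ones). Used to fabricate all the
#' decision-table categories when exercising the merging rules on
#' simulated data.
#'
#' @param x An [AlignmentSet-class].
#' @param fractionMultiple,fractionUnmapped Perturbation fractions.
#' @param seed Integer seed.
#' @return An [AlignmentSet-class].
#' @export
perturbMappingStatus <- function(x, fractionMultiple = 0.1,
                                 fractionUnmapped = 0.1, seed) {
  set.seed(seed)
  r <- x@reads
  u <- runif(nrow(r))
  toMult <- u < fractionMultiple
  toUnm <- u >= fractionMultiple & u < fractionMultiple + fractionUnmapped
  r$status[toMult] <- "multiple"
  r$status[toUnm] <- "unmapped"
  r$rname[toUnm] <- NA_character_
  r$strand[toUnm] <- NA_character_
  r$start[toUnm] <- NA_integer_
  r$blockStarts[toUnm] <- ""
  r$blockWidths[toUnm] <- ""
  new("AlignmentSet", reads = r, metadata = x@metadata)
}

#' Write reads as FASTQ
#'
#' Writes reads in sequencing (5' to 3') orientation; pass the
#' transcript-space read set of a simulation, whose records are stored
#' in read orientation.
#'
#' @param x An [AlignmentSet-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeFASTQ <- function(x, file) {
  r <- x@reads
  lines <- rbind(paste0("@", r$readId), r$seq, "+", r$qual)
  writeLines(as.vector(lines), file)
  invisible(file)
}
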