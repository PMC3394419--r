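# Shared fixture builders and independent oracles. Everything is built
# in code; no binary fixtures.

# deterministic pseudo-random DNA string
randomDNA <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

samRecord <- function(qname, flag, rname, pos1, cigar, seq,
                      qual = strrep("I", nchar(seq)), tags = character()) {
  paste(c(qname, flag, rname, pos1, 255L, cigar, "*", 0L, 0L, seq, qual,
          tags), collapse = "\t")
}

unmappedRecord <- function(qname, seq = "ACGTACGTAC",
                           qual = strrep("I", nchar(seq))) {
  paste(qname, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, seq, qual, sep = "\t")
}

# Independent brute-force posterior oracle: direct enumeration of
# prior x product over observations, normalized over the ten genotypes.
# Deliberately plain arithmetic, no log space, no package helpers.
bruteForcePosterior <- function(bases, quals, h = 0.001, epsMax = 0.75) {
  gts <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
  eps <- pmin(10^(-quals / 10), epsMax)
  unnorm <- sapply(gts, function(g) {
    a1 <- substr(g, 1, 1)
    a2 <- substr(g, 2, 2)
    prior <- if (a1 == a2) (1 - h) / 4 else h / 6
    lik <- 1
    for (i in seq_along(bases)) {
      r <- bases[i]
      e <- eps[i]
      p <- if (a1 == a2) {
        if (r == a1) 1 - e else e / 3
      } else {
        if (r == a1 || r == a2) 1 / 2 - e / 3 else e / 3
      }
      lik <- lik * p
    }
    prior * lik
  })
  unnorm / sum(unnorm)
}

# Build a PileupTable directly from observation vectors (single locus
# unless chrom/pos given per observation).
makePileup <- function(base, qual, chrom = "chr1", pos = 100L,
                       ref = "A", laneId = "L1", readPos = 0L,
                       readStart = pos) {
  n <- length(base)
  new("PileupTable", observations = data.frame(
    chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n), base = base,
    qual = rep_len(as.integer(qual), n),
    laneId = rep_len(laneId, n), readPos = rep_len(as.integer(readPos), n),
    readStart = rep_len(as.integer(readStart), n),
    stringsAsFactors = FALSE
  ))
}

# Two-transcript annotation used by merge fixtures:
#   tx1: chr1:+ exon [500, 800)
#   tx2: chr1:+ exon [3000, 3300)
mergeFixtureModels <- function() {
  TranscriptModels(
    txId = c("tx1", "tx2"), geneId = c("g1", "g2"), chrom = "chr1",
    strand = "+", exonStarts = list(500L, 3000L),
    exonEnds = list(800L, 3300L)
  )
}

# Ten-read fixture covering every decision-table row, as parallel
# genome-space and transcript-space SAM line vectors. One read per row:
#   r01 unique/unique agree        r06 multiple/multiple
#   r02 unique/unique disagree     r07 multiple/unmapped
#   r03 unique/multiple            r08 unmapped/unique
#   r04 unique/unmapped            r09 unmapped/multiple
#   r05 multiple/unique            r10 unmapped/unmapped
mergeFixtureSams <- function() {
  s <- strrep("ACGTA", 6) # 30 bp
  genome <- c(
    "@HD\tVN:1.6",
    samRecord("r01", 0L, "chr1", 501L, "30M", s),
    samRecord("r02", 0L, "chr1", 1001L, "30M", s),
    samRecord("r03", 0L, "chr1", 2001L, "30M", s),
    samRecord("r04", 0L, "chr1", 2501L, "30M", s),
    samRecord("r05", 0L, "chr1", 601L, "30M", s),
    samRecord("r05", 0L, "chr1", 4001L, "30M", s),
    samRecord("r06", 0L, "chr1", 701L, "30M", s),
    samRecord("r06", 0L, "chr1", 4101L, "30M", s),
    samRecord("r07", 0L, "chr1", 801L, "30M", s),
    samRecord("r07", 0L, "chr1", 4201L, "30M", s),
    unmappedRecord("r08", s),
    unmappedRecord("r09", s),
    unmappedRecord("r10", s)
  )
  transcript <- c(
    "@HD\tVN:1.6",
    samRecord("r01", 0L, "tx1", 1L, "30M", s),    # -> chr1:500, agrees
    samRecord("r02", 0L, "tx1", 101L, "30M", s),  # -> chr1:600, disagrees
    samRecord("r03", 0L, "tx1", 11L, "30M", s),   # two genomic locations
    samRecord("r03", 0L, "tx2", 11L, "30M", s),   #   -> multiple
    unmappedRecord("r04", s),
    samRecord("r05", 0L, "tx1", 21L, "30M", s),   # -> chr1:520, unique
    samRecord("r06", 0L, "tx1", 31L, "30M", s),
    samRecord("r06", 0L, "tx2", 31L, "30M", s),
    unmappedRecord("r07", s),
    samRecord("r08", 0L, "tx1", 41L, "30M", s),   # -> chr1:540, unique
    samRecord("r09", 0L, "tx1", 51L, "30M", s),
    samRecord("r09", 0L, "tx2", 51L, "30M", s),
    unmappedRecord("r10", s)
  )
  list(genome = genome, transcript = transcript)
}

# Independent inverse exon map: map a genomic position back to the
# forward-concatenation transcript coordinate by scanning exons.
inverseMapPosition <- function(gpos, exonStarts, exonEnds) {
  cum <- 0L
  for (j in seq_along(exonStarts)) {
    if (gpos >= exonStarts[j] && gpos < exonEnds[j]) {
      return(cum + (gpos - exonStarts[j]))
    }
    cum <- cum + (exonEnds[j] - exonStarts[j])
  }
  NA_integer_
}

# small simulated dataset reused across test files; ... overrides the
# base configuration
smallSimulation <- function(seed = 42L, ...) {
  args <- list(seed = seed, genomeLength = 100000L, nTranscripts = 10L,
               exonsPerTranscript = c(2L, 5L), exonLength = c(150L, 300L),
               readsPerLane = 2000L, nLanes = 4L, hetRate = 0.003,
               expressionSdLog = 0)
  args <- utils::modifyList(args, list(...))
  simulateDataset(do.call(simulationConfig, args))
}

lociKey <- function(chrom, pos) paste(chrom, pos, sep = ":")
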