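## S4 class definitions and validity methods.

setOldClass("data.table")

#' AlignmentSet: a set of aligned reads
#'
#' Container for single-end read alignments in either genome or transcript
#' coordinate space. Alignments are stored as a flat table, one row per
#' alignment record (a multi-mapping read may occupy several rows):
#' \describe{
#'   \item{readId}{read name}
#'   \item{laneId}{sequencing lane label (batch identity used by
#'     replicate-support filters)}
#'   \item{rname}{reference sequence name (chromosome or transcript id);
#'     \code{NA} for unmapped records}
#'   \item{strand}{"+" or "-"; \code{NA} for unmapped records}
#'   \item{start}{leftmost reference position, 0-based}
#'   \item{blockStarts, blockWidths}{comma-separated 0-based starts and
#'     widths of the aligned blocks (a spliced alignment has >1 block)}
#'   \item{seq, qual, mask}{aligned bases in reference orientation, their
#'     Phred qualities (ASCII, +33), and a per-base "1"/"0" usable flag
#'     (all "1" until trimming masks bases)}
#'   \item{status}{"unique", "multiple" or "unmapped"}
#' }
#' All coordinates are 0-based half-open internally; SAM input/output
#' converts at the boundary.
#'
#' @slot reads data.frame as described above.
#' @slot metadata list of free-form metadata (e.g. per-category merge
#'   counts for merged sets).
#' @export
setClass("AlignmentSet",
  representation(reads = "data.frame", metadata = "list"),
  prototype(reads = data.frame(), metadata = list())
)

.ALN_COLS <- c("readId", "laneId", "rname", "strand", "start",
               "blockStarts", "blockWidths", "seq", "qual", "mask", "status")

setValidity("AlignmentSet", function(object) {
  r <- object@reads
  if (nrow(r) == 0L) return(TRUE)
  missing <- setdiff(.ALN_COLS, names(r))
  if (length(missing)) {
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (!all(r$status %in% c("unique", "multiple", "unmapped"))) {
    return("status must be unique/multiple/unmapped")
  }
  mapped <- r$status != "unmapped"
  if (any(mapped)) {
    widths <- .splitInts(r$blockWidths[mapped])
    total <- vapply(widths, sum, integer(1))
    n <- nchar(r$seq[mapped])
    if (!all(total == n)) return("total block width must equal read length")
    if (!all(n == nchar(r$qual[mapped]) & n == nchar(r$mask[mapped]))) {
      return("seq, qual and mask must have equal length")
    }
    starts <- .splitInts(r$blockStarts[mapped])
    ok <- mapply(function(s, w) {
      length(s) == length(w) &&
        (length(s) <= 1L || all(diff(s) > 0) && all(s[-1] >= (s + w)[-length(s)]))
    }, starts, widths)
    if (!all(ok)) return("blocks must be sorted and non-overlapping")
    if (!all(r$strand[mapped] %in% c("+", "-"))) {
      return("mapped records need strand + or -")
    }
  }
  TRUE
})

#' TranscriptModels: transcript annotation
#'
#' Transcript structures (chromosome, strand, ordered exon intervals)
#' defining the transcript-to-genome coordinate map used for spliced
#' transfer of transcript-space alignments. Exons are stored sorted by
#' genomic coordinate and non-overlapping; all coordinates 0-based
#' half-open.
#'
#' @slot tx data.frame with columns txId, geneId, chrom, strand,
#'   exonStarts, exonEnds (comma-separated), txLength.
#' @export
setClass("TranscriptModels",
  representation(tx = "data.frame"),
  prototype(tx = data.frame())
)

setValidity("TranscriptModels", function(object) {
  t <- object@tx
  if (nrow(t) == 0L) return(TRUE)
  need <- c("txId", "geneId", "chrom", "strand", "exonStarts", "exonEnds",
            "txLength")
  missing <- setdiff(need, names(t))
  if (length(missing)) {
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(t$txId)) return("duplicate transcript ids")
  if (!all(t$strand %in% c("+", "-"))) return("strand must be + or -")
  ss <- .splitInts(t$exonStarts)
  ee <- .splitInts(t$exonEnds)
  for (i in seq_len(nrow(t))) {
    s <- ss[[i]]; e <- ee[[i]]
    if (length(s) == 0L || length(s) != length(e)) {
      return(paste0("transcript ", t$txId[i], ": malformed exon lists"))
    }
    if (any(e <= s)) {
      return(paste0("transcript ", t$txId[i], ": exon end <= start"))
    }
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)])) {
      return(paste0("transcript ", t$txId[i],
                    ": exons must be sorted and non-overlapping"))
    }
    if (sum(e - s) != t$txLength[i]) {
      return(paste0("transcript ", t$txId[i],
                    ": txLength != sum of exon lengths"))
    }
  }
  TRUE
})

#' PileupTable: per-locus base observations
#'
#' A vertical slicing of a set of alignments: one row per (locus, base
#' observation). Columns: chrom, pos (0-based), ref (reference base),
#' base, qual (integer Phred), laneId, readPos (0-based offset within the
#' read, 5' to 3'), readStart (0-based genomic start of the source read).
#' Bases with Phred quality 0 or 1 and masked (trimmed) bases are never
#' admitted.
#'
#' @slot observations data.frame as described.
#' @export
setClass("PileupTable",
  representation(observations = "data.frame"),
  prototype(observations = data.frame())
)

.PILEUP_COLS <- c("chrom", "pos", "ref", "base", "qual", "laneId",
                  "readPos", "readStart")

setValidity("PileupTable", function(object) {
  o <- object@observations
  if (nrow(o) == 0L) return(TRUE)
  missing <- setdiff(.PILEUP_COLS, names(o))
  if (length(missing)) {
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(o$qual < 2L)) return("quality 0/1 observations are not allowed")
  if (!all(o$base %in% c(.BASES, "N"))) return("base must be A/C/G/T/N")
  TRUE
})

#' GenotypePosteriors: per-locus genotype posterior distributions
#'
#' Result of the SNVQ Bayesian model over a pileup: for every locus with
#' at least one observation, the log-likelihood and the normalized
#' posterior probability of each of the ten diploid genotypes (columns
#' ordered as [GENOTYPES]).
#'
#' @slot loci data.frame with chrom, pos, ref, coverage (usable
#'   observation count).
#' @slot logLik numeric matrix, loci x 10 genotype log-likelihoods.
#' @slot posterior numeric matrix, loci x 10, rows summing to 1.
#' @slot h numeric, heterozygosity rate used for the prior.
#' @export
setClass("GenotypePosteriors",
  representation(loci = "data.frame", logLik = "matrix",
                 posterior = "matrix", h = "numeric")
)

setValidity("GenotypePosteriors", function(object) {
  n <- nrow(object@loci)
  if (!identical(dim(object@posterior), c(n, 10L)) &&
      !(n == 0L && length(object@posterior) == 0L)) {
    return("posterior must be an n x 10 matrix")
  }
  if (n > 0L) {
    s <- rowSums(object@posterior)
    if (any(abs(s - 1) > 1e-9)) return("posterior rows must sum to 1")
    if (any(object@posterior < 0)) return("posterior must be non-negative")
  }
  if (object@h <= 0 || object@h >= 1) return("h must be in (0,1)")
  TRUE
})

#' GenotypeCalls: called genotypes
#'
#' One row per called locus: chrom, pos (0-based), ref, genotype
#' (canonical two-letter string), posterior (probability of the called
#' genotype), variantPosterior (1 - posterior of homozygous reference),
#' isVariant, coverage.
#'
#' @slot calls data.frame as described.
#' @slot h numeric heterozygosity rate used.
#' @export
setClass("GenotypeCalls",
  representation(calls = "data.frame", h = "numeric"),
  prototype(calls = data.frame(), h = 0.001)
)

setValidity("GenotypeCalls", function(object) {
  cl <- object@calls
  if (nrow(cl) == 0L) return(TRUE)
  need <- c("chrom", "pos", "ref", "genotype", "posterior",
            "variantPosterior", "isVariant", "coverage")
  missing <- setdiff(need, names(cl))
  if (length(missing)) {
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  expectVar <- cl$genotype != paste0(cl$ref, cl$ref)
  if (!identical(as.logical(cl$isVariant), expectVar)) {
    return("isVariant must equal (genotype != homozygous reference)")
  }
  TRUE
})

#' MismatchProfile: per-cycle mismatch diagnostic
#'
#' For each read offset (5' to 3'), the fraction of aligned reads whose
#' base at that offset mismatches the reference, and the number of reads
#' contributing at that offset. The diagnostic precedes trimming, so
#' masked bases are included.
#'
#' @slot fraction numeric vector of mismatch fractions, index = offset+1.
#' @slot counts integer vector of contributing read counts.
#' @export
setClass("MismatchProfile",
  representation(fraction = "numeric", counts = "integer")
)

setValidity("MismatchProfile", function(object) {
  if (length(object@fraction) != length(object@counts)) {
    return("fraction and counts must have equal length")
  }
  f <- object@fraction[object@counts > 0L]
  if (any(f < 0 | f > 1)) return("fractions must be in [0,1]")
  TRUE
})

#' SimulationConfig: parameters of the read simulator
#'
#' Defaults emulate a 2009-era Illumina whole-transcriptome run: 33 bp
#' reads across 7 lanes, planted heterozygosity rate 0.001 (one third of
#' planted variants homozygous non-reference), constant reported quality
#' Q30 with the true per-cycle error rate defaulting to the Phred-implied
#' rate, no PCR duplicates. `perCycleTrueError` may be set independently
#' of `perCycleQuality` to model 3'-end de-phasing error that the base
#' caller's reported qualities do not admit.
#'
#' @slot seed integer random seed (mandatory for reproducibility).
#' @slot genomeLength integer genome size in bp.
#' @slot nTranscripts integer number of transcripts to place.
#' @slot exonsPerTranscript integer range (min,max) of exons per transcript.
#' @slot exonLength integer range (min,max) of exon lengths.
#' @slot intronLength integer range (min,max) of intron lengths.
#' @slot hetRate numeric planted heterozygosity rate h.
#' @slot homAltFraction numeric fraction of planted variants that are
#'   homozygous non-reference rather than heterozygous.
#' @slot expressionSdLog numeric sdlog of the lognormal expression weight
#'   distribution (0 = uniform expression).
#' @slot readLength integer read length in bp.
#' @slot readsPerLane integer reads sampled per lane.
#' @slot nLanes integer number of lanes.
#' @slot perCycleQuality integer vector of reported Phred qualities, one
#'   per cycle (recycled to readLength).
#' @slot perCycleTrueError numeric vector of true per-cycle error rates;
#'   NA entries default to 10^(-q/10) of the reported quality.
#' @slot duplicateRate numeric probability that a read emits one extra
#'   PCR-duplicate copy.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer", genomeLength = "integer", nTranscripts = "integer",
    exonsPerTranscript = "integer", exonLength = "integer",
    intronLength = "integer", hetRate = "numeric",
    homAltFraction = "numeric", expressionSdLog = "numeric",
    readLength = "integer", readsPerLane = "integer", nLanes = "integer",
    perCycleQuality = "integer", perCycleTrueError = "numeric",
    duplicateRate = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  if (length(object@seed) != 1L || is.na(object@seed)) {
    return("seed is mandatory")
  }
  rates <- c(object@hetRate, object@homAltFraction, object@duplicateRate)
  if (any(rates < 0 | rates > 1)) return("rates must be in [0,1]")
  if (object@hetRate >= 0.1) return("hetRate must be < 0.1")
  if (object@readLength < 1L) return("readLength must be positive")
  if (any(object@perCycleQuality < 0L)) return("qualities must be >= 0")
  te <- object@perCycleTrueError
  if (any(!is.na(te) & (te < 0 | te > 1))) {
    return("true error rates must be in [0,1]")
  }
  TRUE
})

#' TruthSet: planted variants and their genotypes
#'
#' Gold-standard table produced by the simulator: one row per planted
#' variant with chrom, pos (0-based), ref, alt, genotype (canonical),
#' zygosity ("het"/"hom"), and phase (which haplotype carries the
#' alternative allele for heterozygous variants; both for homozygous).
#'
#' @slot variants data.frame as described.
#' @export
setClass("TruthSet",
  representation(variants = "data.frame"),
  prototype(variants = data.frame())
)

setValidity("TruthSet", function(object) {
  v <- object@variants
  if (nrow(v) == 0L) return(TRUE)
  need <- c("chrom", "pos", "ref", "alt", "genotype", "zygosity", "phase")
  missing <- setdiff(need, names(v))
  if (length(missing)) {
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(v$genotype == paste0(v$ref, v$ref))) {
    return("planted genotypes must differ from homozygous reference")
  }
  TRUE
})

#' SimulatedDataset: a complete simulated experiment
#'
#' Bundles the synthetic genome, transcript models, planted-variant truth
#' set, and the sampled reads in both genomic coordinates (truth
#' alignments) and transcript coordinates, so the merge and genotyping
#' machinery can be exercised end to end without external data.
#'
#' @slot genome DNAStringSet of chromosome sequences.
#' @slot models TranscriptModels.
#' @slot truth TruthSet.
#' @slot genomeReads AlignmentSet in genomic coordinates.
#' @slot transcriptReads AlignmentSet in transcript coordinates.
#' @slot config SimulationConfig used.
#' @export
setClass("SimulatedDataset",
  representation(
    genome = "DNAStringSet", models = "TranscriptModels",
    truth = "TruthSet", genomeReads = "AlignmentSet",
    transcriptReads = "AlignmentSet", config = "SimulationConfig"
  )
)
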