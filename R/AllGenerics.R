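## Generics, accessors and show methods.

#' @import methods
#' @importFrom stats rbinom runif rlnorm setNames
#' @importFrom utils head
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom data.table data.table as.data.table setorder setnames := .N .SD
#' @keywords internal
"_PACKAGE"

#' Number of alignment records
#'
#' @param x An [AlignmentSet-class].
#' @return Integer count of alignment rows.
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname nReads
setMethod("nReads", "AlignmentSet", function(x) nrow(x@reads))

#' Alignment table of an AlignmentSet
#'
#' @param x An [AlignmentSet-class].
#' @return The underlying data.frame of alignment records.
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))

#' @rdname alignments
setMethod("alignments", "AlignmentSet", function(x) x@reads)

#' Metadata list
#'
#' @param x An object with a metadata slot.
#' @return The metadata list.
#' @export
setGeneric("alnMetadata", function(x) standardGeneric("alnMetadata"))

#' @rdname alnMetadata
setMethod("alnMetadata", "AlignmentSet", function(x) x@metadata)

#' Transcript table of a TranscriptModels object
#'
#' @param x A [TranscriptModels-class].
#' @return The underlying data.frame of transcript records.
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname transcripts
setMethod("transcripts", "TranscriptModels", function(x) x@tx)

#' Observation table of a PileupTable
#'
#' @param x A [PileupTable-class].
#' @return The underlying data.frame of base observations.
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname observations
setMethod("observations", "PileupTable", function(x) x@observations)

#' Call table of a GenotypeCalls object
#'
#' @param x A [GenotypeCalls-class].
#' @return The underlying data.frame of genotype calls.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname calls
setMethod("calls", "GenotypeCalls", function(x) x@calls)

#' Loci, likelihood and posterior accessors for GenotypePosteriors
#'
#' @param x A [GenotypePosteriors-class].
#' @return `posteriorLoci`: data.frame of loci; `posteriorMatrix`: the
#'   loci x 10 posterior matrix; `logLikMatrix`: the loci x 10 genotype
#'   log-likelihood matrix.
#' @export
setGeneric("posteriorLoci", function(x) standardGeneric("posteriorLoci"))

#' @rdname posteriorLoci
setMethod("posteriorLoci", "GenotypePosteriors", function(x) x@loci)

#' @rdname posteriorLoci
#' @export
setGeneric("posteriorMatrix", function(x) standardGeneric("posteriorMatrix"))

#' @rdname posteriorLoci
setMethod("posteriorMatrix", "GenotypePosteriors", function(x) x@posterior)

#' @rdname posteriorLoci
#' @export
setGeneric("logLikMatrix", function(x) standardGeneric("logLikMatrix"))

#' @rdname posteriorLoci
setMethod("logLikMatrix", "GenotypePosteriors", function(x) x@logLik)

#' Truth table of a TruthSet
#'
#' @param x A [TruthSet-class].
#' @return The underlying data.frame of planted variants.
#' @export
setGeneric("truthVariants", function(x) standardGeneric("truthVariants"))

#' @rdname truthVariants
setMethod("truthVariants", "TruthSet", function(x) x@variants)

setMethod("show", "AlignmentSet", function(object) {
  r <- object@reads
  cat("AlignmentSet with", nrow(r), "alignment record(s)\n")
  if (nrow(r)) {
    tab <- table(r$status)
    cat("  status:", paste(names(tab), as.integer(tab), collapse = ", "),
        "\n")
    cat("  references:", length(unique(r$rname[!is.na(r$rname)])),
        " lanes:", length(unique(r$laneId)), "\n")
  }
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  }
})

setMethod("show", "TranscriptModels", function(object) {
  t <- object@tx
  cat("TranscriptModels with", nrow(t), "transcript(s)")
  if (nrow(t)) {
    cat(" on", length(unique(t$chrom)), "chromosome(s);",
        "total exonic length", sum(t$txLength), "bp")
  }
  cat("\n")
})

setMethod("show", "PileupTable", function(object) {
  o <- object@observations
  cat("PileupTable:", nrow(o), "base observation(s)")
  if (nrow(o)) {
    nl <- nrow(unique(o[, c("chrom", "pos")]))
    cat(" over", nl, "locus/loci")
  }
  cat("\n")
})

setMethod("show", "GenotypePosteriors", function(object) {
  cat("GenotypePosteriors over", nrow(object@loci),
      "locus/loci (h =", object@h, ")\n")
})

setMethod("show", "GenotypeCalls", function(object) {
  cl <- object@calls
  cat("GenotypeCalls:", nrow(cl), "call(s),",
      sum(cl$isVariant), "variant(s) (h =", object@h, ")\n")
  if (nrow(cl)) print(head(cl, 5))
})

setMethod("show", "MismatchProfile", function(object) {
  cat("MismatchProfile over", length(object@fraction), "read cycle(s);",
      "mean mismatch fraction",
      signif(mean(object@fraction[object@counts > 0]), 4), "\n")
})

setMethod("show", "TruthSet", function(object) {
  v <- object@variants
  cat("TruthSet with", nrow(v), "planted variant(s)")
  if (nrow(v)) {
    cat(" (", sum(v$zygosity == "het"), "het /",
        sum(v$zygosity == "hom"), "hom )")
  }
  cat("\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:\n")
  cat("  genome:", sum(Biostrings::width(object@genome)), "bp on",
      length(object@genome), "chromosome(s)\n")
  cat("  transcripts:", nrow(object@models@tx), "\n")
  cat("  planted variants:", nrow(object@truth@variants), "\n")
  cat("  reads:", nrow(object@genomeReads@reads), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "| genome",
      object@genomeLength, "bp |", object@nTranscripts, "transcripts | h",
      object@hetRate, "|", object@readLength, "bp reads x",
      object@readsPerLane, "per lane x", object@nLanes, "lanes\n")
})
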