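## SNVQ: Bayesian SNV detection and genotyping over all ten diploid
## genotypes, driven by Phred base qualities.
##
## Per-observation model: with error probability eps derived from the
## Phred score, the probability of observing base r under genotype
## G = {H, H'} is
##     1 - eps        if G homozygous and r = H
##     eps / 3        if r matches neither allele
##     1/2 - eps/3    otherwise (heterozygous, r matches one allele)
## which sums to 1 over the four bases for every G. Reads are treated as
## independent, so the genotype likelihood is the product over spanning
## observations; the prior puts (1-h)/4 on each homozygous and h/6 on
## each heterozygous genotype. All accumulation is in log space; products
## of hundreds of small per-read terms underflow otherwise.

#' Phred quality to error probability
#'
#' epsilon = 10^(-q/10), capped at `epsMax` so that the per-read
#' likelihood terms 1 - eps and 1/2 - eps/3 stay positive and informative
#' for very low qualities (quality-0/1 calls are discarded before
#' genotyping anyway; the cap is defensive).
#'
#' @param q Integer vector of Phred scores (>= 0).
#' @param epsMax Upper cap on the error probability (default 0.75).
#' @return Numeric vector of error probabilities.
#' @export
phredToErrorProb <- function(q, epsMax = 0.75) {
  if (any(q < 0)) stop("negative Phred quality")
  pmin(10^(-q / 10), epsMax)
}

#' Per-read conditional probability P(r | G)
#'
#' @param base Character vector of observed bases (A/C/G/T).
#' @param eps Numeric vector of error probabilities (recycled).
#' @param genotype A single two-letter genotype string.
#' @return Numeric vector of conditional probabilities.
#' @export
readLikelihood <- function(base, eps, genotype) {
  if (any(!base %in% .BASES)) {
    stop("N or invalid bases must be excluded before computing ",
         "likelihoods")
  }
  stopifnot(all(eps > 0 & eps < 1))
  genotype <- canonicalGenotype(genotype)
  h1 <- substr(genotype, 1L, 1L)
  h2 <- substr(genotype, 2L, 2L)
  if (h1 == h2) {
    ifelse(base == h1, 1 - eps, eps / 3)
  } else {
    ifelse(base == h1 | base == h2, 1 / 2 - eps / 3, eps / 3)
  }
}

#' Genotype prior distribution
#'
#' Each of the 4 homozygous genotypes gets (1-h)/4 and each of the 6
#' heterozygous genotypes h/6, where h is the expected heterozygosity
#' rate (default 0.001). The prior is position- and strand-independent
#' and does not favor the reference allele or distinguish
#' transitions/transversions.
#'
#' @param h Heterozygosity rate in (0,1).
#' @return Named numeric vector over [GENOTYPES], summing to 1.
#' @export
genotypePriors <- function(h = 0.001) {
  stopifnot(length(h) == 1L, h > 0, h < 1)
  setNames(ifelse(.GT_IS_HOM, (1 - h) / 4, h / 6), GENOTYPES)
}

## Per-observation log-likelihood matrix: n x 10 for bases/eps vectors.
.obsLogLik <- function(base, eps) {
  out <- matrix(NA_real_, length(base), 10L,
                dimnames = list(NULL, GENOTYPES))
  logMiss <- log(eps / 3)
  for (g in seq_len(10L)) {
    if (.GT_IS_HOM[g]) {
      out[, g] <- ifelse(base == .GT_ALLELE1[g], log1p(-eps), logMiss)
    } else {
      hit <- base == .GT_ALLELE1[g] | base == .GT_ALLELE2[g]
      out[, g] <- ifelse(hit, log(1 / 2 - eps / 3), logMiss)
    }
  }
  out
}

#' Genotype posterior for a single pileup column
#'
#' Convenience single-locus version of the model: given the observed
#' bases and qualities spanning one locus, returns the normalized
#' posterior over the ten genotypes. With zero observations the posterior
#' equals the prior (empty product).
#'
#' @param base Character vector of observed bases (N must be excluded).
#' @param qual Integer vector of Phred qualities (same length).
#' @param h Heterozygosity rate.
#' @param epsMax Error-probability cap, see [phredToErrorProb()].
#' @return Named numeric vector of posterior probabilities over
#'   [GENOTYPES].
#' @export
genotypePosterior <- function(base, qual, h = 0.001, epsMax = 0.75) {
  stopifnot(length(base) == length(qual))
  logPost <- log(genotypePriors(h))
  if (length(base)) {
    eps <- phredToErrorProb(qual, epsMax)
    logPost <- logPost + colSums(.obsLogLik(base, eps))
  }
  m <- max(logPost)
  p <- exp(logPost - m)
  p / sum(p)
}

#' Genotype posteriors over a pileup
#'
#' Vectorized SNVQ over every locus of a pileup. Observations with base
#' "N" or reference "N" are excluded; loci left without observations are
#' dropped. Computation aggregates observations into (locus, base,
#' quality) counts, accumulates genotype log-likelihoods in log space and
#' normalizes with log-sum-exp over the ten genotypes.
#'
#' @param pileup A [PileupTable-class].
#' @param h Heterozygosity rate (default 0.001).
#' @param epsMax Error-probability cap.
#' @return A [GenotypePosteriors-class], loci sorted by (chrom, pos).
#' @export
genotypePosteriors <- function(pileup, h = 0.001, epsMax = 0.75) {
  o <- data.table::as.data.table(pileup@observations)
  o <- o[o$base != "N" & o$ref != "N", ]
  empty <- function() new("GenotypePosteriors",
    loci = data.frame(chrom = character(), pos = integer(),
                      ref = character(), coverage = integer()),
    logLik = matrix(numeric(0), 0L, 10L,
                    dimnames = list(NULL, GENOTYPES)),
    posterior = matrix(numeric(0), 0L, 10L,
                       dimnames = list(NULL, GENOTYPES)),
    h = h)
  if (!nrow(o)) return(empty())
  agg <- o[, list(n = .N, ref = ref[1L]),
           by = c("chrom", "pos", "base", "qual")]
  data.table::setorder(agg, chrom, pos)
  lociKey <- paste(agg$chrom, agg$pos, sep = "\r")
  lid <- match(lociKey, unique(lociKey))
  nLoci <- max(lid)
  eps <- phredToErrorProb(agg$qual, epsMax)
  perObs <- .obsLogLik(agg$base, eps) * agg$n
  ll <- rowsum(perObs, lid, reorder = FALSE)
  colnames(ll) <- GENOTYPES
  logPrior <- log(genotypePriors(h))
  lp <- sweep(ll, 2L, logPrior, `+`)
  norm <- .rowLogSumExp(lp)
  post <- exp(lp - norm)
  first <- !duplicated(lid)
  loci <- data.frame(
    chrom = agg$chrom[first], pos = agg$pos[first], ref = agg$ref[first],
    coverage = as.integer(rowsum(agg$n, lid, reorder = FALSE)),
    stringsAsFactors = FALSE
  )
  new("GenotypePosteriors", loci = loci, logLik = ll, posterior = post,
      h = h)
}

#' Call genotypes from posteriors
#'
#' The called genotype is the posterior argmax; exact ties are broken
#' toward homozygous reference, then lexicographically (the conservative
#' no-variant outcome wins). A variant is called when the argmax differs
#' from homozygous reference; `variantPosterior` is 1 minus the posterior
#' of homozygous reference, the quantity thresholded by the
#' sensitivity/specificity sweeps. Loci with reference "N" are never
#' called.
#'
#' @param gp A [GenotypePosteriors-class].
#' @param emitReference Emit homozygous-reference calls too (default
#'   TRUE; the pipeline driver [callVariants()] defaults to variants
#'   only).
#' @param minVariantPosterior Drop variant calls below this
#'   variant-posterior threshold (default 0: keep all).
#' @return A [GenotypeCalls-class].
#' @export
callGenotypes <- function(gp, emitReference = TRUE,
                          minVariantPosterior = 0) {
  loci <- gp@loci
  post <- gp@posterior
  keepRef <- loci$ref %in% .BASES
  loci <- loci[keepRef, , drop = FALSE]
  post <- post[keepRef, , drop = FALSE]
  emptyCalls <- function() new("GenotypeCalls", calls = data.frame(
    chrom = character(), pos = integer(), ref = character(),
    genotype = character(), posterior = numeric(),
    variantPosterior = numeric(), isVariant = logical(),
    coverage = integer(), stringsAsFactors = FALSE), h = gp@h)
  if (!nrow(loci)) return(emptyCalls())
  refIdx <- match(paste0(loci$ref, loci$ref), GENOTYPES)
  best <- max.col(post, ties.method = "first")  # lexicographic-first
  maxP <- post[cbind(seq_len(nrow(post)), best)]
  refP <- post[cbind(seq_len(nrow(post)), refIdx)]
  best[refP == maxP] <- refIdx[refP == maxP]  # tie toward hom-ref
  genotype <- GENOTYPES[best]
  posterior <- post[cbind(seq_len(nrow(post)), best)]
  variantPosterior <- 1 - refP
  isVariant <- best != refIdx
  cl <- data.frame(
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref,
    genotype = genotype, posterior = posterior,
    variantPosterior = variantPosterior, isVariant = isVariant,
    coverage = loci$coverage, stringsAsFactors = FALSE
  )
  if (!emitReference) cl <- cl[cl$isVariant, , drop = FALSE]
  if (minVariantPosterior > 0) {
    cl <- cl[!cl$isVariant | cl$variantPosterior >= minVariantPosterior, ,
             drop = FALSE]
  }
  rownames(cl) <- NULL
  new("GenotypeCalls", calls = cl, h = gp@h)
}

#' Streaming driver: pileup to variant calls
#'
#' Runs the SNVQ model over a sorted pileup and emits one call per locus
#' with at least one usable observation (by default only variant calls;
#' set `emitReference = TRUE` to keep homozygous-reference calls).
#' Deterministic: no randomness is involved.
#'
#' @param pileup A [PileupTable-class] sorted by (chrom, pos).
#' @param h Heterozygosity rate (default 0.001).
#' @param emitReference Also emit homozygous-reference calls.
#' @param minVariantPosterior Threshold on the variant posterior.
#' @param epsMax Error-probability cap.
#' @return A [GenotypeCalls-class] sorted by (chrom, pos).
#' @export
callVariants <- function(pileup, h = 0.001, emitReference = FALSE,
                         minVariantPosterior = 0, epsMax = 0.75) {
  o <- pileup@observations
  if (nrow(o) && !.isSortedByChromPos(o$chrom, o$pos)) {
    stop("pileup must be sorted by (chrom, pos)")
  }
  gp <- genotypePosteriors(pileup, h = h, epsMax = epsMax)
  callGenotypes(gp, emitReference = emitReference,
                minVariantPosterior = minVariantPosterior)
}

#' Write genotype calls as a tab-separated variant table
#'
#' Columns: chrom, 1-based pos, ref, genotype, posterior,
#' variantPosterior, coverage.
#'
#' @param x A [GenotypeCalls-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeCalls <- function(x, file) {
  cl <- x@calls
  header <- "#chrom\tpos\tref\tgenotype\tposterior\tvariantPosterior\tcoverage"
  lines <- paste(cl$chrom, cl$pos + 1L, cl$ref, cl$genotype,
                 signif(cl$posterior, 6), signif(cl$variantPosterior, 6),
                 cl$coverage, sep = "\t")
  writeLines(c(header, lines), file)
  invisible(file)
}

#' Read a tab-separated variant table written by [writeCalls()]
#'
#' @param file Path.
#' @param h Heterozygosity rate to record on the object.
#' @return A [GenotypeCalls-class].
#' @export
readCalls <- function(file, h = 0.001) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(new("GenotypeCalls", calls = data.frame(
      chrom = character(), pos = integer(), ref = character(),
      genotype = character(), posterior = numeric(),
      variantPosterior = numeric(), isVariant = logical(),
      coverage = integer(), stringsAsFactors = FALSE), h = h))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  cl <- data.frame(
    chrom = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)) - 1L,
    ref = vapply(f, `[[`, character(1), 3L),
    genotype = vapply(f, `[[`, character(1), 4L),
    posterior = as.numeric(vapply(f, `[[`, character(1), 5L)),
    variantPosterior = as.numeric(vapply(f, `[[`, character(1), 6L)),
    coverage = as.integer(vapply(f, `[[`, character(1), 7L)),
    stringsAsFactors = FALSE
  )
  cl$isVariant <- cl$genotype != paste0(cl$ref, cl$ref)
  cl <- cl[, c("chrom", "pos", "ref", "genotype", "posterior",
               "variantPosterior", "isVariant", "coverage")]
  new("GenotypeCalls", calls = cl, h = h)
}

#' Export calls as a minimal VCF
#'
#' Convenience export: fixed columns plus a GT sample field. Reference
#' calls are skipped.
#'
#' @param x A [GenotypeCalls-class].
#' @param file Output path.
#' @param sample Sample name for the genotype column.
#' @return Invisibly, the file path.
#' @export
writeVCF <- function(x, file, sample = "sample") {
  cl <- x@calls[x@calls$isVariant, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tFORMAT\t", sample)
  )
  if (!nrow(cl)) {
    writeLines(header, file)
    return(invisible(file))
  }
  a1 <- substr(cl$genotype, 1L, 1L)
  a2 <- substr(cl$genotype, 2L, 2L)
  alt <- mapply(function(r, x1, x2) {
    paste(unique(setdiff(c(x1, x2), r)), collapse = ",")
  }, cl$ref, a1, a2, USE.NAMES = FALSE)
  gtIdx <- function(a, r, altStr) {
    ifelse(a == r, "0", as.character(match(a, strsplit(altStr, ",")[[1]])))
  }
  gt <- vapply(seq_len(nrow(cl)), function(i) {
    paste(gtIdx(a1[i], cl$ref[i], alt[i]), gtIdx(a2[i], cl$ref[i], alt[i]),
          sep = "/")
  }, character(1))
  qual <- round(-10 * log10(pmax(1 - cl$posterior, 1e-10)), 2)
  lines <- paste(cl$chrom, cl$pos + 1L, ".", cl$ref, alt, qual, "PASS",
                 "GT", gt, sep = "\t")
  writeLines(c(header, lines), file)
  invisible(file)
}
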