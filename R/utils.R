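## Shared constants and low-level helpers.

#' The ten diploid genotypes
#'
#' All unordered pairs of alleles over \{A,C,G,T\}, encoded as two-letter
#' strings with alleles in alphabetical order ("AC", never "CA"), listed
#' lexicographically. This ordering is the column order of every genotype
#' posterior/likelihood matrix in the package.
#'
#' @format Character vector of length 10.
#' @export
GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

.BASES <- c("A", "C", "G", "T")

## First/second allele of each genotype, aligned with GENOTYPES.
.GT_ALLELE1 <- substr(GENOTYPES, 1L, 1L)
.GT_ALLELE2 <- substr(GENOTYPES, 2L, 2L)
.GT_IS_HOM <- .GT_ALLELE1 == .GT_ALLELE2

#' Canonicalize a genotype string
#'
#' Sorts the two allele letters so that \{A,C\} and \{C,A\} map to the same
#' encoding "AC".
#'
#' @param x Character vector of two-letter genotype strings.
#' @return Character vector of canonical genotype strings.
#' @examples
#' canonicalGenotype(c("CA", "AC", "TT"))
#' @export
canonicalGenotype <- function(x) {
  stopifnot(is.character(x))
  bad <- !is.na(x) & (nchar(x) != 2L |
    !(substr(x, 1L, 1L) %in% .BASES) | !(substr(x, 2L, 2L) %in% .BASES))
  if (any(bad)) {
    stop("invalid genotype string(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  a1 <- substr(x, 1L, 1L)
  a2 <- substr(x, 2L, 2L)
  ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
}

#' Alleles of a genotype
#'
#' @param x A single two-letter genotype string.
#' @return Character vector of the one or two distinct alleles.
#' @export
genotypeAlleles <- function(x) {
  x <- canonicalGenotype(x)
  unique(c(substr(x, 1L, 1L), substr(x, 2L, 2L)))
}

#' Is a genotype heterozygous?
#'
#' @param x Character vector of genotype strings.
#' @return Logical vector.
#' @export
isHeterozygous <- function(x) {
  x <- canonicalGenotype(x)
  substr(x, 1L, 1L) != substr(x, 2L, 2L)
}

## Split comma-separated integer strings into a list of integer vectors.
## "" maps to integer(0).
.splitInts <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(v) as.integer(v[nzchar(v)]))
}

.joinInts <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ","), character(1))
}

## Decode a vector of equal-meaning per-base strings (seq/qual/mask) into
## one flat character/integer representation. Returns the concatenation as
## a single raw vector for speed.
.charsOf <- function(x) {
  # flat vector of single characters across all strings, in order
  strsplit(paste(x, collapse = ""), "", fixed = TRUE)[[1]]
}

.phredOf <- function(qualStrings, offset = 33L) {
  utf8ToInt(paste(qualStrings, collapse = "")) - offset
}

## log-sum-exp over matrix rows
.rowLogSumExp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), na.rm = TRUE))
  mx + log(rowSums(exp(m - mx)))
}

## Reverse each string in a character vector (vectorized enough for our use).
.revStrings <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.revCompStrings <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## stable check that a numeric vector is sorted by (chrom, pos)
.isSortedByChromPos <- function(chrom, pos) {
  if (length(chrom) <= 1L) return(TRUE)
  o <- order(chrom, pos, method = "radix")
  identical(o, seq_along(chrom))
}
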