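## Gold-standard genotype tables: tab-separated chromosome, 1-based
## position, two-letter genotype. Internally 0-based, genotypes
## canonicalized as unordered pairs.

#' Read a gold-standard genotype table
#'
#' @param file Path to a tab-separated file with columns chromosome,
#'   1-based position, two-letter genotype ("AC" and "CA" are the same
#'   genotype). Lines starting with "#" are ignored.
#' @return data.frame with chrom, pos (0-based) and genotype (canonical),
#'   suitable as the `gold` argument of the evaluation functions.
#' @export
readGoldStandard <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos = integer(),
                      genotype = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) {
    stop("gold-standard line with fewer than 3 fields: line ",
         which(lengths(f) < 3L)[1L])
  }
  gt <- canonicalGenotype(vapply(f, `[[`, character(1), 3L))
  out <- data.frame(
    chrom = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)) - 1L,
    genotype = gt,
    stringsAsFactors = FALSE
  )
  if (anyNA(out$pos) || any(out$pos < 0L)) {
    stop("invalid position in gold-standard table")
  }
  key <- paste(out$chrom, out$pos)
  if (anyDuplicated(key)) {
    d <- unique(key[duplicated(key)])
    conflict <- vapply(d, function(k) {
      length(unique(out$genotype[key == k])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop("conflicting genotypes at position(s): ",
           paste(d[conflict], collapse = ", "))
    }
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write a gold-standard genotype table
#'
#' @param gold data.frame with chrom, pos (0-based), genotype.
#' @param file Output path (written 1-based).
#' @return Invisibly, the file path.
#' @export
writeGoldStandard <- function(gold, file) {
  writeLines(paste(gold$chrom, gold$pos + 1L, gold$genotype, sep = "\t"),
             file)
  invisible(file)
}
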