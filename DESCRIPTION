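Package: snvq
Title: Detection and Genotyping of Expressed Single Nucleotide Variants
    from RNA-Seq Alignments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for calling single nucleotide variants from whole
    transcriptome sequencing data. Implements dual-reference read mapping
    reconciliation (hard and soft merging of genome-space and
    transcript-space alignments, with spliced transfer of transcript
    alignments to genomic coordinates and collapsing of multi-isoform
    hits), a Bayesian genotyper (SNVQ) that computes posterior
    probabilities over all ten diploid genotypes from Phred base
    qualities, data-curation filters (aligned-read trimming, start-locus
    read caps, lane-support and minimum allele-count thresholds, per-cycle
    mismatch profiling), a sensitivity/specificity evaluation framework
    against gold-standard genotypes, and a fully deterministic RNA-Seq
    read simulator with planted variants for end-to-end validation.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    S4Vectors,
    Biostrings,
    IRanges,
    GenomicRanges,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicAlignments,
    BiocGenerics,
    yaml
Config/testthat/edition: 3
biocViews: Genetics, SNP, VariantDetection, Sequencing, RNASeq, Bayesian
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sam-io.R'
    'annotation-io.R'
    'pileup.R'
    'gold-standard.R'
    'merge.R'
    'genotyper.R'
    'filters.R'
    'evaluate.R'
    'simulate.R'
    'cli.R'
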