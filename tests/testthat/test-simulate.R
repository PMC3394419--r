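test_that("simulation is byte-identical across runs under a fixed seed", {
  s1 <- smallSimulation(seed = 5L)
  s2 <- smallSimulation(seed = 5L)
  expect_identical(as.character(s1@genome), as.character(s2@genome))
  expect_identical(transcripts(s1@models), transcripts(s2@models))
  expect_identical(truthVariants(s1@truth), truthVariants(s2@truth))
  expect_identical(alignments(s1@genomeReads), alignments(s2@genomeReads))
  s3 <- smallSimulation(seed = 6L)
  expect_false(identical(as.character(s3@genome),
                         as.character(s1@genome)))
})

test_that("transcript packing respects the genome and exon-count bounds", {
  cfg <- simulationConfig(seed = 2L, genomeLength = 50000L,
                          nTranscripts = 5L,
                          exonsPerTranscript = c(1L, 1L),
                          exonLength = c(200L, 400L))
  gt <- simulateGenomeAndTranscripts(cfg)
  t <- transcripts(gt$models)
  expect_identical(nrow(t), 5L)
  # single-exon config -> unspliced transcripts only
  expect_false(any(grepl(",", t$exonStarts)))
  expect_lte(sum(t$txLength), cfg@genomeLength)
  # infeasible packing errors with advice
  tight <- simulationConfig(seed = 2L, genomeLength = 3000L,
                            nTranscripts = 50L)
  expect_error(simulateGenomeAndTranscripts(tight), "genomeLength")
})

test_that("planted variant counts follow the binomial expectation", {
  cfg <- simulationConfig(seed = 3L, genomeLength = 400000L,
                          nTranscripts = 60L,
                          exonsPerTranscript = c(2L, 4L),
                          exonLength = c(300L, 600L))
  gt <- simulateGenomeAndTranscripts(cfg)
  exonic <- sum(transcripts(gt$models)$txLength)
  h <- 0.005
  truth <- plantVariants(gt$genome, gt$models, hetRate = h, seed = 4L)
  v <- truthVariants(truth)
  expect_gt(nrow(v), exonic * h - 3 * sqrt(exonic * h))
  expect_lt(nrow(v), exonic * h + 3 * sqrt(exonic * h))
  # no planted genotype equals homozygous reference, hom/het split sane
  expect_false(any(v$genotype == paste0(v$ref, v$ref)))
  expect_true(all(v$zygosity %in% c("het", "hom")))
  expect_true(all(v$alt != v$ref))
  # h = 0 -> empty truth set
  empty <- plantVariants(gt$genome, gt$models, hetRate = 0, seed = 4L)
  expect_identical(nrow(truthVariants(empty)), 0L)
})

test_that("error-free reads match a true haplotype exactly", {
  sim <- smallSimulation(seed = 8L, perCycleQuality = 41L,
                         perCycleTrueError = 0)
  pu <- buildPileup(sim@genomeReads, sim@genome)
  o <- observations(pu)
  tv <- truthVariants(sim@truth)
  mm <- o[o$base != o$ref, ]
  # every mismatch sits at a planted variant locus
  expect_true(all(lociKey(mm$chrom, mm$pos) %in%
                  lociKey(tv$chrom, tv$pos)))
  # and carries the planted alternative allele
  alt <- setNames(tv$alt, lociKey(tv$chrom, tv$pos))
  expect_true(all(mm$base == alt[lociKey(mm$chrom, mm$pos)]))
})

test_that("empirical mismatch rate at quality 20 is about one percent", {
  sim <- smallSimulation(seed = 12L, hetRate = 0, perCycleQuality = 20L)
  o <- observations(buildPileup(sim@genomeReads, sim@genome))
  p <- mean(o$base != o$ref)
  n <- nrow(o)
  expect_gt(p, 0.01 - 3 * sqrt(0.01 * 0.99 / n))
  expect_lt(p, 0.01 + 3 * sqrt(0.01 * 0.99 / n))
})

test_that("read counts per transcript follow the expression weights", {
  cfg <- simulationConfig(seed = 21L, genomeLength = 150000L,
                          nTranscripts = 12L,
                          exonsPerTranscript = c(1L, 3L),
                          exonLength = c(200L, 400L),
                          readsPerLane = 20000L, nLanes = 5L,
                          hetRate = 0, expressionSdLog = 1)
  gt <- simulateGenomeAndTranscripts(cfg)
  truth <- plantVariants(gt$genome, gt$models, hetRate = 0, seed = 1L)
  rs <- sampleReads(gt$genome, gt$models, truth, cfg)
  obs <- table(factor(alignments(rs$transcriptReads)$rname,
                      levels = transcripts(gt$models)$txId))
  expected <- rs$expressionWeights * sum(obs)
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs),
                                            p = rs$expressionWeights))
  expect_gt(gof$p.value, 0.001)
  expect_gt(stats::cor(as.integer(obs), expected), 0.99)
})

test_that("PCR duplicates are exact copies under fresh ids", {
  sim <- smallSimulation(seed = 14L, duplicateRate = 0.4)
  r <- alignments(sim@genomeReads)
  dup <- r[grepl("dup$", r$readId), ]
  expect_gt(nrow(dup), 0L)
  orig <- r[match(sub("dup$", "", dup$readId), r$readId), ]
  expect_identical(dup$seq, orig$seq)
  expect_identical(dup$blockStarts, orig$blockStarts)
  expect_identical(dup$laneId, orig$laneId)
})

test_that("transcript- and genome-space reads describe the same bases", {
  sim <- smallSimulation(seed = 17L)
  tr <- alignments(sim@transcriptReads)
  gr <- alignments(sim@genomeReads)
  expect_identical(tr$readId, gr$readId)
  t <- transcripts(sim@models)
  strand <- setNames(t$strand, t$txId)
  minus <- strand[tr$rname] == "-"
  expect_identical(gr$strand, unname(ifelse(minus, "-", "+")))
  i <- which(minus)[1]
  expect_identical(
    gr$seq[i],
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tr$seq[i]))))
  j <- which(!minus)[1]
  expect_identical(gr$seq[j], tr$seq[j])
  # aligned length preserved by the projection
  wsum <- function(s) vapply(strsplit(s, ","), function(v)
    sum(as.integer(v)), numeric(1))
  expect_identical(wsum(gr$blockWidths), wsum(tr$blockWidths))
})

test_that("pooling tags individuals and unions the truth", {
  sims <- lapply(1:3, function(i) {
    cfg <- simulationConfig(seed = 50L, genomeLength = 60000L,
                            nTranscripts = 6L, readsPerLane = 500L,
                            nLanes = 2L, hetRate = 0.005,
                            expressionSdLog = 0)
    gt <- simulateGenomeAndTranscripts(cfg)
    truth <- plantVariants(gt$genome, gt$models, hetRate = 0.005,
                           seed = 100L + i)
    reads <- sampleReads(gt$genome, gt$models, truth, cfg,
                         seed = 200L + i)
    new("SimulatedDataset", genome = gt$genome, models = gt$models,
        truth = truth, genomeReads = reads$genomeReads,
        transcriptReads = reads$transcriptReads, config = cfg)
  })
  pool <- poolIndividuals(sims)
  expect_identical(nReads(pool$genomeReads),
                   sum(vapply(sims, function(s) nReads(s@genomeReads),
                              integer(1))))
  expect_true(all(grepl("^ind[123]\\.", alignments(pool$genomeReads)$readId)))
  nTruth <- vapply(sims, function(s) nrow(truthVariants(s@truth)),
                   integer(1))
  expect_identical(nrow(pool$truth), sum(nTruth))
  # union loci = sum minus shared sites
  keys <- lapply(sims, function(s) {
    tv <- truthVariants(s@truth)
    lociKey(tv$chrom, tv$pos)
  })
  expect_identical(nrow(pool$unionLoci),
                   length(unique(unlist(keys))))
  # k = 1 is the identity
  one <- poolIndividuals(sims[1])
  expect_identical(alignments(one$genomeReads),
                   alignments(sims[[1]]@genomeReads))
  # mismatched references are rejected
  other <- sims[[2]]
  other@genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 100)))
  expect_error(poolIndividuals(list(sims[[1]], other)), "different")
})

test_that("simulated SAM output survives a parse round trip", {
  sim <- smallSimulation(seed = 23L)
  keep <- new("AlignmentSet",
              reads = alignments(sim@genomeReads)[1:300, ])
  f <- withr::local_tempfile(fileext = ".sam")
  writeSAM(sortAlignments(keep), f)
  back <- readSAM(f)
  expect_identical(nReads(back), 300L)
  puA <- buildPileup(sortAlignments(keep), sim@genome)
  puB <- buildPileup(back, sim@genome)
  expect_identical(nrow(observations(puA)), nrow(observations(puB)))
})
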