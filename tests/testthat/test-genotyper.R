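test_that("Phred conversion follows 10^(-q/10) with a defensive cap", {
  expect_identical(phredToErrorProb(10L), 0.1)
  expect_identical(phredToErrorProb(20L), 0.01)
  expect_identical(phredToErrorProb(0L), 0.75)  # capped below 1
  expect_identical(phredToErrorProb(c(30L, 40L)), c(1e-3, 1e-4))
  expect_error(phredToErrorProb(-1L), "negative")
})

test_that("per-read likelihoods match the three-case formula", {
  expect_equal(readLikelihood("A", 0.01, "AA"), 0.99)
  expect_equal(readLikelihood("C", 0.01, "AA"), 0.01 / 3)
  expect_equal(readLikelihood("A", 0.01, "AC"), 0.5 - 0.01 / 3)
  # error-free heterozygote: both haplotypes sampled equally
  expect_equal(readLikelihood("A", 1e-12, "AC"), 0.5, tolerance = 1e-9)
  # unordered genotype symmetry
  expect_equal(readLikelihood("G", 0.2, "GT"),
               readLikelihood("G", 0.2, "TG"))
  expect_error(readLikelihood("N", 0.01, "AA"), "excluded")
})

test_that("likelihoods normalize over the four bases for every genotype", {
  for (eps in c(1e-4, 1e-3, 0.01, 0.1, 0.25, 0.5, 0.74)) {
    for (g in GENOTYPES) {
      s <- sum(vapply(c("A", "C", "G", "T"),
                      function(b) readLikelihood(b, eps, g), numeric(1)))
      expect_equal(s, 1, tolerance = 1e-12)
    }
  }
})

test_that("priors put (1-h)/4 on homozygotes and h/6 on heterozygotes", {
  p <- genotypePriors(0.001)
  expect_equal(unname(p["AA"]), 0.24975)
  expect_equal(unname(p["AC"]), 0.001 / 6)
  for (h in c(1e-4, 0.001, 0.01, 0.5)) {
    expect_identical(sum(genotypePriors(h)), 1)
  }
})

test_that("the single-observation worked example reproduces by hand", {
  post <- genotypePosterior("A", 20L, h = 0.001)
  expect_equal(unname(post["AA"]), 0.98901, tolerance = 1e-5)
  # unnormalized mass is exactly 1/4 by base symmetry
  pr <- genotypePriors(0.001)
  unnorm <- sum(vapply(GENOTYPES, function(g) {
    pr[g] * readLikelihood("A", 0.01, g)
  }, numeric(1)))
  expect_equal(unnorm, 0.25, tolerance = 1e-12)
})

test_that("zero observations return the prior", {
  post <- genotypePosterior(character(0), integer(0), h = 0.01)
  expect_equal(unname(post), unname(genotypePriors(0.01)))
})

test_that("streaming log-space posteriors match brute-force enumeration", {
  set.seed(123)
  for (rep in 1:60) {
    n <- sample(0:10, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    quals <- sample(2:40, n, replace = TRUE)
    oracle <- bruteForcePosterior(bases, quals)
    mine <- genotypePosterior(bases, quals)
    expect_equal(unname(mine), unname(oracle), tolerance = 1e-9)
    if (n > 0) {
      pu <- makePileup(bases, quals)
      vec <- posteriorMatrix(genotypePosteriors(pu))
      expect_equal(unname(vec[1, ]), unname(oracle), tolerance = 1e-9)
    }
  }
})

test_that("relabeling bases consistently permutes the posterior", {
  bases <- c("A", "A", "C", "G")
  quals <- c(30L, 25L, 12L, 7L)
  perm <- c(A = "T", C = "G", G = "A", T = "C")
  p1 <- genotypePosterior(bases, quals)
  p2 <- genotypePosterior(unname(perm[bases]), quals)
  permGt <- canonicalGenotype(paste0(perm[substr(GENOTYPES, 1, 1)],
                                     perm[substr(GENOTYPES, 2, 2)]))
  expect_equal(unname(p2[permGt]), unname(p1), tolerance = 1e-12)
})

test_that("posterior of the truth approaches 1 monotonically with coverage", {
  post <- vapply(c(2, 5, 10, 20, 40), function(n) {
    p <- genotypePosterior(rep(c("A", "C"), n), rep(35L, 2 * n))
    unname(p["AC"])
  }, numeric(1))
  expect_false(is.unsorted(post))
  expect_gt(post[length(post)], 0.999999)
})

test_that("calling picks the argmax with conservative tie-breaking", {
  # strong homozygous non-reference
  pu <- makePileup(rep("C", 20), rep(30L, 20), ref = "A")
  cl <- calls(callVariants(pu, emitReference = TRUE))
  expect_identical(cl$genotype, "CC")
  expect_true(cl$isVariant)
  expect_gt(cl$variantPosterior, 1 - 1e-10)

  # the worked single-observation example is not a variant
  pu1 <- makePileup("A", 20L, ref = "A")
  cl1 <- calls(callVariants(pu1, emitReference = TRUE))
  expect_identical(cl1$genotype, "AA")
  expect_false(cl1$isVariant)
  expect_equal(cl1$variantPosterior, 0.01099, tolerance = 1e-5)

  # N observations are excluded; an all-N column yields no call
  puN <- makePileup(c("N", "N"), c(30L, 30L), ref = "A")
  expect_identical(nrow(calls(callVariants(puN, emitReference = TRUE))),
                   0L)

  # reference N loci are never called
  puRefN <- makePileup("A", 30L, ref = "N")
  expect_identical(nrow(calls(callVariants(puRefN,
                                           emitReference = TRUE))), 0L)
})

test_that("an exact posterior tie resolves toward homozygous reference", {
  # balanced evidence for both alleles overrides the sparse-het prior
  pu <- makePileup(c("A", "A", "C", "C"), rep(20L, 4), ref = "C")
  cl <- calls(callVariants(pu, emitReference = TRUE))
  expect_identical(cl$genotype, "AC")
  # true tie: no observations at all is not emitted by callVariants;
  # use callGenotypes on a posterior equal to the prior
  gp <- new("GenotypePosteriors",
            loci = data.frame(chrom = "chr1", pos = 0L, ref = "G",
                              coverage = 0L),
            logLik = matrix(0, 1, 10, dimnames = list(NULL, GENOTYPES)),
            posterior = matrix(genotypePriors(0.001), 1, 10,
                               dimnames = list(NULL, GENOTYPES)),
            h = 0.001)
  cl0 <- calls(callGenotypes(gp))
  expect_identical(cl0$genotype, "GG")  # among 4 equal homozygotes
  expect_false(cl0$isVariant)
})

test_that("callVariants demands sorted pileups and is deterministic", {
  o <- observations(makePileup(c("A", "C"), c(30L, 30L)))
  o$pos <- c(10L, 5L)
  expect_error(callVariants(new("PileupTable", observations = o)),
               "sorted")
  pu <- makePileup(rep("C", 6), rep(25L, 6), pos = c(1L, 1L, 5L, 5L, 9L, 9L),
                   ref = "T")
  expect_identical(calls(callVariants(pu)), calls(callVariants(pu)))
  expect_identical(nrow(calls(callVariants(pu, emitReference = TRUE))), 3L)
})

test_that("variant tables and VCF exports round-trip the fields they keep", {
  pu <- makePileup(rep(c("A", "G"), 8), rep(33L, 16), ref = "A",
                   pos = 42L)
  cv <- callVariants(pu, emitReference = TRUE)
  f <- withr::local_tempfile()
  writeCalls(cv, f)
  back <- readCalls(f)
  expect_identical(calls(back)$genotype, calls(cv)$genotype)
  expect_identical(calls(back)$pos, calls(cv)$pos)
  expect_equal(calls(back)$variantPosterior, calls(cv)$variantPosterior,
               tolerance = 1e-4)
  vcf <- withr::local_tempfile()
  writeVCF(cv, vcf)
  lines <- grep("^#", readLines(vcf), invert = TRUE, value = TRUE)
  expect_identical(length(lines), 1L)
  expect_match(lines, "^chr1\t43\t\\.\tA\tG\t")
  expect_match(lines, "0/1$")
})
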