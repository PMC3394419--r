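---
title: "Calling expressed SNVs from RNA-Seq: models and methods"
author: "snvq package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling expressed SNVs from RNA-Seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvq)
```

## The problem

RNA-Seq reads carry the expressed portion of an individual's genome, so
they can be used to detect and genotype single nucleotide variants
(SNVs) in transcribed regions at a fraction of the cost of genome
sequencing. Two obstacles make this harder than genomic variant
calling. First, mRNA reads that span splice junctions do not align
contiguously to the genome, while alignment against a transcript
library misses reads from unannotated genes; neither reference alone
recovers all mappable reads. Second, coverage follows expression:
read depth varies by orders of magnitude between transcripts, so a
caller must quantify its confidence per locus rather than rely on a
depth heuristic.

`snvq` addresses both: a *dual-reference merging* step reconciles
alignments computed independently against the genome and against a
transcript library, and the *SNVQ* Bayesian genotyper converts base
qualities into posterior probabilities over all ten diploid genotypes.
Everything is exercisable end to end on synthetic data produced by the
package's own simulator.

## Dual-reference merging

Reads are mapped (by any external mapper) twice: against the genome and
against a spliced transcript library. Transcript-space alignments are
transferred to genomic coordinates through the exon map of their
transcript, splicing the alignment into blocks where it crosses exon
junctions; on reverse-strand transcripts the strand is flipped and the
bases reverse-complemented. A read hitting several isoforms that share
a genomic location is not genuinely ambiguous: if all of its transferred
alignments have the same chromosome, strand and block structure, one is
kept and the read counts as uniquely mapped. Collapsing runs *before*
the read's mapping status enters the decision rules.

Each read then has a (genome status, transcript status) pair in
\{unique, multiple, unmapped\}, plus an agreement bit for dual-unique
reads. Two rule sets combine them:

| genome | transcript | agree | hard | soft |
|--------|-----------|-------|------|------|
| unique | unique | yes | keep | keep |
| unique | unique | no  | drop | drop |
| unique | multiple | — | drop | keep |
| unique | unmapped | — | keep | keep |
| multiple | unique | — | drop | keep |
| unmapped | unique | — | keep | keep |
| all other rows | | | drop | drop |

*Hard* merging demands dual-unique agreement or one-sided uniqueness
against an unmapped other side; *soft* merging relaxes uniqueness to
"unique on at least one side". By construction every read kept by hard
merging is kept by soft merging; the package asserts this invariant
property-style in its tests.

Two points the rules leave open were fixed as follows. *Agreement* is
strict equality of chromosome, strand and leftmost genomic position —
block structures may legitimately differ between a contiguous genomic
alignment and a spliced transfer, so the start is the robust common
denominator. When both sides are unique and agree, the genome record is
emitted (it is the mapper's original genomic alignment); when only one
side is unique, that side is emitted. Isoform collapsing requires
identical block structure, not mere overlap, which keeps paralog-like
near-hits ambiguous.

## The SNVQ genotyper

At a locus $i$ let $R_i$ be the aligned bases spanning it. For a read
$r$ with base $r(i)$ and Phred quality $q(i)$, the error probability is
$\varepsilon = 10^{-q(i)/10}$. Writing the genotype as an unordered
allele pair $G = \{H, H'\}$, the per-read likelihood is

$$
P(r \mid G) =
\begin{cases}
1 - \varepsilon & G \text{ homozygous}, \; r(i) = H \\
\varepsilon / 3 & r(i) \notin \{H, H'\} \\
\tfrac12 - \varepsilon/3 & \text{otherwise,}
\end{cases}
$$

i.e. an erroneous call is uniformly one of the other three bases and
the two haplotypes of a heterozygote are sampled with equal
probability. For every $G$ and $\varepsilon$ the four base
probabilities sum to one — asserted over a grid in the tests. Reads are
independent, so $P(R_i \mid G) = \prod_{r} P(r \mid G)$, and the prior
puts $(1-h)/4$ on each homozygous and $h/6$ on each heterozygous
genotype, with heterozygosity rate $h = 0.001$ by default. The
posterior follows by Bayes' rule over the ten genotypes; a *variant* is
called when the posterior argmax differs from homozygous reference, and
the *variant posterior* $1 - P(\{\mathrm{ref},\mathrm{ref}\} \mid R_i)$
is the quantity swept by the sensitivity/specificity curves.

Numerical choices: likelihoods accumulate in log space and normalize
with log-sum-exp, because products of hundreds of small terms
underflow; $\varepsilon$ is capped at 0.75 so the likelihood terms stay
positive and informative at very low qualities (quality-0/1 calls are
discarded before genotyping anyway, following the method's data
handling); exact posterior ties break toward homozygous reference and
then lexicographically, favoring the conservative no-variant outcome.
Bases called `N`, and loci whose reference base is `N`, never reach the
model. Zero-coverage loci are not emitted (with no data the posterior
equals the prior, which carries no evidence). The prior is
deliberately uniform across positions and strands and does not favor
the reference allele or distinguish transitions from transversions —
the contrast with reference-biased priors is intentional, since it lets
the same model score all ten genotypes on equal footing.

The vectorized implementation aggregates observations into
(locus, base, quality) count triples before computing the ten genotype
log-likelihoods; the tests verify it against a direct, per-column
enumeration of prior × product on random small columns to $10^{-9}$
relative error.

## Data curation

Three curation strategies target the systematic error structure of
short-read sequencers:

* **Aligned-read trimming** (`trimAlignments`, defaults 1 leading and
  10 trailing cycles) masks the read extremes where de-phasing
  concentrates miscalls. Masked bases are excluded from pileups but the
  alignment itself is untouched — trimming aligned reads rather than
  raw reads keeps correctly sequenced trimmed bases available for
  placing the read. Cycles are counted 5'→3', i.e. for a reverse-strand
  alignment the trailing mask lands on the genomic left. For 33 bp
  reads the defaults discard exactly one third of the aligned bases.
* **Start-locus cap** (`startLocusFilter`) keeps at most $x$ reads per
  (chromosome, start, strand) key, suppressing PCR amplification spikes
  and flattening expression-driven coverage. Strand is part of the key
  because opposite-strand reads starting at one locus cannot be PCR
  copies of each other. The retained reads are the $x$ with highest
  mean base quality, ties broken by read id, making the filter
  deterministic and order-independent.
* **Call vetoes** (`laneSupportFilter`, `minAltCountFilter`) reject a
  variant call unless each called non-reference allele is seen in at
  least $k$ distinct lanes, or at least $k$ times overall. They are
  applied after genotyping as call-level vetoes rather than by removing
  observations, so the posterior itself is unchanged; the veto is
  interpreted per non-reference allele.

The `mismatchProfile` diagnostic reports the fraction of aligned reads
mismatching the reference at each cycle; a flat profile indicates
unbiased errors, a 3' ramp is the de-phasing signature that motivates
trimming. It runs before trimming and therefore includes masked bases.

## Evaluation framework

Against a gold-standard genotype table, a *genotyping* true positive is
a correctly called heterozygous or homozygous non-reference genotype; a
call asserting any allele the gold genotype does not carry is a false
positive (this single rule covers both the reference-genotype case and
the phantom-reference-allele case of a homozygous variant called
heterozygous); a heterozygous gold locus called homozygous-within-gold,
or not called at all, is neutral, since it may reflect nothing more
than missing coverage of one allele. Under *detection* scoring only
variant-versus-reference matters: any variant call at a non-reference
gold locus is a true positive regardless of the exact genotype. One
edge case the definitions do not cover — gold heterozygous, call
asserting a third allele (gold \{A,C\}, call \{G,G\}) — is scored as a
genotyping false positive here, since a nonexistent allele is asserted.
Gold loci with no call are neutral for curve purposes; the
coverage-binned view counts uncalled or miscalled gold variants as
false negatives, which is the view that exposes low-expression
sensitivity loss.

`accuracyCurve` sweeps a minimum variant posterior and reports TP/FP
counts, both provably non-increasing in the threshold.
`exonCoverage` computes average per-exon coverage (aligned bases
overlapping the exon divided by exon length), the quantity proportional
to RPKM; `rpkmToCoverage` converts via
$\mathrm{cov} = \mathrm{RPKM} \times T \times L \times 10^{-9}$ for $T$
total mapped reads of length $L$. `coverageBinnedAccuracy` bins gold
loci by the coverage of their first containing exon; bin edges are
user-supplied.

## The simulator

`simulateDataset` generates, deterministically under a seed: a random
genome; non-overlapping multi-exon genes on both strands; planted
variants at per-exonic-site rate $h$ (default 0.001, matching the
model's prior assumption), of which one third are homozygous
non-reference — roughly the population expectation for a diploid — and
heterozygous variants sit on a random haplotype; and reads drawn from
the two transcript haplotypes with expression weights that are
lognormal across transcripts (`expressionSdLog = 0` gives even
per-base coverage). Defaults emulate a 2009-era Illumina transcriptome
run: 33 bp reads, 7 lanes, constant reported quality Q30.

Sequencing errors are injected per cycle, each error uniformly one of
the other three bases. The *reported* quality profile and the *true*
per-cycle error rate are configured independently: by default the true
rate is the Phred-implied one (well-calibrated qualities), but a 3'
ramp can be injected beyond what the reported qualities admit. That
miscalibration is what makes aligned-read trimming matter — a
quality-aware Bayesian caller already discounts honestly-reported low
qualities, so only errors the qualities do not admit create confident
false positives. PCR duplicates are exact copies of a read (same
alignment, bases and lane) under a fresh id, at a configured rate.
Reads are emitted with truth alignments in both transcript and genomic
coordinates, so the merging and genotyping machinery are testable
without running a mapper; `perturbMappingStatus` fabricates the
multiple/unmapped decision-table categories.

What the simulator does *not* model: antisense/strand-flipped read
sampling (reads are sense-strand), isoform sharing between transcripts,
indels, machine-specific error motifs beyond the per-cycle profile, and
mapping errors (truth alignments are exact). Passing tests therefore
demonstrate the correctness of the implemented models under their own
assumptions, not performance on real data with mapper noise.

## Validation studies and problem sizes

The acceptance studies (re-runnable via `scripts/acceptance.R`) use
problem sizes chosen to give stable statistics on a single CPU:

* **Parameter recovery** — 200 five-exon transcripts of 5 kb (1 Mb
  exonic), $h = 0.001$ (~1000 planted variants), even expression, mean
  coverage 25×, Q30. Genotyping accuracy at planted loci exceeds 99%.
  The zero-false-positive check at variant posterior ≥ 0.99 is
  evaluated at loci meeting the study's ≥ 20× coverage condition:
  transcript termini necessarily fall below any finite mean coverage
  (a terminal base is reachable only by reads starting at one
  position), and at coverage 1 a single miscalled base is
  indistinguishable from a true allele — the situation the
  minimum-alt-count curation filter exists for.
* **Curation** — 100 three-exon transcripts of 2.1 kb, ~24×, reported
  quality flat Q30 with true error $0.001 + 0.12\,((c-1)/32)^6$ at
  cycle $c$: a sharply 3'-concentrated, miscalibrated ramp. The
  mismatch profile rises monotonically toward the 3' end and default
  trimming strictly reduces false positives at a fixed 0.99 threshold.
  A separate run with 50% PCR duplicates verifies that the $x = 1$
  start-locus filter removes all duplicate excess.
* **Pooling** — three individuals simulated on one genome and
  annotation with shared lognormal expression (sdlog 1.5), ~12× each,
  independently planted variants. Pooling dilutes a private
  heterozygous allele to expected frequency 1/6, so at a fixed 0.99
  threshold the pooled sample needs proportionally more supporting
  reads per variant; detection sensitivity on the pooled reads is
  markedly below every individual's own.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `h` | 0.001 | heterozygosity rate; prior mass $h/6$ per heterozygous genotype |
| `epsMax` | 0.75 | cap on the per-base error probability |
| `minBaseQuality` | 2 | pileup floor; discards quality-0/1 calls |
| `trimLeading`, `trimTrailing` | 1, 10 | cycles masked per aligned read |
| `maxPerStart` | off (1 or 3 typical) | reads kept per start locus |
| `minLanes`, `minAltObservations` | off (2–3 typical) | variant-call vetoes |
| `minVariantPosterior` | 0 | call-emission threshold on $1 - P(\mathrm{hom\ ref})$ |

## Limitations

The caller is diploid and single-sample: no indels, no somatic
paired designs, no phasing, no quality recalibration. The merge rules
assume single-end reads with at most the unique/multiple/unmapped
status trichotomy from the upstream mapper. SAM support covers the
fields this toolkit uses (text SAM, single-end records, NH/XT/RG tags);
binary BAM/CRAM and full-spec SAM are out of scope, as is GFF3
annotation ingestion — the tab-separated transcript table documented in
`readTranscriptModels` is the supported dialect.
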