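---
title: "Methods: joint differential expression and polymorphism from pooled RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint differential expression and polymorphism from pooled RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and design

pooldiff re-implements, as a tested and reusable pipeline, an analysis
design in which whole-organism RNA pools of a selected strain and its
susceptible parent are sequenced (two technical cDNA libraries per pool)
and the same reads serve two purposes: per-transcript counts for
differential-transcription testing, and per-site allele counts for pooled
allele-frequency comparison. Read alignment, transcript re-annotation and
GO re-annotation are deliberately upstream of this package: its inputs are
a gene-level count table with exonic lengths, a library manifest with total
mapped reads, per-strain pileup allele counts, a reference genome with GFF3
gene models, and an optional gene-to-category map.

## The expression model

Counts for one transcript in two libraries are assumed Poisson with a
shared unknown rate under the null. With a flat prior on the rate, the
posterior predictive probability of seeing $y$ reads in a library of $N_2$
total mapped reads given $x$ reads in one of $N_1$ is

$$p(y \mid x) \;=\; \binom{x+y}{y}\,
  \frac{N_2^{\,y}\, N_1^{\,x+1}}{(N_1+N_2)^{x+y+1}},$$

the negative-binomial mass at $y$ with size $x+1$ and success probability
$N_1/(N_1+N_2)$. `ac_pmf()` evaluates it in log space via `lchoose`;
`ac_test()` accumulates both tails directly in log space. The upper tail is
summed blockwise from $y$ upward until the remaining (geometrically
bounded) mass is negligible, rather than as $1 - P(Y < y)$ — the
subtraction floors at the double-precision resolution of 1 (about
$10^{-13}$ after thousands of accumulated terms) and would make the
$10^{-15}$ significance threshold unreachable for strongly shifted
transcripts.

The two-sided p-value is twice the smaller tail (each including the
observed count), capped at 1. The sidedness construction is a design
choice: doubling the smaller tail is the standard discrete two-library
convention, and one-sided modes remain available via `alternative=`.
Because the test is discrete and conservative near its mode, the null
type-I rate at $p<0.05$ sits at or below 0.05; the test suite asserts the
bound, not equality.

Technical replicates of one strain are pooled by summing counts and
library totals after an r² concordance check (warning below 0.9, no
abort). Pooling models the actual design — both libraries derive from one
bench-pooled RNA sample — so there is no biological-replicate dispersion to
estimate, and none is modelled. This is the main statistical limitation of
the design: the test sees technical sampling variance only.

Key expression parameters, with defaults:

* `detect_min = 0.5` RPKM (strict `>`, in at least one strain): detection
  filter applied before testing; the BH family is the detected transcripts
  of one comparison.
* `alpha_de = 1e-15`, `fc_min = 2`: call gates on adjusted p-value and fold
  change in either direction.
* `epsilon = 0.05` RPKM (one tenth of the detection threshold): fold change
  is computed on floored RPKM, $(R_{sel}+\epsilon)/(R_{sus}+\epsilon)$, so
  a transcript silent in one strain yields a finite, large fold change
  instead of infinity. The source analysis did not state its fold-change
  formula; this floor is the package's choice and is configurable.

## SNP calling and differential polymorphism

Pileup rows carry per-strain A/C/G/T counts and a per-site quality score.
A site yields a SNP record when it is outside homopolymer masks, its
quality reaches the configured floor in every strain, at least one strain
has total coverage strictly above 20 reads, and a non-reference allele is
observed. The variant allele is the most frequent non-reference allele
summed over strains, ties broken in A<C<G<T order; remaining alleles are
dropped from the frequency denominator, so frequencies are
$100\,v/(r+v)$. A zero $r+v$ denominator is flagged as `NA`, never
silently 0.

Homopolymer masking removes positions inside maximal single-base runs of
length ≥ 11 (runs "longer than 10") plus one flanking position on each
side.

A SNP is *differential* for a comparison when the **sum** of the two
strains' coverages at the site is ≥ 30 reads and the absolute frequency
difference is ≥ 40 percentage points. The summed reading of "total
coverage" is deliberate: published per-strain coverages as low as 9 reads
appear among retained differential SNPs, which is only consistent with
summing. Both thresholds, and the ≥ comparison, are configurable.

The per-site quality column is a generic stand-in for caller-internal
confidence scores; its floor defaults to permissive (0) because no
transferable semantics exist for such scores. Per-base quality filtering is
assumed done upstream, by whatever produced the pileup counts. Only
biallelic substitutions are analysed; adjacent qualifying SNPs are reported
individually (a merged dinucleotide annotation is a presentation question,
not a calling one).

## Effect annotation

Gene models (gene/mRNA/exon/CDS/UTR with ID/Parent attributes) are read
through `rtracklayer`; intervals are held 1-based inclusive in
IRanges-style data frames, the Bioconductor convention, and GFF3 I/O does
no coordinate shifting. Each SNP gets exactly one class out of
`five_prime_UTR, synonymous, non_synonymous, three_prime_UTR, other`;
introns and intergenic positions are `other`, with the finer region kept
separately. Intergenic SNPs within 1 kb of a gene (configurable; no
published distance exists for "close to gene boundaries") are linked to the
nearest gene.

For coding positions the reference codon is read from the spliced CDS —
codons split across introns are handled naturally — and the variant base is
substituted after complementing for minus-strand genes, since pileup
alleles are reported on the forward genome strand. Translation uses the
standard nuclear genetic code; stop gain/loss is non-synonymous with `*` as
the amino-acid letter. Spliced-CDS coordinates count from the annotated CDS
start (position 1 = first base of the start codon), so the amino-acid index
is $\lceil \mathrm{cds\_pos}/3 \rceil$. Published cDNA positions that
include an unannotated 5'UTR offset will differ from CDS-relative
positions; the package always reports the latter. A SNP overlapping two
genes (impossible in the synthetic annotation, possible in real ones) is
annotated once per gene and flagged.

The annotation is audited in the test suite by an independent brute-force
oracle: mutate the genome, re-extract and re-translate the whole protein
with a separate translation implementation, and diff — agreement is
asserted at 100% for every synthetic coding SNP on both strands.

## Enrichment

Category and GO-term over-representation use the one-sided Fisher exact
test (hypergeometric upper tail) of the selected gene set against the
universe of all detected genes, BH-corrected across the terms tested for
one selected set, threshold 0.05. One-sided testing is used for GO terms as
well as categories; GO ancestry propagation is not performed (terms are
tested as mapped). The non-synonymous burden comparison contrasts
candidate genes against all other genes carrying qualifying SNPs on the
2×2 table of non-synonymous versus other effects.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` generates, from one seed, a toy genome (4 contigs of
150 kb by default) with 200 non-overlapping multi-exon genes on both
strands (CDS a multiple of three, start and stop codons, 5'/3' UTRs), one
intergenic homopolymer run of 14 bases to exercise the mask, Poisson
counts for 3 strains × 2 technical libraries of $10^6$ mapped reads each
(per-gene rates lognormal with median 200 reads; technical replicates share
one rate), 40 genes shifted by $\log_2\mathrm{FC}=\pm2$ in both selected
strains, and 240 variant sites placed so that every effect class occurs on
both strands, with per-strain coverage Poisson(100) and binomial alternate
counts at true frequencies cycling through a 50-point upward shift, a null
pattern, and a 50-point downward shift. One site is forced inside the
homopolymer run and one below the coverage threshold, so the filters are
always exercised. These defaults are the package's study conditions; the
acceptance script runs them unchanged.

The generator works at count level: no reads, no alignment, no sequencing
error, no base-quality model, no indels, no multi-isoform genes, no
overdispersion between biological replicates (the design has none). Passing
tests therefore demonstrate the correctness of the statistics, filters and
annotation logic on data matching the pipeline's own assumptions — not
robustness to alignment artefacts or biological-replicate variance in real
data.

Problem sizes in the tests and acceptance script were chosen as the
smallest that make the Monte-Carlo assertions stable: 2,000 genes for null
calibration, 300 genes (100 planted) for expression recall, 220 sites for
SNP recall and frequency correlation, 120 sites for the annotation audit.

## Numerical and reporting conventions

* Report percentages and frequencies round half away from zero to one
  decimal (`round_half_up()`), matching table-style reporting; internal
  computation is unrounded.
* Direction labels (`over`/`under`) are defined relative to the
  susceptible parent, whose pooled count is always the test's $x$.
* Degenerate inputs fail loudly: empty detected set warns and returns an
  empty result; an undefined correlation or frequency, a missing strain, a
  reference-base mismatch and an over-full simulation configuration are
  errors naming the offender.
* Byte-identical reproducibility: all randomness derives from the single
  configured seed (stage-specific offsets), and identical configurations
  reproduce identical output files, asserted by hash in the tests.
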