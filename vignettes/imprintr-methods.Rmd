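---
title: "Methods: allelic imprint discovery in reciprocal hybrid embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic imprint discovery in reciprocal hybrid embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the design decisions taken
where the analysis was genuinely open, and what the synthetic-data
generator does and does not emulate. It states no empirical result that
the package's tests and `scripts/acceptance.R` do not themselves compute.

## The experimental design being modeled

Two inbred strains (B6 and CAST) are crossed in both orientations; the
maternal strain is written first, so B6/CAST and CAST/B6 are reciprocal
hybrids. Reads overlapping a strain-discriminating SNP can be assigned to
a parental genome. A region whose allelic skew follows the *parent*
across the reciprocal crosses is imprinted; one whose skew follows the
*strain* (it switches parent between crosses) is strain-specific. A third
cross, matDKO/CAST, uses mothers whose oocytes carry a conditional
*Dnmt3a/Dnmt3b* double knockout and therefore transmit no maternal DNA
methylation: imprints that dissolve in this cross are canonical
(gDMR-dependent), imprints that persist are non-canonical (or canonical
paternal, distinguished by a known paternal-gDMR annotation). The matDKO
maternal genome is predominantly B6 with roughly 15% residual
129-derived segments, which motivates the two-pass read assignment.

## Allele assignment

A read's observed bases at SNP positions give a three-way sort: genome1
iff every informative observation matches the genome1 base (and at least
one SNP is overlapped), symmetrically genome2, otherwise unassigned. A
base matching neither genome is treated as a conflict (unassigned), not
ignored — the conservative reading of a three-way sort. Observations at
positions absent from the SNP table are ignored. For matDKO samples,
pass 1 uses the B6/CAST table from which positions where the 129 allele
equals the CAST allele have been removed (such positions would
misassign maternal 129 reads to the paternal genome); reads left
unassigned are re-evaluated against a 129/CAST table, 129 calls join the
maternal set, and CAST calls from either pass form the paternal set. The
handling of pass-2 CAST calls is not fully determined by the design; this
package merges them into the paternal set, which is correct for
CAST-origin reads but can mislabel B6-origin reads that overlap only
129-only SNP positions (where B6 = CAST). These are rare — they require a
read with no informative pass-1 SNP at all — and the per-read assignment
itself is exactly oracle-checked in the test suite.

## The allelic-bias test

The null hypothesis everywhere is a maternal allelic proportion
$\pi = 0.5$ for a region's (mat, pat) read counts. Replicates of the same
region share $\pi$ but show extra-binomial variation; we model the
maternal count of replicate $j$ as

$$m_j \sim \mathrm{BetaBinomial}(n_j,\ \pi,\ \rho),$$

with intraclass correlation $\rho$ shared across regions. $\rho$ is
estimated once per cross by method of moments from the excess variance of
replicate-level allelic fractions over the binomial expectation, floored
at zero, and averaged across informative regions. The test is then a
likelihood-ratio test of $\pi = 0.5$ against the MLE (one-dimensional
optimization of the beta-binomial likelihood), with p from
$\chi^2_1$. With a single replicate, or $\rho = 0$, the test reduces to a
two-sided exact binomial on the pooled counts, with the two-sided p
defined by doubling the smaller tail and capping at 1 — a definition that
is exactly reproducible by pmf enumeration, which the tests do.

The original analysis used a named count-model package for this step;
re-specifying the test as exact-binomial / beta-binomial LRT makes it
self-contained and oracle-testable while keeping the same decision
boundary (BH-adjusted q < 0.05 within one cross × assay × tissue family,
direction from the pooled fraction). Under the default simulation null
(π = 0.5, ρ = 0.02, depth 100, 2 replicates, 10,000 regions) the raw
rejection rate at 0.05 is computed by the acceptance script and the test
suite and falls within [0.03, 0.07].

Pseudocounts (c = 1) are used only for the displayed
$\log_2((\mathrm{pat}+c)/(\mathrm{mat}+c))$, never in testing. The
allelic ratio is $\mathrm{mat}/(\mathrm{mat}+\mathrm{pat})$ on
replicate-pooled (optionally size-factor-corrected) counts.

## Classification

* **Consensus**: significant in both reciprocal crosses with the same
  parental direction → imprinted (maternal/paternal); significant in both
  with switched direction → strain-specific (the favored strain is read
  off the cross orientation); significant in exactly one →
  `single_cross_only`, excluded from the consensus; neither → biallelic.
  Regions missing from either cross are `unresolved`, never dropped.
* **Canonical vs non-canonical**: "lost allelic bias in matDKO" is
  operationalized as *not significant AND matDKO allelic ratio within
  [0.35, 0.65]*. The ratio band guards against loss of power
  masquerading as loss of imprinting: a region that is merely
  underpowered in matDKO but still skewed stays `unresolved` instead of
  being called canonical. Retained bias with the same parental direction
  is canonical paternal when the region carries a paternal-gDMR
  annotation (matched by id or ≥ 1 bp overlap), otherwise non-canonical.
* **Gene assignment**: promoter = TSS − 1000 bp to TSS + 500 bp,
  strand-oriented (the analysis needs *a* promoter definition; this is a
  conventional asymmetric window and is configurable). Peaks overlapping
  several promoters report all of them; otherwise the nearest gene body
  within 10 kb, ties broken by distance then lexicographic gene id.
* Downstream feature analyses focus on paternal-direction non-canonical
  calls (the maternal ones arising inside large gDMR-controlled clusters
  have distinct regulation); maternal non-canonical calls are still
  emitted.

## LTR promoter criteria

Active promoter calls are conjunctive: (a) the LTR intersects an H3K4me3
peak (≥ 1 bp); (b) ≥ 5 same-strand reads over the LTR in ≥ 2 replicate
units, where each (sample, replicate) pair — across any supplied tissue —
is one unit (the pooled reading of the multi-tissue "and/or" design);
(c) at least one junction read whose splice donor lies inside the LTR;
(d) no junction read splicing into the LTR from a donor 5′ of it on the
transcript strand, with no distance bound — any such read marks the LTR
as a pass-through exon rather than an initiation site. Junctions are
stored genomically (left < right) and interpreted by transcript strand.
Unstranded LTRs are evaluated on both strands and take the
better-supported one, flagged. Chimeras require the acceptor inside an
annotated exon of a same-strand gene; the reported target exon is the
lowest transcription-order exon hit.

## Methylation and secondary imprints

Methylation is pooled over all CpGs within a region ± 500 bp per allele;
zero-coverage regions yield a missing level, never 0. A DMR needs both
alleles covered (≥ 10 calls and ≥ 5 CpGs each), |level difference| ≥ 0.3
and two-sided Fisher p < 0.05 on the pooled calls. These thresholds are
standard for bisulfite DMR screens; the underlying study reported its
DMR displays without numeric cutoffs, so the values here are this
package's contract and are configurable. A *secondary imprint* is a
region with no DMR and both alleles < 0.25 in gametes and
pre-implantation, plus a maternal DMR in post-implantation
extra-embryonic ectoderm; bi-allelic methylation ≥ 0.5 in the epiblast
sets the silencing flag. Missing stages suppress exactly the flags they
make undecidable. Allelic ChIP trajectories across pre-implantation
stages are summarized on raw counts: library-size scaling is
inappropriate there because the two alleles genuinely differ in global
signal abundance.

## The synthetic-data generator

The generator plants a complete architecture on 3 autosomes × 10 Mb:
1,000 peaks (70% biallelic, 10% + 10% strain-specific, 6% canonical
maternal, 1% canonical paternal, 3% non-canonical), each with a partner
gene whose TSS sits at the peak center. Every non-canonical peak carries
one solo ERVK LTR in intron 1 of its partner gene (the configuration of
the best-characterized chimeric locus), within 3 kb of the TSS and on
the same strand for 85% of cases; canonical peaks overlap CpG islands
annotated as gDMRs. Half of the non-canonical LTRs are active promoters;
60% of those (when on the gene's strand) splice onto exon 2 of the
partner gene, the rest initiate ncRNAs at unannotated acceptors. Three
decoy LTR types inside biallelic peaks each defeat exactly one promoter
criterion: too few reads, no donor junction, or an incoming upstream
junction.

Counts follow Poisson(100) total depth per peak per replicate with a
beta-binomial maternal share: π = 0.5 (biallelic), 0.9 toward the
favored allele otherwise, ρ = 0.02, 2 ChIP and 3 RNA replicates. The
defaults were chosen once as desk-scale analogues of a well-powered
embryo experiment: depth 100 gives near-complete power at π = 0.9 while
leaving the null calibration informative, and ρ = 0.02 is a mild,
realistic replicate overdispersion — the study data's true noise model is
unknown, so ρ is a calibration knob, not a claim. In the matDKO cross,
canonical-maternal peaks revert to π = 0.5; non-canonical and
canonical-paternal peaks retain their bias. SNPs are uniform at 1/150 bp
(B6/CAST) plus 1/450 bp 129-only positions; 30% of B6/CAST SNPs share
the CAST allele with 129; a contiguous 15% of each chromosome is
129-derived in the matDKO maternal genome. Methylation programs:
non-canonical LTRs 0.10/0.10 (gamete, pre-implantation), 0.80/0.10
(ExE, mat/pat), 0.85/0.85 (epiblast); canonical maternal gDMRs 0.85/0.10
from the gamete onward, maternal ≈ 0.02 in matDKO; coverage
Poisson(30) per CpG per allele. LTR sequences carry planted CpG
dinucleotide densities (0.10 active vs 0.01 background).

Each output kind draws from its own RNG stream derived from the master
seed, so adding an output never perturbs the others, and identical
configs give identical datasets.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: alignment and mappability artifacts (reads are
error-free and SNP observations exact), fragment-length/GC bias, PCR
duplicates, cell-type mixtures, realistic gene structure (all genes have
three exons of fixed geometry), linked SNP haplotype structure, and
bisulfite conversion error. Recovery metrics on simulated data are
upper bounds for real-data performance; the calibration and oracle
checks (exact test behavior, assignment logic, BH, chi-square) transfer
directly.

## Numerical choices

* Read-to-region counting uses the midpoint rule: a read counts once per
  region containing its midpoint, avoiding double counting across merged
  peaks and adjacent windows.
* Size factors are median-of-ratios against the geometric-mean
  pseudo-reference on autosomal regions positive in all samples, with a
  warned total-count fallback; sex/mitochondrial regions are scaled but
  never drive estimation.
* Enrichment display normalization maps the 40th and 99th percentiles of
  the non-zero values to 0 and 1 by an affine map, without clipping, so
  rank order and relative enrichment are preserved. Quantiles use R's
  default linear interpolation (type 7).
* Peak merging unions intervals overlapping by ≥ 1 bp; abutting peaks
  are kept separate. The overlap predicate everywhere is ≥ 1 bp
  intersection. Chi-square statistics are Pearson's without continuity
  correction (a Yates flag exists); degenerate tables (a zero margin)
  return χ² = 0, p = 1.
* The beta-binomial MLE is found by `optimize()` on π ∈ (10⁻⁸, 1−10⁻⁸);
  the LRT statistic is floored at 0. Regions with zero reads in every
  replicate are reported untested (NA p), not significant.
* All coordinates are 0-based half-open end to end (BED convention);
  GRanges conversion happens only inside interval operations.
  Chromosome names are taken verbatim from inputs.

## Problem sizes

The test suite exercises a 120-peak dataset for unit tests and the
default 1,000-peak dataset for end-to-end recovery; the null calibration
uses 10,000 regions. The full default simulate + pipeline run completes
in about a minute on one CPU.

## Known limitations

* The shared-ρ beta-binomial has no per-region dispersion shrinkage
  (deliberately out of scope); heavy-tailed regional noise would inflate
  the LRT.
* `single_cross_only` regions are excluded from consensus rather than
  rescued by meta-analysis across crosses.
* Interval scans in the TSS-proximity statistics are dense (all LTRs ×
  all genes) and sized for desk-scale catalogs, not whole-genome repeat
  annotations.
* The two-pass paternal merge can mislabel rare B6 reads overlapping
  only 129-only SNP positions, as discussed above.
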