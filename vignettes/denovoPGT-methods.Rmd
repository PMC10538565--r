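---
title: "Methods: reference-free PGT-M for de novo mutations"
author: "denovoPGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free PGT-M for de novo mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovoPGT)
```

# The problem

A carrier of a heterozygous *de novo* pathogenic mutation wants embryos
diagnosed before transfer.  Standard SNP- or STR-based PGT-M phases the
informative markers through an affected relative; with a de novo mutation
no such relative exists.  Direct mutation detection from a 4–10-cell
trophectoderm biopsy is possible but fragile: whole-genome amplification
drops one allele at a meaningful rate (allele dropout, ADO), and a single
dropped allele at the mutation site flips the apparent genotype.  The
workflow implemented here establishes the linkage phase *directly in the
carrier* from long sequencing reads, then diagnoses each embryo from many
markers at once, so that no single dropout can change a call, and reads
chromosome-level copy number from the same shallow embryo sequencing.

# Carrier phasing by minimum error correction

Let the carrier's heterozygous sites in the target window (the mutation
plus flanking SNPs) be columns of a matrix whose rows are QC-passing
reads, with entries ref/alt/missing.  Under a symmetric per-site error
rate, the maximum-likelihood assignment of reads to the two parental
haplotypes minimizes the number of entries that disagree with their
group's per-column majority — the minimum error correction (MEC)
partition.  The solver is exact (full enumeration over bipartitions) for
instances up to 10 reads × 16 sites, which also gives the test suite an
oracle-checkable regime; larger instances use a greedy left-to-right
chaining pass (each read, in genomic order, joins the group it agrees
with over already-covered columns, so phase information propagates along
read overlaps) refined by local search with seeded random restarts.
Greedy chaining matters: pure local search from random starts can lock
into "flipped block" optima on long windows where both halves are
internally consistent but mutually inverted, and single-read moves cannot
escape; chaining never creates such a state.

Two reads' groups are only comparable where phase blocks connect:
adjacent columns join one block when at least `minOverlapReads = 2` reads
observe both (each such read shares ≥ 2 informative sites with the pair,
satisfying `minSharedSnps = 1`).  The mutation is assigned to the group
with majority alternate-allele support at its column; ties, an unobserved
column, or a mutation column in a singleton block stay `unresolved` —
both single-read linkage and chained linkage through intermediate columns
are accepted, chained being the default behaviour of the MEC partition.

Read QC mirrors the standard nanopore pass-read filter: mean read quality
≥ 7, 50 bp cropped from each end, and a post-crop length of ≥ 1000 bp;
the crop is applied before the length test, and marker observations
falling inside cropped ends are discarded.  Coordinates are 1-based
inclusive throughout, matching VCF convention.  All tie-breaks
(consensus ties, equal-cost partitions, equidistant reassignment) are
deterministic, so identical inputs give bit-identical phases.

# Embryo linkage diagnosis

A marker is *informative* when the carrier is heterozygous and the
partner homozygous — or hemizygous, the relevant case for an X-linked
locus with a male partner.  Within ±2 Mb of the gene at most 15 markers
per side are kept, closest first, each recording which allele rides the
mutant versus the wild-type carrier haplotype.  Per embryo and marker:
XY embryos at X-linked loci are hemizygous, so the single observed allele
is read off directly; XX embryos have one obligate partner allele
subtracted, and the remainder is the maternal allele.  Alleles seen in
neither parent (amplification artifacts) are counted and excluded;
ambiguous partial observations are uninformative; absent ones missing.

The diagnosis is a majority vote.  Defaults — at least 10 supporting
votes and a winning fraction of ≥ 0.8 — were chosen so that no single
ADO- or artifact-corrupted marker can flip a call on a 30-marker panel;
both are configuration keys.  A run of at least 3 consecutive markers
switching haplotype is treated as candidate recombination (shorter runs
are single-marker noise): votes then restrict to the gene-containing
flank, and if the inferred breakpoint interval straddles the gene itself
the embryo is honestly inconclusive, since neither flank determines the
genotype at the mutation.  Concordance against the direct mutation-site
assay is reported wherever both calls exist.

# Copy number from shallow bin counts

Reads are counted in 1 Mb bins genome-wide.  Counts are regressed on bin
GC by robust loess (symmetric family, span 0.3) over non-zero autosomal
bins and divided by the fit, then scaled so the autosomal median ratio is
1.0.  Copy number obeys the dose rule `copy = round(2 × ratio)` — counts
rise by 50 % from copy 2 to 3 and fall by 50 % from 2 to 1 — with exact
half-way ratios rounded *toward* diploid (a conservative choice: a 1.25
ratio stays diploid rather than becoming a gain).

Change-points come from circular binary segmentation: per chromosome,
the arc maximizing the two-sample t-like statistic
|mean(arc) − mean(rest)| / sqrt(1/k + 1/(n−k)) is found exhaustively
(an O(n²) scan implemented in C++), accepted when its permutation
p-value is ≤ α, and applied recursively.  Defaults α = 0.01 with 10 000
permutations, seeded; the permutation loop stops early once the
exceedance count proves p > α, which makes null chromosomes cheap while
significant splits pay the full permutation price.  Segments whose mean
ratio is within 0.2 of diploid are pulled back to copy 2 before adjacent
same-copy segments merge; the ≥ 4 Mb reporting rule is applied *after*
merging (the more conservative reading of an unstated order).  Segments
never cross chromosome boundaries.

Karyotype strings follow clinical notation: total count = 46 plus
whole-chromosome gains minus losses, sex designation from the X/Y mean
ratios (XX expects X ≈ 1, Y ≈ 0; XY expects X ≈ 0.5, Y ≈ 0.5), and
events appended as `+Y (×2)` or `-21(start-end, ~27 Mb, ×1)`.  A
chromosome counts as whole-chromosome aneuploid only when a single
non-diploid state covers ≥ 90 % of it; sub-4 Mb events are suppressed
but retained in an attribute.  No cytoband table is bundled (keeping the
package download-free), so segmental events print raw coordinates rather
than band names; a sex-ratio pair far from any integer copy state is
reported as ambiguous together with the raw ratios.  Self-normalization
is the default because external reference baselines are
platform-specific; a per-bin baseline can be supplied.

# Variant annotation

`codonIndex(p) = ceiling(p / 3)` maps a CDS position to its residue.
Frameshift consequences re-translate the shifted frame from the variant
codon and report the first *genuinely differing* residue (never residue
0: in repetitive sequence the shifted frame can initially coincide with
the reference) and the stop position counted with the first changed
residue as 1 (`fs*K`, HGVS v20+ counting; no downstream stop gives
`fs*?`, an immediate stop the nonsense form `p.<Ref><N>*`).  Transcript
retrieval is deliberately not built in — the CDS is user-supplied FASTA,
keeping the package offline.  ACMG evidence codes combine through the
published rules table; conflicting pathogenic and benign evidence yields
VUS.

# What the generators emulate — and what they do not

`simulateFamily` draws biallelic het sites over the window (the mutation
row is a single-base deletion, carrier-heterozygous, absent in the
partner).  Site counts can be given directly (30 by default, a curated
panel's size) or as a density; the pipeline phases over a dense scaffold
of 250 sites/Mb, a deliberately conservative stand-in for typical human
heterozygosity (~1 het SNP per 1.3 kb): at 14 kb reads, chaining is
physically impossible across a 30-marker/4 Mb panel (mean gap ≈ 130 kb),
exactly as in real data, where phasing runs on all het SNPs and the
informative panel is selected afterwards.

`simulateLongReads` uses gamma-distributed lengths (shape 2) — the heavy
right tail of size-selected nanopore libraries — around a configurable
mean (default 14.4 kb) at a configurable depth (default 28X), flips each
marker observation independently (default 5 %, an ONT-like per-site
allele error), and assigns per-read mean qualities with a configurable
fraction below the q = 7 threshold.  `simulateEmbryos` gives each embryo
one carrier haplotype (fair coin), at most one recombination breakpoint
per window (a ~4 Mb window makes two crossovers negligible), partner
alleles (none on X for XY embryos), and independent per-allele dropout.
ADO is modeled as missingness by default, matching how marker matrices
record "0" at failed sites; the classic dropout-to-homozygote
misdiagnosis signature is available as a mode.  The study's own WGA ADO
rate is not published; the default 0.05 is mid-range for MALBAC-style
amplification of 4–10 cells and is a parameter, not an asserted value.

`simulateBinCounts` draws negative-binomial counts with mean
(copy/2) × reads-per-bin × gcBias(gc), a smooth unimodal GC bias, and a
fixed per-genome GC profile.  The dispersion default 0.02 gives a ~15 %
per-bin CV at the default 200 reads/bin — matching the ~10–15 %
reproducibility CV reported for quasi-linear WGA at 1 Mb bins, and
conservative relative to it.  200 reads/bin is a desk-scaled stand-in
for real shallow sequencing (~5X is tens of thousands of 100 bp reads
per bin); because dispersion dominates the CV at both scales, results
are insensitive to this choice.

Not emulated: base-level sequence errors (no FASTQ), library prep,
alignment, mappability and replication-timing structure in bin counts,
mosaicism in biopsies, and linkage disequilibrium in partner alleles
(transmitted independently per marker — irrelevant to carrier-haplotype
votes, which never use partner phase).  Passing tests therefore
demonstrate the statistical machinery under the stated noise model, not
robustness to every artifact of real sequencing.

# Problem sizes used by the test suite

Simulation-heavy checks run at reduced but statistically meaningful
sizes, chosen as the package's own validation design: phasing recovery
uses 200 seeded replicates of a 0.2 Mb-flank window at 28X / 14.4 kb /
5 % error; classification recovery uses 500 embryos on a 30-marker panel
at 15 % ADO (plus a deliberately mis-phased carrier as a label-inversion
control); CNV recovery uses 100 seeds of a 27-bin single-copy loss in a
240-bin two-chromosome genome plus 100 diploid seeds for the
false-positive rate; dose-response estimates average 20–100 replicate
genomes.  Exhaustive oracles (all read bipartitions; all segmentation
arcs in plain R) cover the small-instance regime.

# Known limitations

* The MEC solver is heuristic beyond the exact regime; with deep
  long-read coverage the greedy-chaining start has always reached the
  optimum in testing, but no optimality certificate is produced.
* Sex inference and sex-chromosome copy calls come from X/Y bin ratios
  alone; low-level sex-chromosome mosaicism will read as an ambiguous
  ratio rather than a mosaic fraction.
* The ±50 % dose rule quantizes to integer copies; mosaic intermediate
  ratios are rounded, not estimated.
* Karyotype strings lack cytoband names without a user band table.
* X-linked loci are the primary mode (maternal-only haplotype columns
  for XY embryos); autosomal mode is supported through configuration but
  paternal-haplotype linkage is not separately diagnosed.
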