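# denovoPGT

Preimplantation genetic testing for monogenic disease (PGT-M) normally
anchors its linkage analysis on an affected relative: informative SNPs are
phased through the pedigree, and each embryo biopsy is diagnosed by which
parental haplotype it inherited.  When the carrier's mutation is *de novo*
— present in the carrier but in neither parent — there is no relative to
phase against, and direct mutation detection alone is vulnerable to allele
dropout (ADO) from whole-genome amplification of the 4–10 biopsied cells.

`denovoPGT` implements the reference-free alternative for R users working
on embryo diagnostics:

1. **Direct haplotype phasing from long reads.** Reads spanning the
   mutation and nearby heterozygous SNPs are partitioned into the
   carrier's two haplotypes by minimum error correction (MEC): find the
   two-group read partition minimizing the total number of allele
   observations that disagree with their group consensus, which is the
   maximum-likelihood partition under a symmetric per-marker error.  The
   de novo mutation is assigned to a haplotype by majority vote of the
   reads carrying it; QC follows the standard nanopore pass-read filter
   (mean q ≥ 7, 50 bp end-crop, post-crop length ≥ 1 kb).
2. **Informative-SNP linkage diagnosis with ADO tolerance.** Markers
   heterozygous in the carrier and homozygous (or hemizygous) in the
   partner, within ±2 Mb of the gene (up to 15 per side), identify which
   carrier haplotype each embryo inherited.  Diagnosis is by majority
   vote (default: ≥ 10 votes and ≥ 80 % margin), with recombination
   detection and concordance checking against direct mutation detection.
3. **Low-coverage CNV calling and karyotyping.** Genome-wide 1 Mb bin
   read counts are GC-normalized (loess) and scaled to the autosomal
   median; copy number follows the dose rule `copy = round(2 × ratio)`
   (a bin's counts rise 50 % from copy 2→3 and fall 50 % from 2→1);
   change-points come from circular binary segmentation (CBS) with a
   permutation acceptance test; events ≥ 4 Mb are reported in
   cytogenetic strings such as `46, XY` or `47, XYY, +Y (×2)`.
4. **Variant annotation.** HGVS frameshift consequences recomputed from a
   user-supplied CDS (`p.<Ref><N><New>fs*<K>`), and ACMG evidence-code
   combination into the five-tier classification.

Because per-sample human data from such studies is not redistributable,
the package ships first-class synthetic generators (`simulateFamily`,
`simulateLongReads`, `simulateEmbryos`, `simulateBinCounts`) that emulate
the data structure end to end — long reads of configurable depth/length/
error, WGA genotypes with ADO and X-hemizygosity, negative-binomial bin
counts with GC bias and CNV/aneuploidy events — so every stage is testable
offline and against known truth.

## Worked example

```r
library(denovoPGT)
res <- runPipeline(runConfig(windowBp = 4e5, nEmbryos = 4, seed = 11))
res$report[, c("embryo_id", "karyotype", "haplotype_mutation",
               "direct_mutation", "concordant")]
```

```
  embryo_id karyotype haplotype_mutation direct_mutation concordant
1        E1    46, XX                 NO              NO       TRUE
2        E2    46, XX                 NO              NO       TRUE
3        E3    46, XX                YES             YES       TRUE
4        E4    46, XY                 NO              NO       TRUE
```

Each row is one simulated trophectoderm biopsy: its CNV-stage karyotype,
whether the haplotype linkage analysis identified the maternal pathogenic
mutation (`YES` = the embryo inherited the mutation-carrying haplotype),
the direct mutation-site assay result, and whether the two agree.  Here
embryo E3 inherited the mutant haplotype (29 of 30 informative markers
voting, one lost to dropout) and the remaining embryos are unaffected;
all four linkage calls are concordant with direct detection.

Single stages are available on their own, e.g.

```r
codonIndex(1496)                       # 499
combineAcmg(c("PVS1", "PM2", "PM6"))   # "Pathogenic"
callCopyNumber(c(0.5, 1, 1.5))         # 1 2 3
```

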