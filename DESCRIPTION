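Package: denovoPGT
Title: Long-Read Haplotype Phasing, SNP Linkage Analysis and Low-Coverage
    Karyotyping for PGT-M of De Novo Mutations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reference-free preimplantation genetic testing workflow for
    carriers of de novo monogenic mutations. Establishes the carrier's
    two-haplotype phase over the target region directly from long reads by
    minimum-error-correction partitioning (no pedigree needed), selects
    informative SNP markers (heterozygous in the carrier, homozygous or
    hemizygous in the partner), diagnoses embryo biopsies by haplotype
    inheritance with allele-dropout tolerance and recombination detection,
    and calls copy-number variants and aneuploidies from shallow 1 Mb bin
    counts via GC normalization and circular binary segmentation, emitting
    cytogenetic karyotype strings. Includes seeded synthetic-family
    generators (long reads, whole-genome-amplified embryo genotypes,
    GC-biased bin counts) emulating the statistical structure of such
    studies, plus HGVS frameshift consequence annotation and ACMG evidence
    combination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, CopyNumberVariation, Sequencing, Preprocessing
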