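# Central S4 classes.  Allele observations are coded 0 = reference,
# 1 = alternate, NA = unobserved throughout; allele letters live only in
# FamilyTruth / MarkerPanel tables.

#' FamilyTruth: simulated ground truth for a carrier couple
#'
#' Holds the carrier's two haplotypes (the one carrying the de novo mutation
#' and the wild-type one) over heterozygous marker positions inside the
#' target window, plus the partner's genotypes.  One marker row (flagged
#' \code{isMutation}) is the pathogenic site itself; the carrier is
#' heterozygous there by construction and the partner carries the reference
#' allele.
#'
#' @slot markers \code{DataFrame} with columns \code{pos}, \code{ref},
#'   \code{alt}, \code{hapMut}, \code{hapWt} (allele letters on each carrier
#'   haplotype), \code{partner1}, \code{partner2} (\code{NA} when the
#'   partner is hemizygous), \code{isMutation}.
#' @slot chrom chromosome name.
#' @slot geneStart,geneEnd target gene interval (1-based, inclusive).
#' @slot mutationPos coordinate of the de novo mutation.
#' @slot windowBp half-window around the gene within which markers lie.
#' @slot xLinked logical; if \code{TRUE} the partner is hemizygous and male
#'   embryos inherit no partner allele.
#' @export
setClass("FamilyTruth",
  slots = c(markers = "DataFrame", chrom = "character",
            geneStart = "numeric", geneEnd = "numeric",
            mutationPos = "numeric", windowBp = "numeric",
            xLinked = "logical"))

setValidity("FamilyTruth", function(object) {
  m <- object@markers
  need <- c("pos", "ref", "alt", "hapMut", "hapWt", "partner1", "partner2",
            "isMutation")
  if (!all(need %in% colnames(m)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(m$pos, strictly = TRUE))
    return("marker positions must be strictly increasing")
  if (any(m$hapMut == m$hapWt))
    return("carrier must be heterozygous at every marker")
  if (sum(m$isMutation) != 1L)
    return("exactly one marker row must be the mutation site")
  lo <- object@geneStart - object@windowBp
  hi <- object@geneEnd + object@windowBp
  if (any(m$pos < lo | m$pos > hi))
    return("all markers must lie within the window around the gene")
  mp <- object@mutationPos
  if (mp < object@geneStart || mp > object@geneEnd)
    return("mutationPos must lie inside the gene interval")
  if (m$pos[which(m$isMutation)] != mp)
    return("mutation marker row position must equal mutationPos")
  TRUE
})

#' SimReadSet: simulated long reads with per-marker allele observations
#'
#' @slot reads \code{DataFrame} with \code{id}, \code{start}, \code{end},
#'   \code{qscore} (per-read mean quality), \code{truthHap} ("mut"/"wt",
#'   the haplotype of origin before error injection).
#' @slot obs integer matrix, reads x marker sites, 0/1/NA.
#' @slot positions marker coordinates (columns of \code{obs}).
#' @slot chrom chromosome name.
#' @slot mutationIndex column index of the mutation site (NA if absent).
#' @export
setClass("SimReadSet",
  slots = c(reads = "DataFrame", obs = "matrix", positions = "numeric",
            chrom = "character", mutationIndex = "integer"))

setValidity("SimReadSet", function(object) {
  if (nrow(object@reads) != nrow(object@obs))
    return("reads table and observation matrix disagree on read count")
  if (length(object@positions) != ncol(object@obs))
    return("positions and observation matrix disagree on site count")
  if (length(object@positions) > 1L &&
      is.unsorted(object@positions, strictly = TRUE))
    return("positions must be strictly increasing")
  if (nrow(object@obs)) {
    covered <- !is.na(object@obs)
    inside <- outer(object@reads$start, object@positions, `<=`) &
              outer(object@reads$end, object@positions, `>=`)
    if (any(covered & !inside))
      return("observed alleles outside the read interval")
  }
  TRUE
})

#' ReadAlleleMatrix: QC-passing reads restricted to heterozygous sites
#'
#' @slot mat integer matrix (reads x het sites), entries 0/1/NA; every row
#'   covers at least one site.
#' @slot positions strictly increasing site coordinates.
#' @slot chrom chromosome name.
#' @slot mutationIndex column index of the mutation site (NA if absent).
#' @export
setClass("ReadAlleleMatrix",
  slots = c(mat = "matrix", positions = "numeric", chrom = "character",
            mutationIndex = "integer"))

setValidity("ReadAlleleMatrix", function(object) {
  if (length(object@positions) != ncol(object@mat))
    return("positions and matrix disagree on site count")
  if (length(object@positions) > 1L &&
      is.unsorted(object@positions, strictly = TRUE))
    return("positions must be strictly increasing")
  if (nrow(object@mat) && any(rowSums(!is.na(object@mat)) == 0L))
    return("every retained read must cover at least one site")
  TRUE
})

#' PhasedTargetRegion: the carrier's two haplotypes over the target window
#'
#' Result of minimum-error-correction phasing.  \code{hap1}/\code{hap2} are
#' complementary (0/1) wherever resolved.  Adjacent markers belong to the
#' same phase block only when enough reads span both; markers outside the
#' mutation-containing block have undefined phase relative to the mutation.
#'
#' @slot chrom,positions site coordinates.
#' @slot hap1,hap2 integer 0/1/NA haplotype allele codes per site.
#' @slot blockId integer phase-block membership per site.
#' @slot blockSupport reads spanning each adjacent site pair
#'   (length \code{length(positions) - 1}).
#' @slot mutationPos,mutationHap mutation coordinate and its haplotype
#'   assignment ("hap1", "hap2" or "unresolved").
#' @slot window numeric length-2 (start, end) of the phased window.
#' @slot groupCounts 4 x sites matrix of per-read-group allele tallies
#'   (rows alt1, ref1, alt2, ref2), kept for mutation assignment and QC.
#' @slot mecCost achieved minimum-error-correction cost.
#' @export
setClass("PhasedTargetRegion",
  slots = c(chrom = "character", positions = "numeric",
            hap1 = "integer", hap2 = "integer",
            blockId = "integer", blockSupport = "numeric",
            mutationPos = "numeric", mutationHap = "character",
            window = "numeric", groupCounts = "matrix",
            mecCost = "numeric"))

setValidity("PhasedTargetRegion", function(object) {
  n <- length(object@positions)
  if (length(object@hap1) != n || length(object@hap2) != n ||
      length(object@blockId) != n)
    return("hap1, hap2 and blockId must match positions in length")
  if (n > 1L && length(object@blockSupport) != n - 1L)
    return("blockSupport must have one entry per adjacent site pair")
  both <- !is.na(object@hap1) & !is.na(object@hap2)
  if (any(object@hap1[both] == object@hap2[both]))
    return("hap1 and hap2 must be complementary at every resolved site")
  if (!object@mutationHap %in% c("hap1", "hap2", "unresolved"))
    return("mutationHap must be hap1, hap2 or unresolved")
  TRUE
})

#' MarkerPanel: informative SNPs used for embryo linkage
#'
#' Markers heterozygous in the carrier and homozygous (or hemizygous) in the
#' partner, within the window, phased onto the mutant / wild-type carrier
#' haplotypes.
#'
#' @slot markers \code{DataFrame} with \code{pos}, \code{ref}, \code{alt},
#'   \code{mutAllele}, \code{wtAllele} (letters on the mutant / wild-type
#'   haplotype), \code{partner1}, \code{partner2}, \code{side}
#'   ("upstream"/"downstream"), \code{distanceBp}.
#' @slot chrom,geneStart,geneEnd locus description.
#' @slot xLinked logical.
#' @export
setClass("MarkerPanel",
  slots = c(markers = "DataFrame", chrom = "character",
            geneStart = "numeric", geneEnd = "numeric", xLinked = "logical"))

setValidity("MarkerPanel", function(object) {
  m <- object@markers
  need <- c("pos", "ref", "alt", "mutAllele", "wtAllele", "partner1",
            "partner2", "side", "distanceBp")
  if (!all(need %in% colnames(m)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  if (nrow(m) == 0L) return("panel must contain at least one marker")
  if (any(m$mutAllele == m$wtAllele))
    return("carrier must be heterozygous at every panel marker")
  het <- !is.na(m$partner2) & m$partner1 != m$partner2
  if (any(het))
    return("partner must be homozygous or hemizygous at every panel marker")
  TRUE
})

#' EmbryoTruth: one simulated embryo's ground truth
#'
#' @slot id embryo identifier.
#' @slot sex "XX" or "XY".
#' @slot hapByMarker "mut"/"wt" carrier haplotype of origin at each marker
#'   (differs along the window after recombination).
#' @slot inheritedHap carrier haplotype at the mutation site.
#' @slot breakpoint recombination coordinate (length 0 if none).
#' @slot paternalAllele partner allele letter per marker (NA for XY embryos
#'   at X-linked loci).
#' @slot cnvEvents data.frame(chrom, start, end, copy) of simulated CNVs.
#' @slot positions marker coordinates.
#' @export
setClass("EmbryoTruth",
  slots = c(id = "character", sex = "character", hapByMarker = "character",
            inheritedHap = "character", breakpoint = "numeric",
            paternalAllele = "character", cnvEvents = "data.frame",
            positions = "numeric"))

setValidity("EmbryoTruth", function(object) {
  if (!object@sex %in% c("XX", "XY")) return("sex must be XX or XY")
  if (length(object@hapByMarker) != length(object@positions))
    return("hapByMarker must match positions in length")
  if (length(object@breakpoint) > 1L)
    return("at most one recombination breakpoint per embryo")
  TRUE
})

#' EmbryoObservation: observed biopsy genotypes at marker sites
#'
#' Genotypes are strings over allele letters: \code{"A/B"} for diploid
#' calls, with \code{"."} marking an allele lost to dropout (e.g.
#' \code{"A/."}); hemizygous X sites in XY embryos carry a single letter.
#' A fully missing site is \code{"./."} (or \code{"."}), the "0" state of
#' whole-genome-amplification marker matrices.
#'
#' @slot id embryo identifier.
#' @slot sex "XX" or "XY".
#' @slot positions marker coordinates.
#' @slot genotypes character vector of genotype strings.
#' @slot directCall direct mutation-site assay result: "mut", "wt" or
#'   "missing".
#' @export
setClass("EmbryoObservation",
  slots = c(id = "character", sex = "character", positions = "numeric",
            genotypes = "character", directCall = "character"))

setValidity("EmbryoObservation", function(object) {
  if (length(object@genotypes) != length(object@positions))
    return("genotypes must match positions in length")
  if (!object@directCall %in% c("mut", "wt", "missing"))
    return("directCall must be mut, wt or missing")
  TRUE
})

#' BinCountTrack: genome-wide 1 Mb bin read counts
#'
#' Bins tile each chromosome without overlap.  \code{mcols(binCounts(x))}
#' holds \code{count}, \code{gc} and, after \code{\link{normalizeBins}},
#' \code{normalized} (1.0 = diploid expectation).
#'
#' @slot bins \code{GRanges} of bins with metadata columns.
#' @slot binSizeBp nominal bin width in bp.
#' @export
setClass("BinCountTrack",
  slots = c(bins = "GRanges", binSizeBp = "numeric"))

setValidity("BinCountTrack", function(object) {
  mc <- mcols(object@bins)
  if (!all(c("count", "gc") %in% colnames(mc)))
    return("bins must carry 'count' and 'gc' metadata columns")
  if (any(mc$count < 0)) return("counts must be non-negative")
  if ("normalized" %in% colnames(mc)) {
    bad <- mc$count > 0 & !is.na(mc$normalized) & mc$normalized <= 0
    if (any(bad)) return("normalized ratios must be positive where counts are")
  }
  TRUE
})

#' EmbryoCall: linkage diagnosis for one embryo
#'
#' @slot id embryo identifier.
#' @slot assignments per-marker assignment: "mut", "wt", "uninformative",
#'   "missing" or "inconsistent" (non-parental allele).
#' @slot voteMut,voteWt vote tallies used for the diagnosis.
#' @slot diagnosis "affected", "unaffected" or "inconclusive".
#' @slot directCall direct mutation assay: "mut", "wt" or "missing".
#' @slot concordant logical, NA when either call is unavailable.
#' @slot recombination numeric length-0 or length-2 breakpoint interval.
#' @slot inconsistencyCount markers excluded as genotype-inconsistent.
#' @slot reason explanation when inconclusive ("" otherwise).
#' @export
setClass("EmbryoCall",
  slots = c(id = "character", assignments = "character",
            voteMut = "integer", voteWt = "integer",
            diagnosis = "character", directCall = "character",
            concordant = "logical", recombination = "numeric",
            inconsistencyCount = "integer", reason = "character"))

setValidity("EmbryoCall", function(object) {
  if (!object@diagnosis %in% c("affected", "unaffected", "inconclusive"))
    return("diagnosis must be affected, unaffected or inconclusive")
  ok <- c("mut", "wt", "uninformative", "missing", "inconsistent")
  if (!all(object@assignments %in% ok))
    return("invalid per-marker assignment value")
  if (object@voteMut + object@voteWt > length(object@assignments))
    return("votes cannot exceed panel size")
  if (!length(object@recombination) %in% c(0L, 2L))
    return("recombination must be empty or a length-2 interval")
  TRUE
})

#' RunConfig: pipeline parameter bundle
#'
#' Validated flat list of every tunable the pipeline stages use; build with
#' \code{\link{runConfig}}.
#'
#' @slot params named list of parameters.
#' @export
setClass("RunConfig", slots = c(params = "list"))
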