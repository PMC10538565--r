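#' Simulate a carrier couple's ground truth over the target window
#'
#' Generates biallelic SNP markers around a target gene, assigns their
#' alleles to the carrier's two haplotypes (the carrier is heterozygous at
#' every marker, so all are phase-informative candidates), draws partner
#' genotypes, and places a heterozygous de novo mutation inside the gene on
#' one haplotype.  The default locus mimics an X-linked gene at Xp22 with a
#' hemizygous male partner.
#'
#' Marker count can be given directly (\code{nMarkers}) or as a density in
#' markers/Mb (\code{markerDensity}, which then overrides \code{nMarkers});
#' densities of a few hundred per Mb approximate the genome-wide
#' heterozygous SNP scaffold that long reads actually chain across, while
#' the default 30 corresponds to a curated informative-marker panel.
#'
#' @param nMarkers number of het markers (>= 1).
#' @param windowBp half-window around the gene interval (default 2 Mb).
#' @param markerDensity optional markers per Mb; overrides \code{nMarkers}.
#' @param seed integer seed; identical seeds give identical objects.
#' @param chrom,geneStart,geneEnd target locus (defaults: an X-linked gene
#'   of ~117 kb at Xp22).
#' @param mutationPos mutation coordinate; default the gene midpoint.
#' @param xLinked if \code{TRUE} the partner is hemizygous (single X allele).
#' @param partnerHetFraction for autosomal loci, fraction of markers at
#'   which the partner is heterozygous (those markers are uninformative for
#'   linkage); ignored when \code{xLinked}.
#' @return a \code{\link{FamilyTruth}}.
#' @examples
#' fam <- simulateFamily(nMarkers = 30, seed = 1)
#' fam
#' @export
simulateFamily <- function(nMarkers = 30, windowBp = 2e6,
                           markerDensity = NULL, seed = 1,
                           chrom = "chrX",
                           geneStart = 20168001, geneEnd = 20285000,
                           mutationPos = NULL, xLinked = TRUE,
                           partnerHetFraction = 0.3) {
  checkScalarCount(windowBp, "windowBp")
  if (!is.null(markerDensity)) {
    checkScalarCount(markerDensity, "markerDensity", minimum = 1e-6)
    nMarkers <- max(1L, round(markerDensity * 2 * windowBp / 1e6))
  }
  checkScalarCount(nMarkers, "nMarkers")
  nMarkers <- as.integer(nMarkers)
  if (geneEnd <= geneStart) stop("geneEnd must exceed geneStart")
  if (is.null(mutationPos)) mutationPos <- floor((geneStart + geneEnd) / 2)
  if (mutationPos < geneStart || mutationPos > geneEnd)
    stop("mutationPos must lie inside the gene interval")

  withSeed(seed, {
    # het sites cover the whole span including the gene body (long reads
    # phase the mutation through intragenic SNPs); panel selection later
    # restricts to sites upstream/downstream of the gene
    span <- c(geneStart - windowBp, geneEnd + windowBp)
    pos <- span[1] - 1 + sample.int(span[2] - span[1] + 1,
                                    nMarkers + 1L)
    pos <- sort(setdiff(pos, mutationPos)[seq_len(nMarkers)])
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nMarkers, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    # which allele rides on the mutation-carrying haplotype
    altOnMut <- runif(nMarkers) < 0.5
    hapMut <- ifelse(altOnMut, alt, ref)
    hapWt <- ifelse(altOnMut, ref, alt)
    if (xLinked) {
      partner1 <- ifelse(runif(nMarkers) < 0.5, ref, alt)
      partner2 <- rep(NA_character_, nMarkers)
    } else {
      het <- runif(nMarkers) < partnerHetFraction
      a <- ifelse(runif(nMarkers) < 0.5, ref, alt)
      partner1 <- a
      partner2 <- ifelse(het, ifelse(a == ref, alt, ref), a)
    }
    mk <- DataFrame(pos = pos, ref = ref, alt = alt,
                    hapMut = hapMut, hapWt = hapWt,
                    partner1 = partner1, partner2 = partner2,
                    isMutation = rep(FALSE, nMarkers))
    # the pathogenic site: single-base deletion, carrier het, partner ref
    mut <- DataFrame(pos = mutationPos, ref = "G", alt = "-",
                     hapMut = "-", hapWt = "G",
                     partner1 = "G",
                     partner2 = if (xLinked) NA_character_ else "G",
                     isMutation = TRUE)
    mk <- rbind(mk, mut)
    mk <- mk[order(mk$pos), ]
    rownames(mk) <- NULL
    new("FamilyTruth", markers = mk, chrom = chrom,
        geneStart = geneStart, geneEnd = geneEnd,
        mutationPos = mutationPos, windowBp = windowBp, xLinked = xLinked)
  })
}

#' Build the carrier's true phase as a PhasedTargetRegion
#'
#' Converts simulated ground truth into a fully-resolved
#' \code{\link{PhasedTargetRegion}} (hap1 = mutation-carrying haplotype,
#' single phase block, mutation assigned).  Used to validate downstream
#' linkage analysis independently of the read-based phasing stage, and to
#' build deliberately mis-phased controls by swapping haplotypes.
#'
#' @param truth a \code{\link{FamilyTruth}}.
#' @param swap if \code{TRUE} the marker phase is inverted relative to the
#'   mutation (the mutation stays assigned to hap1 but hap1 carries the
#'   wild-type marker alleles), emulating a phasing failure.  A plain label
#'   swap would be equivalent under label-swap symmetry; this is not.
#' @return a \code{\link{PhasedTargetRegion}}.
#' @export
truthPhase <- function(truth, swap = FALSE) {
  stopifnot(is(truth, "FamilyTruth"))
  m <- truth@markers
  h1 <- as.integer(m$hapMut == m$alt)
  if (swap) h1 <- ifelse(m$isMutation, h1, 1L - h1)
  n <- nrow(m)
  counts <- rbind(alt1 = ifelse(h1 == 1L, 1L, 0L),
                  ref1 = ifelse(h1 == 1L, 0L, 1L),
                  alt2 = ifelse(h1 == 1L, 0L, 1L),
                  ref2 = ifelse(h1 == 1L, 1L, 0L))
  new("PhasedTargetRegion", chrom = truth@chrom, positions = m$pos,
      hap1 = h1, hap2 = 1L - h1,
      blockId = rep(1L, n),
      blockSupport = if (n > 1L) rep(Inf, n - 1L) else numeric(0),
      mutationPos = truth@mutationPos,
      mutationHap = "hap1",
      window = c(truth@geneStart - truth@windowBp,
                 truth@geneEnd + truth@windowBp),
      groupCounts = counts, mecCost = 0)
}
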