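# Informative-SNP selection and embryo linkage diagnosis.

#' Select informative SNPs for embryo linkage
#'
#' A marker is informative when the carrier is heterozygous (true for every
#' phased het site), the partner is homozygous or hemizygous, the site lies
#' within \code{windowBp} of the gene, and its phase is linked to the
#' mutation (same phase block).  If more than \code{maxPerSide} qualify on
#' one side of the gene, the closest are kept.  Each panel marker records
#' which allele rides on the mutant vs wild-type carrier haplotype.
#'
#' @param phased a \code{\link{PhasedTargetRegion}} with the mutation
#'   assigned (\code{mutationHap != "unresolved"}).
#' @param sites site table carrying allele letters and partner genotypes:
#'   a \code{\link{FamilyTruth}}, or any data.frame/DataFrame with columns
#'   \code{pos}, \code{ref}, \code{alt}, \code{partner1}, \code{partner2}
#'   (\code{partner2 = NA} for hemizygous).
#' @param geneStart,geneEnd gene interval; defaulted from \code{sites}
#'   when it is a \code{FamilyTruth}.
#' @param windowBp maximum distance from the gene (default 2 Mb).
#' @param maxPerSide marker cap per side of the gene (default 15).
#' @return a \code{\link{MarkerPanel}}.
#' @examples
#' fam <- simulateFamily(seed = 1)
#' panel <- selectInformativeSnps(truthPhase(fam), fam)
#' panel
#' @export
selectInformativeSnps <- function(phased, sites, geneStart = NULL,
                                  geneEnd = NULL, windowBp = 2e6,
                                  maxPerSide = 15) {
  stopifnot(is(phased, "PhasedTargetRegion"))
  if (phased@mutationHap == "unresolved")
    stop("carrier phase is unresolved at the mutation; no panel possible")
  xLinked <- TRUE
  if (is(sites, "FamilyTruth")) {
    if (is.null(geneStart)) geneStart <- sites@geneStart
    if (is.null(geneEnd)) geneEnd <- sites@geneEnd
    xLinked <- sites@xLinked
    sites <- as.data.frame(sites@markers[!sites@markers$isMutation, ])
  } else {
    sites <- as.data.frame(sites)
    if (is.null(geneStart) || is.null(geneEnd))
      stop("geneStart and geneEnd are required with a plain site table")
  }
  need <- c("pos", "ref", "alt", "partner1", "partner2")
  stopifnot(all(need %in% colnames(sites)))

  idx <- match(sites$pos, phased@positions)
  keep <- !is.na(idx)
  sites <- sites[keep, , drop = FALSE]
  idx <- idx[keep]

  mutHapIs1 <- phased@mutationHap == "hap1"
  hapM <- if (mutHapIs1) phased@hap1[idx] else phased@hap2[idx]
  mutBlock <- phased@blockId[match(phased@mutationPos, phased@positions)]
  if (is.na(mutBlock)) mutBlock <- -1L

  partnerHom <- is.na(sites$partner2) | sites$partner1 == sites$partner2
  inWindow <- sites$pos >= geneStart - windowBp &
              sites$pos <= geneEnd + windowBp
  outsideGene <- sites$pos < geneStart | sites$pos > geneEnd
  linked <- phased@blockId[idx] == mutBlock & !is.na(hapM)
  ok <- partnerHom & inWindow & outsideGene & linked
  if (!any(ok))
    stop("no informative markers: diagnosis impossible for this couple")

  sites <- sites[ok, , drop = FALSE]
  hapM <- hapM[ok]
  side <- ifelse(sites$pos < geneStart, "upstream", "downstream")
  dist <- ifelse(side == "upstream", geneStart - sites$pos,
                 sites$pos - geneEnd)
  pick <- unlist(lapply(c("upstream", "downstream"), function(s) {
    i <- which(side == s)
    i[order(dist[i])][seq_len(min(maxPerSide, length(i)))]
  }))
  pick <- sort(pick)

  mk <- DataFrame(pos = sites$pos[pick], ref = sites$ref[pick],
                  alt = sites$alt[pick],
                  mutAllele = ifelse(hapM[pick] == 1L, sites$alt[pick],
                                     sites$ref[pick]),
                  wtAllele = ifelse(hapM[pick] == 1L, sites$ref[pick],
                                    sites$alt[pick]),
                  partner1 = sites$partner1[pick],
                  partner2 = sites$partner2[pick],
                  side = side[pick], distanceBp = dist[pick])
  new("MarkerPanel", markers = mk, chrom = phased@chrom,
      geneStart = geneStart, geneEnd = geneEnd, xLinked = xLinked)
}

#' Assign one embryo genotype observation to a carrier haplotype
#'
#' For XX embryos the obligate partner allele is subtracted and the
#' remaining (maternal) allele matched against the mutant / wild-type
#' haplotype alleles; XY embryos at X-linked loci are hemizygous, so the
#' sole allele is read off directly.  An allele seen in neither parent is
#' flagged \code{"inconsistent"} (amplification artifact; excluded from
#' votes).  Ambiguous partial observations are \code{"uninformative"};
#' absent observations are \code{"missing"}.
#'
#' @param genotype genotype string (see
#'   \code{\linkS4class{EmbryoObservation}}): \code{"A/B"}, \code{"A/."},
#'   \code{"./."}, or a single letter / \code{"."} for hemizygous sites.
#' @param marker one row of \code{markers(panel)} (a list-like with
#'   \code{mutAllele}, \code{wtAllele}, \code{partner1}, \code{partner2}).
#' @param embryoSex "XX" or "XY".
#' @param xLinked is the locus X-linked (default TRUE).
#' @return one of "mut", "wt", "uninformative", "missing", "inconsistent".
#' @export
assignMarker <- function(genotype, marker, embryoSex = "XX",
                         xLinked = TRUE) {
  stopifnot(embryoSex %in% c("XX", "XY"))
  alleles <- strsplit(as.character(genotype), "/", fixed = TRUE)[[1]]
  alleles <- alleles[alleles != "." & nzchar(alleles)]
  if (!length(alleles)) return("missing")

  mutA <- as.character(marker$mutAllele)
  wtA <- as.character(marker$wtAllele)
  pA <- unique(stats::na.omit(c(as.character(marker$partner1),
                                as.character(marker$partner2))))
  parental <- unique(c(mutA, wtA, pA))
  if (any(!alleles %in% parental)) return("inconsistent")

  hemizygous <- xLinked && embryoSex == "XY"
  if (hemizygous) {
    if (length(unique(alleles)) > 1L) return("inconsistent")
    a <- alleles[1]
    return(if (a == mutA) "mut" else if (a == wtA) "wt" else "uninformative")
  }

  if (length(alleles) >= 2L) {
    i <- match(pA[1], alleles)
    if (!is.na(i)) {
      # subtract one obligate partner allele; the rest is maternal
      maternal <- alleles[-i][1]
      return(if (maternal == mutA) "mut"
             else if (maternal == wtA) "wt" else "uninformative")
    }
    # partner allele absent: an apparently homozygous carrier allele is the
    # classic dropout-to-homozygote pattern (maternal allele duplicated);
    # two distinct non-partner alleles are a genotype inconsistency
    if (length(unique(alleles)) == 1L) {
      a <- alleles[1]
      return(if (a == mutA) "mut" else if (a == wtA) "wt"
             else "uninformative")
    }
    return("inconsistent")
  }
  # one surviving allele: informative only if it cannot be the partner's
  a <- alleles[1]
  if (a %in% pA) return("uninformative")
  if (a == mutA) "mut" else if (a == wtA) "wt" else "uninformative"
}

#' Classify an embryo from its per-marker assignments
#'
#' Majority vote over informative non-missing markers.  The diagnosis is
#' \code{"affected"} when the mutant-haplotype fraction reaches
#' \code{minMarginFraction} with at least \code{minVotes} votes
#' (symmetrically \code{"unaffected"}); anything else is inconclusive with
#' an explicit reason.  A switch of at least \code{recombMinRun}
#' consecutive markers is reported as candidate recombination, and votes
#' are then restricted to the gene-containing block; if the inferred
#' breakpoint interval straddles the gene itself the diagnosis is
#' inconclusive.
#'
#' @param assignments character vector of per-marker assignments (output
#'   of \code{\link{assignMarker}}), in positional order.
#' @param positions marker coordinates matching \code{assignments}.
#' @param geneStart,geneEnd gene interval.
#' @param minVotes minimum votes supporting the winning haplotype
#'   (default 10; a single dropout-corrupted marker cannot flip a call).
#' @param minMarginFraction winning-fraction threshold (default 0.8).
#' @param recombMinRun consecutive-marker run length treated as a real
#'   block switch rather than single-marker noise (default 3).
#' @param id embryo identifier carried through to the result.
#' @param directCall optional direct mutation assay ("mut"/"wt"/"missing").
#' @return an \code{\link{EmbryoCall}}.
#' @export
classifyEmbryo <- function(assignments, positions, geneStart, geneEnd,
                           minVotes = 10, minMarginFraction = 0.8,
                           recombMinRun = 3, id = "embryo",
                           directCall = "missing") {
  stopifnot(length(assignments) == length(positions))
  ord <- order(positions)
  assignments <- assignments[ord]
  positions <- positions[ord]

  inconsistencyCount <- sum(assignments == "inconsistent")
  isVote <- assignments %in% c("mut", "wt")
  recomb <- numeric(0)
  useVote <- isVote
  reason <- ""

  if (any(isVote)) {
    v <- assignments[isVote]
    vp <- positions[isVote]
    runs <- rle(v)
    major <- which(runs$lengths >= recombMinRun)
    if (length(major) >= 2L &&
        length(unique(runs$values[major])) == 2L) {
      # block switch between the first two major runs of opposite type
      bnd <- cumsum(runs$lengths)
      i1 <- major[1]
      i2 <- major[which(runs$values[major] != runs$values[i1])[1]]
      lastOf1 <- vp[bnd[i1]]
      firstOf2 <- vp[bnd[i2] - runs$lengths[i2] + 1L]
      recomb <- sort(c(lastOf1, firstOf2))
      geneMid <- (geneStart + geneEnd) / 2
      if (geneMid > recomb[1] && geneMid < recomb[2]) {
        useVote <- rep(FALSE, length(assignments))
        reason <- "candidate recombination straddles the gene"
      } else {
        geneSideBlock <- if (geneMid <= recomb[1]) {
          positions <= recomb[1]
        } else {
          positions >= recomb[2]
        }
        useVote <- isVote & geneSideBlock
      }
    }
  }

  voteMut <- sum(assignments[useVote] == "mut")
  voteWt <- sum(assignments[useVote] == "wt")
  tot <- voteMut + voteWt
  if (nzchar(reason)) {
    diagnosisStr <- "inconclusive"
  } else if (tot == 0L) {
    diagnosisStr <- "inconclusive"
    reason <- "no informative marker observations"
  } else if (max(voteMut, voteWt) < minVotes) {
    diagnosisStr <- "inconclusive"
    reason <- sprintf("winning votes %d below minimum %d",
                      max(voteMut, voteWt), minVotes)
  } else if (max(voteMut, voteWt) / tot < minMarginFraction) {
    diagnosisStr <- "inconclusive"
    reason <- sprintf("vote margin %.2f below %.2f",
                      max(voteMut, voteWt) / tot, minMarginFraction)
  } else {
    diagnosisStr <- if (voteMut > voteWt) "affected" else "unaffected"
  }

  new("EmbryoCall", id = id, assignments = assignments,
      voteMut = as.integer(voteMut), voteWt = as.integer(voteWt),
      diagnosis = diagnosisStr, directCall = directCall,
      concordant = concordance(diagnosisStr, directCall),
      recombination = recomb,
      inconsistencyCount = as.integer(inconsistencyCount),
      reason = reason)
}

#' Concordance between linkage diagnosis and direct mutation detection
#'
#' @param call an \code{\link{EmbryoCall}} or a diagnosis string
#'   ("affected"/"unaffected"/"inconclusive").
#' @param directCall "mut", "wt" or "missing".
#' @return \code{TRUE} when the two calls agree, \code{FALSE} when they
#'   disagree, \code{NA} when either is unavailable (missing direct call
#'   or inconclusive diagnosis).
#' @export
concordance <- function(call, directCall) {
  d <- if (is(call, "EmbryoCall")) call@diagnosis else call
  if (d == "inconclusive" || directCall == "missing") return(NA)
  (d == "affected") == (directCall == "mut")
}

#' Diagnose one embryo against a marker panel
#'
#' Convenience wrapper: looks up the embryo's genotypes at the panel
#' positions, assigns each marker, classifies, and checks concordance with
#' the direct mutation assay.
#'
#' @param obs an \code{\link{EmbryoObservation}}.
#' @param panel a \code{\link{MarkerPanel}}.
#' @param sex embryo sex used for hemizygosity handling; defaults to the
#'   observation's recorded sex but can be overridden (e.g. by the
#'   CNV-stage inference).
#' @param ... passed to \code{\link{classifyEmbryo}} (vote thresholds).
#' @return an \code{\link{EmbryoCall}}.
#' @export
diagnoseEmbryo <- function(obs, panel, sex = obs@sex, ...) {
  stopifnot(is(obs, "EmbryoObservation"), is(panel, "MarkerPanel"))
  mk <- panel@markers
  idx <- match(mk$pos, obs@positions)
  if (anyNA(idx))
    stop("embryo observation lacks some panel marker positions")
  mkl <- as.list(as.data.frame(mk))
  asg <- vapply(seq_len(nrow(mk)), function(i)
    assignMarker(obs@genotypes[idx[i]],
                 list(mutAllele = mkl$mutAllele[i],
                      wtAllele = mkl$wtAllele[i],
                      partner1 = mkl$partner1[i],
                      partner2 = mkl$partner2[i]),
                 embryoSex = sex, xLinked = panel@xLinked),
    character(1))
  classifyEmbryo(asg, mk$pos, panel@geneStart, panel@geneEnd,
                 id = obs@id, directCall = obs@directCall, ...)
}
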