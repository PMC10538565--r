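# Read QC and carrier haplotype phasing by minimum error correction (MEC).
#
# The two-group read partition minimizing total disagreements with the
# group consensus is likelihood-equivalent to maximum likelihood under a
# symmetric per-marker flip error.  Small instances are solved exactly by
# enumeration; larger ones by a greedy left-to-right chaining start (reads
# in genomic order join the group they agree with over already-covered
# sites, so phase information propagates along read overlaps) refined by
# seeded multistart local search.

#' Filter long reads on quality, length and end-crop
#'
#' Mirrors the standard nanopore pass-read filter: reads with mean quality
#' below \code{minQscore} are removed; \code{cropBp} is trimmed from both
#' ends (marker observations inside the trimmed ends are discarded) and the
#' post-crop length must reach \code{minLenBp}.  Crop is applied before the
#' length test.
#'
#' @param reads a \code{\link{SimReadSet}} (from simulation or
#'   \code{\link{readReadTsv}}).
#' @param minQscore minimum mean per-read quality (default 7).
#' @param minLenBp minimum post-crop read length in bp (default 1000).
#' @param cropBp bases trimmed from each read end (default 50).
#' @return a filtered \code{\link{SimReadSet}} (possibly empty).
#' @examples
#' fam <- simulateFamily(seed = 1)
#' rs <- simulateLongReads(fam, depth = 3, seed = 1)
#' qcFilterReads(rs)
#' @export
qcFilterReads <- function(reads, minQscore = 7, minLenBp = 1000,
                          cropBp = 50) {
  stopifnot(is(reads, "SimReadSet"))
  rd <- reads@reads
  if (nrow(rd) == 0L) return(reads)
  newStart <- rd$start + cropBp
  newEnd <- rd$end - cropBp
  keep <- rd$qscore >= minQscore & (newEnd - newStart + 1) >= minLenBp
  obs <- reads@obs[keep, , drop = FALSE]
  rd <- rd[keep, ]
  rd$start <- newStart[keep]
  rd$end <- newEnd[keep]
  if (nrow(rd)) {
    outside <- outer(rd$start, reads@positions, `>`) |
               outer(rd$end, reads@positions, `<`)
    obs[outside] <- NA_integer_
  }
  new("SimReadSet", reads = rd, obs = obs, positions = reads@positions,
      chrom = reads@chrom, mutationIndex = reads@mutationIndex)
}

#' Build the read-by-site allele matrix
#'
#' Restricts reads to those covering at least one heterozygous site and
#' returns the 0/1/NA observation matrix over the requested sites.
#'
#' @param reads a (QC-filtered) \code{\link{SimReadSet}}.
#' @param hetSites site coordinates to keep (default: all sites of
#'   \code{reads}, which for simulated data are the carrier het sites
#'   including the mutation).
#' @return a \code{\link{ReadAlleleMatrix}}; zero rows when no read covers
#'   any site (downstream phase is then unresolved).
#' @export
buildAlleleMatrix <- function(reads, hetSites = NULL) {
  stopifnot(is(reads, "SimReadSet"))
  if (is.null(hetSites)) hetSites <- reads@positions
  if (!length(hetSites)) stop("hetSites must be nonempty")
  hetSites <- sort(unique(hetSites))
  colIdx <- match(hetSites, reads@positions)
  if (anyNA(colIdx))
    stop("hetSites must be a subset of the read set's site positions")
  mat <- reads@obs[, colIdx, drop = FALSE]
  keep <- rowSums(!is.na(mat)) > 0L
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- reads@reads$id[keep]
  mutPos <- if (length(reads@mutationIndex) && !is.na(reads@mutationIndex))
    reads@positions[reads@mutationIndex] else NA_real_
  mi <- if (is.na(mutPos)) NA_integer_ else match(mutPos, hetSites)
  new("ReadAlleleMatrix", mat = mat, positions = hetSites,
      chrom = reads@chrom,
      mutationIndex = if (is.null(mi) || is.na(mi)) NA_integer_
                      else as.integer(mi))
}

#' Minimum-error-correction cost of a read bipartition
#'
#' For each group and site, the cost is the number of reads disagreeing
#' with the within-group majority (the column minority count); the total is
#' summed over both groups and all sites.  Exposed so that the phasing
#' result can be compared against exhaustive search.
#'
#' @param mat 0/1/NA matrix or a \code{\link{ReadAlleleMatrix}}.
#' @param groups integer vector of 1/2 group labels, one per read.
#' @return the MEC cost (non-negative integer).
#' @export
mecCost <- function(mat, groups) {
  if (is(mat, "ReadAlleleMatrix")) mat <- mat@mat
  stopifnot(nrow(mat) == length(groups), all(groups %in% c(1L, 2L)))
  cost <- 0
  for (g in 1:2) {
    sub <- mat[groups == g, , drop = FALSE]
    nAlt <- colSums(sub == 1L, na.rm = TRUE)
    nRef <- colSums(sub == 0L, na.rm = TRUE)
    cost <- cost + sum(pmin(nAlt, nRef))
  }
  cost
}

#' Phase the target region from the allele matrix
#'
#' Partitions reads into two haplotype groups minimizing the MEC cost
#' (exactly for small instances, otherwise greedy chaining plus seeded
#' multistart local search), takes the within-group consensus per site as
#' hap1/hap2, links adjacent sites into a phase block only when at least
#' \code{minOverlapReads} reads span both with at least
#' \code{minSharedSnps} shared informative sites, and assigns the mutation
#' to a haplotype by majority (ties or unlinked mutation columns stay
#' unresolved).
#'
#' @param mat a \code{\link{ReadAlleleMatrix}} (nonempty).
#' @param minOverlapReads reads required to join adjacent sites into one
#'   phase block (default 2).
#' @param minSharedSnps shared informative sites required of a linking
#'   read (default 1; a read observing both adjacent sites shares 2).
#' @param nStarts random restarts for the local search.
#' @param maxIter iteration cap per restart.
#' @param seed seed for the (internal, restart-only) randomness; the
#'   result is deterministic given inputs and seed.
#' @return a \code{\link{PhasedTargetRegion}}.
#' @examples
#' fam <- simulateFamily(nMarkers = 5, windowBp = 2e4, seed = 1)
#' rs <- simulateLongReads(fam, depth = 20, meanLen = 2e4,
#'                         errorRate = 0, seed = 1)
#' ph <- phaseRegion(buildAlleleMatrix(qcFilterReads(rs)))
#' ph
#' @export
phaseRegion <- function(mat, minOverlapReads = 2, minSharedSnps = 1,
                        nStarts = 3, maxIter = 100, seed = 1) {
  stopifnot(is(mat, "ReadAlleleMatrix"))
  m <- mat@mat
  if (nrow(m) == 0L) stop("allele matrix is empty; phase unresolved")
  if (minSharedSnps < 1 || minSharedSnps > 2)
    stop("minSharedSnps must be 1 or 2 under adjacent-pair linking")

  groups <- if (nrow(m) <= 10L && ncol(m) <= 16L) .mecExact(m)
            else .mecSearch(m, nStarts = nStarts, maxIter = maxIter,
                            seed = seed)
  cost <- mecCost(m, groups)

  g1 <- groups == 1L
  alt1 <- colSums(m[g1, , drop = FALSE] == 1L, na.rm = TRUE)
  ref1 <- colSums(m[g1, , drop = FALSE] == 0L, na.rm = TRUE)
  alt2 <- colSums(m[!g1, , drop = FALSE] == 1L, na.rm = TRUE)
  ref2 <- colSums(m[!g1, , drop = FALSE] == 0L, na.rm = TRUE)
  h1 <- ifelse(alt1 > ref1, 1L,
        ifelse(ref1 > alt1, 0L,
        ifelse(alt2 > ref2, 0L, ifelse(ref2 > alt2, 1L, NA_integer_))))
  h1 <- as.integer(h1)
  h2 <- 1L - h1

  nC <- ncol(m)
  support <- if (nC > 1L) {
    obsd <- !is.na(m)
    # a read links sites j, j+1 when it observes both (it then shares two
    # informative sites with the pair, satisfying minSharedSnps of 1 or 2)
    span <- obsd[, -nC, drop = FALSE] & obsd[, -1L, drop = FALSE]
    colSums(span)
  } else numeric(0)
  blockId <- if (nC > 1L)
    as.integer(cumsum(c(1L, support < minOverlapReads))) else 1L

  counts <- rbind(alt1 = alt1, ref1 = ref1, alt2 = alt2, ref2 = ref2)
  mutPos <- if (!is.na(mat@mutationIndex))
    mat@positions[mat@mutationIndex] else NA_real_

  ph <- new("PhasedTargetRegion", chrom = mat@chrom,
            positions = mat@positions, hap1 = h1, hap2 = h2,
            blockId = blockId, blockSupport = as.numeric(support),
            mutationPos = if (is.na(mutPos)) NA_real_ else mutPos,
            mutationHap = "unresolved",
            window = range(mat@positions), groupCounts = counts,
            mecCost = cost)
  if (!is.na(mutPos))
    ph@mutationHap <- assignMutationPhase(ph, mutPos)
  ph
}

#' Assign the de novo mutation to a haplotype
#'
#' The mutation goes to the read group carrying the alternate allele at the
#' mutation site by majority.  Ties, an absent or all-missing mutation
#' column, or a mutation site not linked to any other phased marker
#' (singleton phase block) leave it unresolved.
#'
#' @param phased a \code{\link{PhasedTargetRegion}}.
#' @param mutationPos mutation coordinate (default: the one recorded in
#'   \code{phased}).
#' @return "hap1", "hap2" or "unresolved".
#' @export
assignMutationPhase <- function(phased, mutationPos = phased@mutationPos) {
  stopifnot(is(phased, "PhasedTargetRegion"))
  j <- match(mutationPos, phased@positions)
  if (is.na(j)) return("unresolved")
  if (sum(phased@blockId == phased@blockId[j]) < 2L) return("unresolved")
  cnt <- phased@groupCounts[, j]
  if (sum(cnt) == 0) return("unresolved")
  lean1 <- cnt["alt1"] - cnt["ref1"]
  lean2 <- cnt["alt2"] - cnt["ref2"]
  if (lean1 > lean2) "hap1" else if (lean2 > lean1) "hap2" else "unresolved"
}

# ---- MEC solvers ---------------------------------------------------------

#' Exhaustive MEC over all bipartitions (read 1 pinned to group 1)
#' @noRd
.mecExact <- function(m) {
  nR <- nrow(m)
  if (nR == 1L) return(1L)
  best <- NULL
  bestCost <- Inf
  for (code in 0:(2^(nR - 1L) - 1L)) {
    grp <- c(1L, 1L + bitwAnd(bitwShiftR(code, 0:(nR - 2L)), 1L))
    cost <- mecCost(m, grp)
    if (cost < bestCost) {
      bestCost <- cost
      best <- grp
    }
  }
  best
}

#' Greedy chaining + multistart local search
#' @noRd
.mecSearch <- function(m, nStarts, maxIter, seed) {
  starts <- list(.mecGreedy(m))
  if (nStarts > 1L) {
    extra <- withSeed(seed, lapply(seq_len(nStarts - 1L), function(i)
      sample(c(1L, 2L), nrow(m), replace = TRUE)))
    starts <- c(starts, extra)
  }
  best <- NULL
  bestCost <- Inf
  for (g0 in starts) {
    g <- .mecRefine(m, g0, maxIter)
    cost <- mecCost(m, g)
    if (cost < bestCost) {
      bestCost <- cost
      best <- g
    }
  }
  best
}

#' One left-to-right pass in genomic order: each read joins the group it
#' agrees with over already-assigned overlapping sites.
#' @noRd
.mecGreedy <- function(m) {
  nR <- nrow(m)
  nC <- ncol(m)
  first <- apply(!is.na(m), 1L, which.max)
  ord <- order(first, seq_len(nR))
  grp <- integer(nR)
  cntAlt <- matrix(0L, 2L, nC)
  cntRef <- matrix(0L, 2L, nC)
  for (r in ord) {
    x <- m[r, ]
    j <- which(!is.na(x))
    a <- x[j]
    # disagreement with each group's current tallies
    d1 <- sum(ifelse(a == 1L, cntRef[1L, j], cntAlt[1L, j]))
    d2 <- sum(ifelse(a == 1L, cntRef[2L, j], cntAlt[2L, j]))
    a1 <- sum(ifelse(a == 1L, cntAlt[1L, j], cntRef[1L, j]))
    a2 <- sum(ifelse(a == 1L, cntAlt[2L, j], cntRef[2L, j]))
    # join the group with the better agreement margin; ties -> group 1
    g <- if ((a2 - d2) > (a1 - d1)) 2L else 1L
    grp[r] <- g
    alt <- j[a == 1L]
    ref <- j[a == 0L]
    cntAlt[g, alt] <- cntAlt[g, alt] + 1L
    cntRef[g, ref] <- cntRef[g, ref] + 1L
  }
  grp
}

#' Alternate consensus building and read reassignment to convergence.
#' @noRd
.mecRefine <- function(m, grp, maxIter) {
  nR <- nrow(m)
  nC <- ncol(m)
  for (it in seq_len(maxIter)) {
    cons <- lapply(1:2, function(g) {
      sub <- m[grp == g, , drop = FALSE]
      nAlt <- colSums(sub == 1L, na.rm = TRUE)
      nRef <- colSums(sub == 0L, na.rm = TRUE)
      ifelse(nAlt > nRef, 1L, ifelse(nRef > nAlt, 0L, NA_integer_))
    })
    d <- vapply(1:2, function(g) {
      cm <- matrix(cons[[g]], nR, nC, byrow = TRUE)
      rowSums(m != cm, na.rm = TRUE)
    }, numeric(nR))
    empty <- tabulate(grp, 2L) == 0L
    if (any(empty)) d[, empty] <- Inf
    newGrp <- ifelse(d[, 1L] < d[, 2L], 1L,
              ifelse(d[, 2L] < d[, 1L], 2L, grp))
    if (identical(newGrp, grp)) break
    grp <- as.integer(newGrp)
  }
  grp
}
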