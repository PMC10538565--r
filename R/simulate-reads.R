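#' Simulate long reads over the target window
#'
#' Draws reads alternately from the carrier's two haplotypes (fair coin per
#' read), with gamma-distributed lengths (shape 2, heavy right tail typical
#' of size-selected nanopore libraries), per-marker allele observations
#' flipped independently with \code{errorRate}, and per-read mean quality
#' scores of which a configurable fraction falls below the q=7 filter
#' threshold.
#'
#' @param truth a \code{\link{FamilyTruth}}.
#' @param depth target fold-coverage over the window (> 0).
#' @param meanLen mean read length in bp.
#' @param errorRate per-marker allele flip probability, in [0, 0.5);
#'   at 0.5 the two haplotypes are unidentifiable.
#' @param qBelowFraction expected fraction of reads with mean qscore < 7.
#' @param seed integer seed.
#' @return a \code{\link{SimReadSet}}.
#' @examples
#' fam <- simulateFamily(seed = 1)
#' rs <- simulateLongReads(fam, depth = 5, seed = 2)
#' rs
#' @export
simulateLongReads <- function(truth, depth = 28, meanLen = 14400,
                              errorRate = 0.05, qBelowFraction = 0.1,
                              seed = 1) {
  stopifnot(is(truth, "FamilyTruth"))
  checkScalarCount(depth, "depth", minimum = 1e-9)
  checkScalarCount(meanLen, "meanLen", minimum = 1)
  if (!is.numeric(errorRate) || errorRate < 0 || errorRate >= 0.5)
    stop("errorRate must lie in [0, 0.5): phasing is unidentifiable at 0.5")
  if (qBelowFraction < 0 || qBelowFraction > 1)
    stop("qBelowFraction must lie in [0, 1]")

  m <- truth@markers
  winStart <- truth@geneStart - truth@windowBp
  winEnd <- truth@geneEnd + truth@windowBp
  span <- winEnd - winStart + 1
  nReads <- max(1L, round(depth * span / meanLen))

  withSeed(seed, {
    len <- pmax(200, round(rgamma(nReads, shape = 2, scale = meanLen / 2)))
    start <- floor(runif(nReads, winStart - len + 1, winEnd))
    end <- start + len - 1
    low <- runif(nReads) < qBelowFraction
    qscore <- ifelse(low, runif(nReads, 4, 6.99), runif(nReads, 7, 14))
    hap <- sample(c("mut", "wt"), nReads, replace = TRUE)

    nSites <- nrow(m)
    hapAlt <- rbind(mut = as.integer(m$hapMut == m$alt),
                    wt = as.integer(m$hapWt == m$alt))
    obs <- matrix(NA_integer_, nReads, nSites)
    covered <- outer(start, m$pos, `<=`) & outer(end, m$pos, `>=`)
    src <- hapAlt[hap, , drop = FALSE]
    if (errorRate > 0) {
      flip <- matrix(runif(nReads * nSites) < errorRate, nReads, nSites)
      src <- ifelse(flip, 1L - src, src)
    }
    obs[covered] <- src[covered]

    reads <- DataFrame(id = sprintf("read%05d", seq_len(nReads)),
                       start = start, end = end, qscore = qscore,
                       truthHap = hap)
    new("SimReadSet", reads = reads, obs = obs, positions = m$pos,
        chrom = truth@chrom,
        mutationIndex = which(m$isMutation))
  })
}
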