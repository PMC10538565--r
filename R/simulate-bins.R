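#' Simulate genome-wide 1 Mb bin read counts
#'
#' Per-bin counts are drawn from a negative binomial with mean proportional
#' to \code{(copy/2) * meanReadsPerBin * gcBias(gc)}.  The copy number per
#' bin is 2 on autosomes, sex-scaled on X/Y (XX: 2/0, XY: 1/1), overridden
#' by any supplied CNV events.  The GC bias is a smooth unimodal function
#' of bin GC content (\code{exp(-strength * ((gc - 0.45)/0.1)^2)}); the GC
#' profile itself is a fixed property of the genome, so repeated samples on
#' the same genome share it.
#'
#' @param embryo an \code{\link{EmbryoTruth}} (its sex and CNV events are
#'   used), or a character sex ("XX"/"XY") for a bare karyotype.
#' @param meanReadsPerBin expected diploid reads per bin (>= 1).  The
#'   default 200 is a desk-scaled stand-in for shallow ~5X sequencing
#'   (tens of thousands of 100 bp reads per 1 Mb bin); the count CV is
#'   dominated by \code{dispersion}, so results are insensitive to scale.
#' @param gcProfile optional per-bin GC fractions; default a smooth
#'   deterministic profile shared across calls.
#' @param gcBiasStrength GC bias coefficient (0 = unbiased).
#' @param dispersion negative-binomial dispersion (variance
#'   \code{mu + dispersion * mu^2}); 0 gives Poisson counts.  Default 0.02
#'   reproduces the ~15\% bin-level CV of quasi-linear WGA at 1 Mb.
#' @param cnvEvents optional \code{data.frame(chrom, start, end, copy)}
#'   overriding the sex-derived baseline (used when \code{embryo} is a
#'   bare sex string).
#' @param binSizeBp bin width (default 1 Mb).
#' @param genome named vector of chromosome lengths
#'   (default \code{\link{hg19ChromLengths}()}).
#' @param seed integer seed.
#' @return a \code{\link{BinCountTrack}}.
#' @examples
#' trk <- simulateBinCounts("XY", meanReadsPerBin = 150, seed = 1)
#' trk
#' @export
simulateBinCounts <- function(embryo = "XY", meanReadsPerBin = 200,
                              gcProfile = NULL, gcBiasStrength = 0,
                              dispersion = 0.02, cnvEvents = NULL,
                              binSizeBp = 1e6,
                              genome = hg19ChromLengths(), seed = 1) {
  checkScalarCount(meanReadsPerBin, "meanReadsPerBin")
  checkScalarCount(binSizeBp, "binSizeBp")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (is(embryo, "EmbryoTruth")) {
    sex <- embryo@sex
    cnvEvents <- embryo@cnvEvents
  } else {
    sex <- match.arg(embryo, c("XY", "XX"))
  }
  .validateCnvEvents(cnvEvents)

  bins <- tileGenome(genome, tilewidth = binSizeBp,
                     cut.last.tile.in.chrom = TRUE)
  nBins <- length(bins)
  gc <- if (is.null(gcProfile)) .defaultGcProfile(nBins) else {
    stopifnot(length(gcProfile) == nBins)
    gcProfile
  }

  chr <- sub("^chr", "", as.character(seqnames(bins)))
  copy <- rep(2, nBins)
  copy[chr == "X"] <- if (sex == "XX") 2 else 1
  copy[chr == "Y"] <- if (sex == "XX") 0 else 1
  if (!is.null(cnvEvents) && nrow(as.data.frame(cnvEvents))) {
    ev <- as.data.frame(cnvEvents)
    evGr <- GRanges(ev$chrom,
                    IRanges(pmax(1, ev$start),
                            pmin(ev$end, genome[as.character(ev$chrom)])))
    hits <- findOverlaps(bins, evGr)
    copy[S4Vectors::queryHits(hits)] <- ev$copy[S4Vectors::subjectHits(hits)]
  }

  bias <- .gcBias(gc, gcBiasStrength)
  # partial last tile of each chromosome scales with its width
  mu <- (copy / 2) * meanReadsPerBin * bias * (width(bins) / binSizeBp)
  counts <- withSeed(seed, {
    if (dispersion > 0) rnbinom(nBins, mu = mu, size = 1 / dispersion)
    else rpois(nBins, mu)
  })
  counts[mu == 0] <- 0L

  mcols(bins)$count <- as.numeric(counts)
  mcols(bins)$gc <- gc
  mcols(bins)$copyTruth <- copy
  new("BinCountTrack", bins = bins, binSizeBp = binSizeBp)
}

#' @noRd
.defaultGcProfile <- function(nBins) {
  base <- 0.42 + 0.06 * sin(seq_len(nBins) / 23)
  jit <- withSeed(20230914L, rnorm(nBins, 0, 0.015))
  pmin(pmax(base + jit, 0.30), 0.62)
}

#' @noRd
.gcBias <- function(gc, strength, optimum = 0.45, widthGc = 0.1) {
  exp(-strength * ((gc - optimum) / widthGc)^2)
}
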