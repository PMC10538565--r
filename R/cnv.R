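# Low-coverage CNV calling: GC normalization, circular binary segmentation
# and karyotype rendering.

#' Normalize bin counts by GC content and diploid median
#'
#' Counts are regressed on bin GC content by robust local smoothing
#' (loess, symmetric family) over non-zero autosomal bins and divided by
#' the fit, then scaled so that the autosomal median ratio is 1.0 (the
#' diploid expectation).  An optional external per-bin baseline is divided
#' out bin-wise first.
#'
#' @param track a \code{\link{BinCountTrack}} with at least 100 bins.
#' @param reference optional positive per-bin baseline of the same length.
#' @param gcSpan loess span for the GC fit (default 0.3).
#' @return the track with a \code{normalized} metadata column added.
#' @examples
#' trk <- simulateBinCounts("XY", seed = 1)
#' trk <- normalizeBins(trk)
#' head(S4Vectors::mcols(binCounts(trk))$normalized)
#' @export
normalizeBins <- function(track, reference = NULL, gcSpan = 0.3) {
  stopifnot(is(track, "BinCountTrack"))
  gr <- track@bins
  if (length(gr) < 100) stop("need at least 100 bins to normalize")
  cnt <- mcols(gr)$count
  if (all(cnt == 0)) stop("all-zero track cannot be normalized")
  if (!is.null(reference)) {
    stopifnot(length(reference) == length(gr), all(reference > 0))
    cnt <- cnt / reference
  }
  gc <- mcols(gr)$gc
  auto <- !isSexChrom(seqnames(gr))
  use <- auto & cnt > 0
  if (sum(use) < 30) stop("too few non-zero autosomal bins for GC fit")

  fit <- loess(cnt[use] ~ gc[use], span = gcSpan, degree = 2,
               family = "symmetric",
               control = loess.control(surface = "direct"))
  expected <- predict(fit, newdata = gc)
  fallback <- median(cnt[use])
  expected[!is.finite(expected) | expected <= 0] <- fallback
  ratio <- cnt / expected
  med <- median(ratio[auto & is.finite(ratio)])
  if (!is.finite(med) || med <= 0)
    stop("autosomal median ratio is degenerate")
  mcols(gr)$normalized <- ratio / med
  initialize(track, bins = gr)
}

#' Circular binary segmentation of normalized bin ratios
#'
#' Per chromosome, the arc maximizing a two-sample t-like statistic is
#' found exhaustively and accepted when its permutation p-value is at most
#' \code{alpha}; accepted splits are applied recursively (ternary: before
#' the arc, the arc, after it).  Resulting segments get integer copy
#' numbers via \code{\link{callCopyNumber}}; autosomal segments whose mean
#' ratio is within \code{mergeTol} of 1.0 are pulled back to diploid, and
#' adjacent same-copy segments are merged.  No segment crosses a
#' chromosome boundary.
#'
#' @param track a normalized \code{\link{BinCountTrack}}.
#' @param alpha permutation significance threshold (default 0.01).
#' @param nPerm maximum permutations per split test (default 10000; early
#'   stopping ends hopeless tests sooner).
#' @param seed integer seed for the permutation RNG.
#' @param mergeTol pull-back tolerance around the diploid ratio
#'   (default 0.2).
#' @return a \code{GRanges} of segments with metadata \code{meanRatio},
#'   \code{copyNumber}, \code{nBins}; chromosomes with fewer than 3 bins
#'   are emitted as single segments with a warning.
#' @export
segmentCBS <- function(track, alpha = 0.01, nPerm = 10000, seed = 1,
                       mergeTol = 0.2) {
  stopifnot(is(track, "BinCountTrack"))
  gr <- track@bins
  if (!"normalized" %in% colnames(mcols(gr)))
    stop("run normalizeBins() first")

  withSeed(seed, {
    out <- lapply(unique(as.character(seqnames(gr))), function(ch) {
      sel <- as.character(seqnames(gr)) == ch
      x <- mcols(gr)$normalized[sel]
      st <- start(gr)[sel]
      en <- end(gr)[sel]
      n <- length(x)
      if (n < 3) {
        warning("chromosome ", ch, " has fewer than 3 bins; not segmented")
        bounds <- matrix(c(1L, n), 1L)
      } else {
        bounds <- .cbsRecurse(x, 1L, n, alpha, nPerm)
      }
      segMean <- apply(bounds, 1L, function(b) mean(x[b[1]:b[2]]))
      auto <- !isSexChrom(ch)
      copy <- callCopyNumber(pmax(segMean, 0))
      if (auto) copy[abs(segMean - 1) < mergeTol] <- 2L
      # merge adjacent same-copy segments (weighted mean ratio)
      merged <- .mergeSameCopy(bounds, segMean, copy)
      data.frame(chrom = ch,
                 start = st[merged$lo], end = en[merged$hi],
                 meanRatio = merged$mean, copyNumber = merged$copy,
                 nBins = merged$hi - merged$lo + 1L)
    })
    df <- do.call(rbind, out)
    seg <- GRanges(df$chrom, IRanges(df$start, df$end),
                   seqinfo = GenomeInfoDb::seqinfo(gr))
    mcols(seg)$meanRatio <- df$meanRatio
    mcols(seg)$copyNumber <- df$copyNumber
    mcols(seg)$nBins <- df$nBins
    seg
  })
}

#' @noRd
.cbsRecurse <- function(x, lo, hi, alpha, nPerm) {
  n <- hi - lo + 1L
  if (n < 3L) return(matrix(c(lo, hi), 1L))
  res <- .cbsSplit(x[lo:hi], as.integer(nPerm), alpha)
  if (res$p > alpha || res$j <= res$i)
    return(matrix(c(lo, hi), 1L))
  cuts <- unique(c(0L, res$i, res$j, n))
  cuts <- sort(cuts)
  pieces <- lapply(seq_len(length(cuts) - 1L), function(k)
    .cbsRecurse(x, lo + cuts[k], lo + cuts[k + 1L] - 1L, alpha, nPerm))
  do.call(rbind, pieces)
}

#' @noRd
.mergeSameCopy <- function(bounds, segMean, copy) {
  lo <- bounds[, 1L]
  hi <- bounds[, 2L]
  w <- hi - lo + 1L
  i <- 1L
  outLo <- integer(0); outHi <- integer(0)
  outMean <- numeric(0); outCopy <- integer(0)
  while (i <= length(copy)) {
    j <- i
    while (j < length(copy) && copy[j + 1L] == copy[i]) j <- j + 1L
    ww <- w[i:j]
    outLo <- c(outLo, lo[i])
    outHi <- c(outHi, hi[j])
    outMean <- c(outMean, sum(segMean[i:j] * ww) / sum(ww))
    outCopy <- c(outCopy, copy[i])
    i <- j + 1L
  }
  list(lo = outLo, hi = outHi, mean = outMean, copy = outCopy)
}

#' Integer copy number from a normalized ratio
#'
#' \code{copy = round(2 * ratio)}, with exact .5 boundaries rounded toward
#' the diploid state (conservative: a ratio of 1.25 stays diploid, 1.75
#' becomes 3).  The canonical dose points map as 0.5 -> 1, 1.0 -> 2,
#' 1.5 -> 3 (the plus/minus 50\% read-count rule).
#'
#' @param ratio normalized ratio(s), >= 0.
#' @return integer copy number(s).
#' @examples
#' callCopyNumber(c(0.5, 1, 1.5))
#' @export
callCopyNumber <- function(ratio) {
  if (any(ratio < 0)) stop("ratio must be >= 0")
  x <- 2 * ratio
  f <- floor(x)
  isHalf <- abs(x - f - 0.5) < 1e-9
  cn <- round(x)
  cn[isHalf] <- ifelse(x[isHalf] > 2, f[isHalf], f[isHalf] + 1)
  as.integer(cn)
}

#' Render a cytogenetic karyotype string from segments
#'
#' The total chromosome count is 46 plus whole-chromosome gains minus
#' losses; the sex designation comes from the X/Y mean ratios (expected
#' X = 1, Y = 0 for XX; X = 0.5, Y = 0.5 for XY); whole-chromosome and
#' segmental events of at least \code{minReportBp} are appended as
#' \code{+chrom (xN)} / \code{-chrom(start-end, ~size Mb, xN)}; smaller
#' events are suppressed (recorded in the \code{"suppressed"} attribute).
#' Irreconcilable sex-chromosome ratios (far from any integer copy) are
#' reported as ambiguous with the raw ratios.
#'
#' @param segments segment \code{GRanges} from \code{\link{segmentCBS}}
#'   (with seqlengths, so whole-chromosome events can be recognized).
#' @param sexChromRatios optional named numeric \code{c(X = , Y = )}
#'   overriding the ratios derived from the segments.
#' @param minReportBp minimum reportable segmental event size (default
#'   4 Mb).
#' @return the karyotype string, e.g. \code{"46, XY"} or
#'   \code{"47, XYY, +Y (×2)"}; attributes \code{totalCount},
#'   \code{ambiguous} and \code{suppressed} carry details.
#' @export
karyotypeString <- function(segments, sexChromRatios = NULL,
                            minReportBp = 4e6) {
  stopifnot(is(segments, "GRanges"))
  chr <- as.character(seqnames(segments))
  chromLen <- seqlengths(segments)
  if (any(is.na(chromLen[unique(chr)])))
    stop("segments must carry seqlengths")
  ratio <- mcols(segments)$meanRatio
  copy <- mcols(segments)$copyNumber

  chromRatio <- function(ch) {
    i <- chr == ch
    if (!any(i)) return(NA_real_)
    sum(ratio[i] * width(segments)[i]) / sum(width(segments)[i])
  }
  xName <- grep("X$", unique(chr), value = TRUE)[1]
  yName <- grep("Y$", unique(chr), value = TRUE)[1]
  rx <- if (!is.null(sexChromRatios)) unname(sexChromRatios["X"])
        else if (!is.na(xName)) chromRatio(xName) else 0
  ry <- if (!is.null(sexChromRatios)) unname(sexChromRatios["Y"])
        else if (!is.na(yName)) chromRatio(yName) else 0
  if (is.na(rx)) rx <- 0
  if (is.na(ry)) ry <- 0
  copyX <- callCopyNumber(max(rx, 0))
  copyY <- callCopyNumber(max(ry, 0))
  ambiguous <- max(abs(2 * rx - round(2 * rx)),
                   abs(2 * ry - round(2 * ry))) > 0.3

  autos <- setdiff(unique(chr), c(xName, yName))
  events <- character(0)
  suppressed <- character(0)
  autoCopies <- integer(0)
  for (ch in autos) {
    i <- which(chr == ch)
    wd <- width(segments)[i]
    # a chromosome counts as whole-chromosome aneuploid only when one
    # non-diploid copy state covers (nearly) all of it; otherwise the
    # baseline stays diploid and deviations are segmental events
    byCopy <- tapply(wd, copy[i], sum)
    top <- as.integer(names(byCopy)[which.max(byCopy)])
    modal <- if (top != 2L && max(byCopy) >= 0.9 * chromLen[ch]) top else 2L
    autoCopies <- c(autoCopies, modal)
    label <- sub("^chr", "", ch)
    if (modal != 2L) {
      sign <- if (modal > 2L) "+" else "-"
      events <- c(events,
                  sprintf("%s%s (\u00d7%d)", sign, label, modal))
    }
    seg <- i[copy[i] != modal]
    for (s in seg) {
      wdS <- width(segments)[s]
      ev <- sprintf("%s%s(%d-%d, ~%d Mb, \u00d7%d)",
                    if (copy[s] > modal) "+" else "-", label,
                    start(segments)[s], end(segments)[s],
                    round(wdS / 1e6), copy[s])
      if (wdS >= minReportBp) events <- c(events, ev)
      else suppressed <- c(suppressed, ev)
    }
  }

  total <- sum(autoCopies) + (44L - 2L * length(autos)) + copyX + copyY
  sexDes <- paste0(strrep("X", copyX), strrep("Y", copyY))
  if (!nzchar(sexDes)) sexDes <- "?"
  if (ambiguous)
    sexDes <- sprintf("sex ambiguous (X ratio %.2f, Y ratio %.2f)", rx, ry)
  if (copyY >= 2L)
    events <- c(events, sprintf("+Y (\u00d7%d)", copyY))
  if (copyX >= 2L && copyY >= 1L || copyX >= 3L)
    events <- c(events, sprintf("+X (\u00d7%d)", copyX))

  out <- paste(c(sprintf("%d, %s", total, sexDes), events), collapse = ", ")
  attr(out, "totalCount") <- total
  attr(out, "ambiguous") <- ambiguous
  attr(out, "suppressed") <- suppressed
  out
}

#' Non-diploid segments large enough to report
#'
#' @param segments output of \code{\link{segmentCBS}}.
#' @param minSizeBp reporting threshold (default 4 Mb).
#' @return subset \code{GRanges} of autosomal non-diploid (and sex-chromosome
#'   non-baseline) segments with width at or above the threshold.
#' @export
cnvCalls <- function(segments, minSizeBp = 4e6) {
  keep <- mcols(segments)$copyNumber != 2L &
    !isSexChrom(seqnames(segments))
  segments[keep & width(segments) >= minSizeBp]
}
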