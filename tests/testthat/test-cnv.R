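# GC normalization, circular binary segmentation and karyotype strings.

test_that("self-normalization flattens a diploid track", {
  trk <- simulateBinCounts("XY", meanReadsPerBin = 10000, dispersion = 0,
                           gcBiasStrength = 0, genome = toyGenome4,
                           seed = 1)
  trk <- normalizeBins(trk)
  r <- S4Vectors::mcols(binCounts(trk))$normalized
  expect_lt(abs(mean(r) - 1), 0.01)
  expect_true(all(abs(r - 1) < 0.05))
})

test_that("GC correction removes an injected GC bias", {
  trk <- simulateBinCounts("XY", meanReadsPerBin = 500,
                           gcBiasStrength = 0.3, genome = toyGenome4,
                           seed = 2)
  gr <- binCounts(trk)
  rawCor <- cor(S4Vectors::mcols(gr)$count, S4Vectors::mcols(gr)$gc)
  expect_gt(abs(rawCor), 0.2)                    # the bias is really there
  trk <- normalizeBins(trk)
  gr <- binCounts(trk)
  postCor <- cor(S4Vectors::mcols(gr)$normalized, S4Vectors::mcols(gr)$gc)
  expect_lt(abs(postCor), 0.05)
})

test_that("a trisomic chromosome normalizes to a 1.5 ratio", {
  ev <- data.frame(chrom = "chr4", start = 1, end = 200e6, copy = 3)
  trk <- normalizeBins(simulateBinCounts("XY", cnvEvents = ev,
                                         genome = toyGenome4, seed = 3))
  gr <- binCounts(trk)
  sel <- as.character(GenomicRanges::seqnames(gr)) == "chr4"
  expect_lt(abs(mean(S4Vectors::mcols(gr)$normalized[sel]) - 1.5), 0.05)
})

test_that("normalization rejects degenerate tracks", {
  trk <- simulateBinCounts("XY", genome = c(chr1 = 50e6), seed = 4)
  expect_error(normalizeBins(trk), "100 bins")
  trk2 <- simulateBinCounts("XY", genome = toyGenome4, seed = 5)
  S4Vectors::mcols(trk2@bins)$count <- 0
  expect_error(normalizeBins(trk2), "all-zero")
})

test_that("copy-number calling follows the dose rule with conservative
           half-way rounding", {
  expect_identical(callCopyNumber(c(0.5, 1, 1.5)), c(1L, 2L, 3L))
  # exact .5 copy boundaries round toward diploid
  expect_identical(callCopyNumber(c(0.75, 1.25, 1.75, 0.25)),
                   c(2L, 2L, 3L, 1L))
  expect_identical(callCopyNumber(0), 0L)
  expect_error(callCopyNumber(-0.1), ">= 0")
})

test_that("the compiled best-split search matches a plain-R exhaustive
           oracle on small instances", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n) + rep(c(0, sample(c(0, 1.5), 1)),
                        c(n %/% 2, n - n %/% 2))
    got <- denovoPGT:::.cbsMaxStat(x)
    ref <- refBestArc(x)
    expect_equal(got$stat, ref$stat, tolerance = 1e-10)
    expect_equal(c(got$i, got$j), c(ref$i, ref$j))
  }
})

test_that("a 27-bin single-copy loss is recovered within one bin", {
  ev <- data.frame(chrom = "chr1", start = 40e6 + 1, end = 67e6, copy = 1)
  for (s in 1:5) {
    trk <- normalizeBins(simulateBinCounts("XY", cnvEvents = ev,
                                           genome = toyGenome2, seed = s))
    seg <- segmentCBS(trk, seed = s)
    loss <- seg[S4Vectors::mcols(seg)$copyNumber == 1]
    expect_equal(length(loss), 1)
    expect_lte(abs(GenomicRanges::start(loss) - (40e6 + 1)), 1e6)
    expect_lte(abs(GenomicRanges::end(loss) - 67e6), 1e6)
  }
})

test_that("pure diploid noise yields no non-diploid segments", {
  for (s in 31:35) {
    trk <- normalizeBins(simulateBinCounts("XY", genome = toyGenome2,
                                           seed = s))
    seg <- segmentCBS(trk, seed = s)
    expect_true(all(S4Vectors::mcols(seg)$copyNumber == 2))
  }
})

test_that("segments never cross chromosome boundaries", {
  # a copy step exactly at the chr4/chr5 boundary
  ev <- data.frame(chrom = "chr5", start = 1, end = 40e6, copy = 3)
  trk <- normalizeBins(simulateBinCounts("XY", cnvEvents = ev,
                                         genome = toyGenome5, seed = 6))
  seg <- segmentCBS(trk, seed = 6)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(seg)),
                   start = GenomicRanges::start(seg),
                   end = GenomicRanges::end(seg))
  expect_equal(sum(df$chrom == "chr4"), 1)       # chr4 one diploid segment
  expect_equal(sum(df$chrom == "chr5"), 1)       # chr5 one trisomic segment
  expect_true(all(df$end[df$chrom == "chr4"] <= 200e6))
  expect_identical(
    S4Vectors::mcols(seg)$copyNumber[df$chrom == "chr5"], 3L)
})

test_that("segmentation and karyotype are invariant to count rescaling", {
  ev <- data.frame(chrom = "chr1", start = 40e6 + 1, end = 67e6, copy = 1)
  trk <- simulateBinCounts("XY", cnvEvents = ev, genome = toyGenome2,
                           seed = 7)
  trk7 <- trk
  S4Vectors::mcols(trk7@bins)$count <-
    S4Vectors::mcols(trk7@bins)$count * 7
  seg <- segmentCBS(normalizeBins(trk), seed = 8)
  seg7 <- segmentCBS(normalizeBins(trk7), seed = 8)
  expect_equal(GenomicRanges::start(seg), GenomicRanges::start(seg7))
  expect_equal(S4Vectors::mcols(seg)$copyNumber,
               S4Vectors::mcols(seg7)$copyNumber)
  expect_equal(S4Vectors::mcols(seg)$meanRatio,
               S4Vectors::mcols(seg7)$meanRatio, tolerance = 1e-8)
})

test_that("whole-chromosome aneuploidy detection at study-scale counts", {
  evT <- data.frame(chrom = "chr3", start = 1, end = 240e6, copy = 3)
  evM <- data.frame(chrom = "chr4", start = 1, end = 200e6, copy = 1)
  for (s in 41:45) {
    trk <- normalizeBins(simulateBinCounts(
      "XY", cnvEvents = rbind(evT, evM), meanReadsPerBin = 100,
      genome = toyGenome4, seed = s))
    seg <- segmentCBS(trk, seed = s)
    cp <- S4Vectors::mcols(seg)$copyNumber
    chrOf <- as.character(GenomicRanges::seqnames(seg))
    expect_true(all(cp[chrOf == "chr3"] == 3L))
    expect_true(all(cp[chrOf == "chr4"] == 1L))
    expect_true(all(cp[chrOf %in% c("chr1", "chr2")] == 2L))
  }
})

test_that("karyotype strings mirror the clinical notation", {
  # euploid male / female
  kXY <- karyotypeString(segmentCBS(normalizeBins(
    simulateBinCounts("XY", seed = 51)), seed = 51))
  expect_identical(as.character(kXY), "46, XY")
  kXX <- karyotypeString(segmentCBS(normalizeBins(
    simulateBinCounts("XX", seed = 52)), seed = 52))
  expect_identical(as.character(kXX), "46, XX")

  # double Y
  evY <- data.frame(chrom = "chrY", start = 1, end = 59373566, copy = 2)
  kYY <- karyotypeString(segmentCBS(normalizeBins(
    simulateBinCounts("XY", cnvEvents = evY, seed = 53)), seed = 53))
  expect_equal(attr(kYY, "totalCount"), 47)
  expect_match(as.character(kYY), "^47, XYY")
  expect_match(as.character(kYY), "\\+Y \\(×2\\)")

  # a 3 Mb deletion is suppressed by the 4 Mb reporting rule
  ev3 <- data.frame(chrom = "chr5", start = 50e6 + 1, end = 53e6, copy = 1)
  k3 <- karyotypeString(segmentCBS(normalizeBins(
    simulateBinCounts("XY", cnvEvents = ev3, meanReadsPerBin = 2000,
                      dispersion = 0.002, seed = 54)), seed = 54))
  expect_identical(as.character(k3), "46, XY")
  expect_gte(length(attr(k3, "suppressed")), 1)

  # a 27 Mb segmental loss is reported with size and copy
  ev27 <- data.frame(chrom = "chr21", start = 14e6 + 1, end = 41e6,
                     copy = 1)
  k27 <- karyotypeString(segmentCBS(normalizeBins(
    simulateBinCounts("XY", cnvEvents = ev27, seed = 55)), seed = 55))
  expect_match(as.character(k27), "^46, XY, -21\\(")
  # boundaries are localized to within one bin, so 26-28 Mb
  expect_match(as.character(k27), "~2[678] Mb, ×1")

  # irreconcilable sex ratios are reported as ambiguous with raw ratios
  seg <- segmentCBS(normalizeBins(simulateBinCounts("XY", seed = 56)),
                    seed = 56)
  kAmb <- karyotypeString(seg, sexChromRatios = c(X = 0.67, Y = 0.02))
  expect_true(attr(kAmb, "ambiguous"))
  expect_match(as.character(kAmb), "ambiguous")
  expect_match(as.character(kAmb), "0\\.67")
})
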