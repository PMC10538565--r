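# Synthetic-family generators: determinism, stated distributions, and the
# statistical structure downstream stages rely on.

test_that("simulateFamily meets its contract and is deterministic", {
  fam <- simulateFamily(nMarkers = 30, windowBp = 2e6, seed = 1)
  m <- markers(fam)
  expect_equal(sum(!m$isMutation), 30)
  expect_true(all(m$pos >= fam@geneStart - 2e6 & m$pos <= fam@geneEnd + 2e6))
  expect_true(all(m$hapMut != m$hapWt))        # carrier het everywhere
  expect_true(fam@mutationPos >= fam@geneStart &&
              fam@mutationPos <= fam@geneEnd)
  expect_identical(fam, simulateFamily(nMarkers = 30, windowBp = 2e6,
                                       seed = 1))
  expect_false(identical(m, markers(simulateFamily(nMarkers = 30, seed = 2))))

  one <- markers(simulateFamily(nMarkers = 1, seed = 5))
  expect_equal(sum(!one$isMutation), 1)
  expect_true(all(one$hapMut != one$hapWt))

  expect_error(simulateFamily(nMarkers = 0), "nMarkers")
  expect_error(simulateFamily(windowBp = -1), "windowBp")
})

test_that("marker density requests scale with the window", {
  fam <- simulateFamily(markerDensity = 100, windowBp = 1e6, seed = 3)
  expect_equal(sum(!markers(fam)$isMutation), 200)
})

test_that("simulated read lengths and quality scores match the request", {
  fam <- simulateFamily(seed = 1)
  rs <- simulateLongReads(fam, depth = 28, meanLen = 14400,
                          qBelowFraction = 0.15, seed = 2)
  rd <- rs@reads
  expect_gt(nrow(rd), 1000)
  len <- rd$end - rd$start + 1
  expect_lt(abs(mean(len) - 14400) / 14400, 0.05)
  expect_lt(abs(mean(rd$qscore < 7) - 0.15), 0.03)
  expect_identical(rs, simulateLongReads(fam, depth = 28, meanLen = 14400,
                                         qBelowFraction = 0.15, seed = 2))
  expect_error(simulateLongReads(fam, errorRate = 0.5), "errorRate")
  expect_error(simulateLongReads(fam, depth = 0), "depth")
})

test_that("noiseless reads are exact substrings of one truth haplotype", {
  fam <- simulateFamily(nMarkers = 25, windowBp = 1e5, seed = 4)
  rs <- simulateLongReads(fam, depth = 10, meanLen = 5e4, errorRate = 0,
                          seed = 5)
  m <- markers(fam)
  hapAlt <- rbind(mut = as.integer(m$hapMut == m$alt),
                  wt = as.integer(m$hapWt == m$alt))
  for (r in seq_len(nrow(rs@reads))) {
    j <- which(!is.na(rs@obs[r, ]))
    if (!length(j)) next
    fromMut <- all(rs@obs[r, j] == hapAlt["mut", j])
    fromWt <- all(rs@obs[r, j] == hapAlt["wt", j])
    expect_true(fromMut || fromWt)
    expect_true(xor(fromMut, fromWt) || length(j) == 0 ||
                all(hapAlt["mut", j] == hapAlt["wt", j]))
  }
})

test_that("embryo observations equal the inherited haplotype when ADO = 0", {
  fam <- simulateFamily(nMarkers = 30, seed = 1)
  em <- simulateEmbryos(fam, n = 6, adoRate = 0, recombProb = 0,
                        sexes = rep("XY", 6), seed = 2)
  m <- markers(fam)
  for (e in em) {
    expected <- if (e$truth@inheritedHap == "mut") m$hapMut else m$hapWt
    expect_identical(e$observation@genotypes, as.character(expected))
    expect_identical(e$observation@directCall,
                     if (e$truth@inheritedHap == "mut") "mut" else "wt")
  }
  expect_identical(em, simulateEmbryos(fam, n = 6, adoRate = 0,
                                       recombProb = 0,
                                       sexes = rep("XY", 6), seed = 2))
})

test_that("allele dropout hits the requested fraction of observations", {
  fam <- simulateFamily(nMarkers = 30, seed = 1)
  em <- simulateEmbryos(fam, n = 100, adoRate = 0.1,
                        sexes = rep("XY", 100), seed = 3)
  dropped <- vapply(em, function(e)
    sum(e$observation@genotypes == "."), numeric(1))
  total <- 100 * length(positions(em[[1]]$observation))
  frac <- sum(dropped) / total
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / total) + 0.005)
})

test_that("a 5-of-8 inheritance draw classifies five embryos affected", {
  fam <- simulateFamily(nMarkers = 60, seed = 1)
  em <- simulateEmbryos(fam, n = 8, adoRate = 0, recombProb = 0, seed = 4)
  nMut <- sum(vapply(em, function(e) e$truth@inheritedHap == "mut",
                     logical(1)))
  expect_equal(nMut, 5)
  panel <- selectInformativeSnps(truthPhase(fam), fam)
  dx <- vapply(em, function(e)
    diagnosis(diagnoseEmbryo(e$observation, panel)), character(1))
  expect_equal(sum(dx == "affected"), 5)
  expect_equal(sum(dx == "unaffected"), 3)
})

test_that("embryo simulation rejects invalid parameters", {
  fam <- simulateFamily(seed = 1)
  expect_error(simulateEmbryos(fam, n = 0), "n")
  expect_error(simulateEmbryos(fam, adoRate = 1), "adoRate")
  badSpec <- rep(list(data.frame(chrom = "chr1",
                                 start = c(1, 5e6),
                                 end = c(10e6, 8e6),
                                 copy = c(3, 1))), 2)
  expect_error(simulateEmbryos(fam, n = 2, cnvSpec = badSpec),
               "overlapping")
})

test_that("bin counts are unbiased, dose-linear and deterministic", {
  trk <- simulateBinCounts("XY", meanReadsPerBin = 100, gcBiasStrength = 0,
                           genome = toyGenome4, seed = 1)
  gr <- binCounts(trk)
  full <- GenomicRanges::width(gr) == 1e6
  expect_gt(sum(full), 1000)
  expect_lt(abs(mean(S4Vectors::mcols(gr)$count[full]) - 100) / 100, 0.02)
  expect_identical(trk, simulateBinCounts("XY", meanReadsPerBin = 100,
                                          gcBiasStrength = 0,
                                          genome = toyGenome4, seed = 1))

  # trisomy: +50% raw counts; nullisomy: all zero
  ev <- data.frame(chrom = c("chr3", "chr4"),
                   start = c(1, 1), end = c(240e6, 200e6),
                   copy = c(3, 0))
  trk2 <- simulateBinCounts("XY", meanReadsPerBin = 100,
                            cnvEvents = ev, genome = toyGenome4, seed = 2)
  gr2 <- binCounts(trk2)
  chr <- as.character(GenomicRanges::seqnames(gr2))
  mTri <- mean(S4Vectors::mcols(gr2)$count[chr == "chr3" & full])
  mDip <- mean(S4Vectors::mcols(gr2)$count[chr %in% c("chr1", "chr2") & full])
  expect_lt(abs(mTri / mDip - 1.5), 0.05)
  expect_true(all(S4Vectors::mcols(gr2)$count[chr == "chr4"] == 0))

  # regression of mean count on copy number: slope = meanReadsPerBin / 2
  copies <- c(1, 2, 3, 4)
  means <- vapply(copies, function(cp) {
    evc <- data.frame(chrom = "chr1", start = 1, end = 300e6, copy = cp)
    t <- simulateBinCounts("XY", meanReadsPerBin = 100, cnvEvents = evc,
                           genome = toyGenome4, seed = 10 + cp)
    g <- binCounts(t)
    sel <- as.character(GenomicRanges::seqnames(g)) == "chr1" &
      GenomicRanges::width(g) == 1e6
    mean(S4Vectors::mcols(g)$count[sel])
  }, numeric(1))
  slope <- coef(lm(means ~ copies))[2]
  expect_lt(abs(slope - 50) / 50, 0.05)
})
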