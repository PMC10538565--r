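# Informative-marker selection and embryo diagnosis.

test_that("informative-marker rules: hemizygous partner kept, heterozygous
           partner excluded, nearest-to-gene capping", {
  fam <- simulateFamily(nMarkers = 80, seed = 9)
  panel <- selectInformativeSnps(truthPhase(fam), fam)
  mk <- markers(panel)
  expect_true(all(is.na(mk$partner2)))           # hemizygous partner: "A/"
  expect_lte(sum(mk$side == "upstream"), 15)
  expect_lte(sum(mk$side == "downstream"), 15)
  expect_true(all(mk$distanceBp <= 2e6))
  # kept markers are the closest-to-gene candidates on each side
  mAll <- markers(fam)[!markers(fam)$isMutation, ]
  candUp <- sort(fam@geneStart - mAll$pos[mAll$pos < fam@geneStart])
  candDn <- sort(mAll$pos[mAll$pos > fam@geneEnd] - fam@geneEnd)
  expect_identical(sort(mk$distanceBp[mk$side == "upstream"]),
                   candUp[seq_len(sum(mk$side == "upstream"))])
  expect_identical(sort(mk$distanceBp[mk$side == "downstream"]),
                   candDn[seq_len(sum(mk$side == "downstream"))])

  # autosomal couple: partner-heterozygous sites must be excluded
  famA <- simulateFamily(nMarkers = 60, xLinked = FALSE,
                         partnerHetFraction = 0.5, seed = 10)
  panelA <- selectInformativeSnps(truthPhase(famA), famA)
  mkA <- markers(panelA)
  expect_true(all(mkA$partner1 == mkA$partner2))
  mAll <- markers(famA)
  het <- !is.na(mAll$partner2) & mAll$partner1 != mAll$partner2
  expect_false(any(mAll$pos[het] %in% mkA$pos))
})

test_that("an unresolved carrier phase cannot yield a panel", {
  fam <- simulateFamily(seed = 1)
  ph <- truthPhase(fam)
  ph@mutationHap <- "unresolved"
  expect_error(selectInformativeSnps(ph, fam), "unresolved")
})

test_that("marker assignment follows the worked inheritance example", {
  # partner A/ (hemizygous), carrier A|B with B on the mutant haplotype
  mk <- list(mutAllele = "B", wtAllele = "A",
             partner1 = "A", partner2 = NA_character_)
  # XX embryo observed AB: subtract paternal A -> maternal B -> mutant hap
  expect_identical(assignMarker("A/B", mk, "XX"), "mut")
  expect_identical(assignMarker("A/A", mk, "XX"), "wt")
  # XY embryo: hemizygous read-off
  expect_identical(assignMarker("B", mk, "XY"), "mut")
  expect_identical(assignMarker("A", mk, "XY"), "wt")
  # missing and partial observations
  expect_identical(assignMarker("./.", mk, "XX"), "missing")
  expect_identical(assignMarker(".", mk, "XY"), "missing")
  expect_identical(assignMarker("A/.", mk, "XX"), "uninformative")
  expect_identical(assignMarker("B/.", mk, "XX"), "mut")
  # allele seen in neither parent
  expect_identical(assignMarker("C/A", mk, "XX"), "inconsistent")
  expect_identical(assignMarker("C", mk, "XY"), "inconsistent")
  # dropout-to-homozygote pattern: carrier allele duplicated
  expect_identical(assignMarker("B/B", mk, "XX"), "mut")
})

test_that("per-marker assignments partition the panel (vote conservation)", {
  fam <- simulateFamily(nMarkers = 60, seed = 11)
  panel <- selectInformativeSnps(truthPhase(fam), fam)
  em <- simulateEmbryos(fam, n = 20, adoRate = 0.2, seed = 12)
  for (e in em) {
    cl <- diagnoseEmbryo(e$observation, panel)
    a <- assignments(cl)
    expect_equal(length(a), nrow(markers(panel)))
    expect_equal(sum(a == "mut") + sum(a == "wt") +
                 sum(a == "uninformative") + sum(a == "missing") +
                 sum(a == "inconsistent"), length(a))
    expect_lte(cl@voteMut + cl@voteWt, length(a))
  }
})

test_that("classification thresholds gate the diagnosis", {
  pos <- seq(1e6, 30e6, length.out = 30)
  gs <- 31e6; ge <- 32e6
  all30 <- rep("mut", 30)
  expect_identical(diagnosis(classifyEmbryo(all30, pos, gs, ge)), "affected")
  few <- c(rep("mut", 5), rep("missing", 25))
  cl <- classifyEmbryo(few, pos, gs, ge)
  expect_identical(diagnosis(cl), "inconclusive")
  expect_match(cl@reason, "below minimum")
  mixed <- c(rep("mut", 12), rep("wt", 5), rep("missing", 13))
  clM <- classifyEmbryo(mixed, pos, gs, ge, recombMinRun = 31)
  expect_identical(diagnosis(clM), "inconclusive")
  expect_match(clM@reason, "margin")
  allMissing <- classifyEmbryo(rep("missing", 30), pos, gs, ge)
  expect_identical(diagnosis(allMissing), "inconclusive")
  expect_match(allMissing@reason, "no informative")
})

test_that("a block switch is flagged as recombination and votes restrict
           to the gene-side block", {
  # gene downstream of all markers: 10 mut then 20 wt -> gene side is wt
  pos <- seq(1e6, 30e6, length.out = 30)
  asg <- c(rep("mut", 10), rep("wt", 20))
  cl <- classifyEmbryo(asg, pos, geneStart = 40e6, geneEnd = 41e6)
  expect_identical(diagnosis(cl), "unaffected")
  expect_length(cl@recombination, 2)
  expect_equal(cl@voteWt, 20)
  expect_equal(cl@voteMut, 0)

  # switch straddling the gene: honestly inconclusive
  pos2 <- c(seq(1e6, 15e6, length.out = 15), seq(45e6, 59e6, length.out = 15))
  asg2 <- c(rep("mut", 15), rep("wt", 15))
  cl2 <- classifyEmbryo(asg2, pos2, geneStart = 30e6, geneEnd = 31e6)
  expect_identical(diagnosis(cl2), "inconclusive")
  expect_length(cl2@recombination, 2)
  expect_match(cl2@reason, "recombination")
})

test_that("increasing dropout only moves calls toward inconclusive", {
  fam <- simulateFamily(nMarkers = 60, seed = 13)
  panel <- selectInformativeSnps(truthPhase(fam), fam)
  for (ado in c(0, 0.1, 0.2, 0.4, 0.6)) {
    em <- simulateEmbryos(fam, n = 30, adoRate = ado, seed = 14)
    for (e in em) {
      dx <- diagnosis(diagnoseEmbryo(e$observation, panel))
      truthDx <- if (e$truth@inheritedHap == "mut") "affected"
                 else "unaffected"
      expect_true(dx %in% c(truthDx, "inconclusive"))
    }
  }
})

test_that("concordance compares linkage and direct detection", {
  expect_true(concordance("affected", "mut"))
  expect_true(concordance("unaffected", "wt"))
  expect_false(concordance("affected", "wt"))
  expect_false(concordance("unaffected", "mut"))
  expect_true(is.na(concordance("inconclusive", "mut")))
  expect_true(is.na(concordance("affected", "missing")))

  fam <- simulateFamily(nMarkers = 60, seed = 15)
  panel <- selectInformativeSnps(truthPhase(fam), fam)
  em <- simulateEmbryos(fam, n = 8, adoRate = 0, seed = 16)
  conc <- vapply(em, function(e)
    diagnoseEmbryo(e$observation, panel)@concordant, logical(1))
  expect_true(all(conc))                         # 8/8 noiseless concordance
})
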