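# Simulate -> phase -> panel -> diagnose -> CNV -> report orchestration.

#' Build a validated pipeline configuration
#'
#' Flat key-value parameter bundle for \code{\link{runPipeline}}; any
#' argument overrides its default.  Defaults mirror the workflow's stated
#' operating point: a ±2 Mb window, q ≥ 7 / ≥1 kb / 50 bp-crop read QC,
#' 28X long reads of mean 14.4 kb, ≤15 informative markers per side,
#' vote thresholds 10 / 0.8, 1 Mb bins with a ≥4 Mb reporting rule and
#' CBS at alpha 0.01 with 10000 permutations.
#'
#' @param ... parameter overrides (see \code{runConfig()$params} for the
#'   full set of names).
#' @return a \code{\link{RunConfig}}.
#' @examples
#' cfg <- runConfig(nEmbryos = 4, seed = 7)
#' cfg
#' @export
runConfig <- function(...) {
  p <- list(
    # locus & family
    chrom = "chrX", geneStart = 20168001, geneEnd = 20285000,
    windowBp = 2e6, xLinked = TRUE,
    markerDensity = 250,      # carrier het sites per Mb used for phasing
    # long reads
    depth = 28, meanLen = 14400, readErrorRate = 0.05,
    qBelowFraction = 0.1,
    # read QC
    minQscore = 7, minLenBp = 1000, cropBp = 50,
    # phasing
    minOverlapReads = 2, minSharedSnps = 1,
    # panel & diagnosis
    maxPerSide = 15, minVotes = 10, minMarginFraction = 0.8,
    # embryos
    nEmbryos = 8, adoRate = 0.05, recombProb = 0, sexes = NULL,
    cnvSpec = NULL,
    # bin counts & CNV
    binSizeBp = 1e6, meanReadsPerBin = 200, gcBiasStrength = 0.3,
    dispersion = 0.02, alpha = 0.01, nPerm = 10000, reportMinBp = 4e6,
    seed = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  for (k in c("windowBp", "depth", "meanLen", "minQscore", "minLenBp",
              "maxPerSide", "minVotes", "binSizeBp", "meanReadsPerBin",
              "nPerm"))
    checkScalarCount(p[[k]], k, minimum = 1e-9)
  if (p$nEmbryos < 1) stop("nEmbryos must be >= 1")
  new("RunConfig", params = p)
}

#' Run the full PGT-M workflow on a simulated family
#'
#' Executes every stage in order on synthetic inputs: family truth,
#' long-read simulation, read QC, allele-matrix construction, MEC phasing
#' with mutation assignment, informative-marker selection, embryo
#' simulation, per-embryo linkage diagnosis, bin-count simulation,
#' GC normalization, CBS segmentation, karyotyping, and the final report.
#' Embryo sex is inferred from the CNV-stage X/Y ratios and fed to the
#' linkage stage (hemizygosity handling); a mismatch with the
#' genotype-implied sex raises a flag column.
#'
#' @param config a \code{\link{RunConfig}}.
#' @param outDir optional directory; when given, the phased VCF, panel
#'   TSV, marker matrix, per-embryo SEG files and the report TSV are
#'   written there.
#' @param strict when \code{TRUE}, error if any embryo is inconclusive.
#' @return invisibly, a list with \code{report} (data.frame, one row per
#'   embryo), \code{family}, \code{phased}, \code{panel}, \code{embryos},
#'   \code{calls}, \code{tracks}, \code{segments}, \code{karyotypes}.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL,
                        strict = FALSE) {
  stopifnot(is(config, "RunConfig"))
  p <- config@params
  if (p$nEmbryos < 1) stop("nEmbryos must be >= 1")
  seeds <- deriveSeeds(p$seed, 4 + p$nEmbryos)
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[%5.1fs] %s",
    as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))

  stage("simulating family truth")
  fam <- simulateFamily(markerDensity = p$markerDensity,
                        windowBp = p$windowBp, seed = seeds[1],
                        chrom = p$chrom, geneStart = p$geneStart,
                        geneEnd = p$geneEnd, xLinked = p$xLinked)

  stage("simulating long reads")
  rs <- simulateLongReads(fam, depth = p$depth, meanLen = p$meanLen,
                          errorRate = p$readErrorRate,
                          qBelowFraction = p$qBelowFraction,
                          seed = seeds[2])

  stage("read QC and phasing")
  rsF <- qcFilterReads(rs, minQscore = p$minQscore,
                       minLenBp = p$minLenBp, cropBp = p$cropBp)
  ram <- buildAlleleMatrix(rsF)
  phased <- phaseRegion(ram, minOverlapReads = p$minOverlapReads,
                        minSharedSnps = p$minSharedSnps)
  if (phased@mutationHap == "unresolved")
    stop("phasing stage: mutation could not be linked to a haplotype")

  stage("selecting informative markers")
  panel <- selectInformativeSnps(phased, fam, windowBp = p$windowBp,
                                 maxPerSide = p$maxPerSide)

  stage("simulating embryos")
  embryos <- simulateEmbryos(fam, n = p$nEmbryos, adoRate = p$adoRate,
                             recombProb = p$recombProb,
                             cnvSpec = p$cnvSpec, sexes = p$sexes,
                             seed = seeds[3])

  stage("CNV stage: bin counts, segmentation, karyotypes")
  tracks <- list(); segments <- list(); karyotypes <- character(0)
  sexInferred <- character(0)
  for (i in seq_len(p$nEmbryos)) {
    trk <- simulateBinCounts(embryos[[i]]$truth,
                             meanReadsPerBin = p$meanReadsPerBin,
                             gcBiasStrength = p$gcBiasStrength,
                             dispersion = p$dispersion,
                             binSizeBp = p$binSizeBp,
                             seed = seeds[4 + i])
    trk <- normalizeBins(trk)
    seg <- segmentCBS(trk, alpha = p$alpha, nPerm = p$nPerm,
                      seed = seeds[4 + i])
    kar <- karyotypeString(seg, minReportBp = p$reportMinBp)
    id <- embryos[[i]]$truth@id
    tracks[[id]] <- trk
    segments[[id]] <- seg
    karyotypes[id] <- as.character(kar)
    ratioOf <- function(ch) {
      j <- as.character(seqnames(seg)) == ch
      sum(mcols(seg)$meanRatio[j] * width(seg)[j]) / sum(width(seg)[j])
    }
    sexInferred[id] <-
      if (callCopyNumber(max(ratioOf("chrY"), 0)) >= 1L) "XY" else "XX"
  }

  stage("embryo linkage diagnosis")
  calls <- lapply(seq_len(p$nEmbryos), function(i) {
    obs <- embryos[[i]]$observation
    diagnoseEmbryo(obs, panel, sex = sexInferred[obs@id],
                   minVotes = p$minVotes,
                   minMarginFraction = p$minMarginFraction)
  })

  report <- do.call(rbind, lapply(seq_len(p$nEmbryos), function(i) {
    cl <- calls[[i]]
    obs <- embryos[[i]]$observation
    data.frame(
      embryo_id = cl@id,
      karyotype = karyotypes[cl@id],
      haplotype_mutation = c(affected = "YES", unaffected = "NO",
                             inconclusive = "INCONCLUSIVE")[cl@diagnosis],
      direct_mutation = c(mut = "YES", wt = "NO",
                          missing = "NA")[cl@directCall],
      concordant = cl@concordant,
      vote_mut = cl@voteMut, vote_wt = cl@voteWt,
      recombination = length(cl@recombination) > 0,
      inconsistent_markers = cl@inconsistencyCount,
      sex_inferred = sexInferred[cl@id],
      sex_mismatch = sexInferred[cl@id] != obs@sex,
      reason = cl@reason,
      row.names = NULL, stringsAsFactors = FALSE)
  }))

  if (strict && any(report$haplotype_mutation == "INCONCLUSIVE"))
    stop("strict mode: at least one embryo is inconclusive")

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFamilyVcf(fam, file.path(outDir, "family.vcf"),
                   phased = phased, embryos = embryos)
    write.table(as.data.frame(panel@markers),
                file.path(outDir, "panel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeMarkerMatrix(panel, calls,
                      file.path(outDir, "marker_matrix.tsv"))
    for (id in names(segments))
      writeSeg(segments[[id]],
               file.path(outDir, sprintf("%s.seg", id)), sample = id)
    renderReport(report, file = file.path(outDir, "report.tsv"))
  }

  stage("done")
  invisible(list(report = report, family = fam, phased = phased,
                 panel = panel, embryos = embryos, calls = calls,
                 tracks = tracks, segments = segments,
                 karyotypes = karyotypes))
}

#' Render the embryo report to TSV or markdown
#'
#' @param report the report data.frame from \code{\link{runPipeline}}.
#' @param format "tsv" or "markdown".
#' @param file output path, or \code{NULL} to return the lines.
#' @return the file path (or the formatted lines when \code{file} is
#'   \code{NULL}), invisibly.
#' @export
renderReport <- function(report, format = c("tsv", "markdown"),
                         file = NULL) {
  format <- match.arg(format)
  if (!is.data.frame(report) || nrow(report) == 0L)
    stop("report is empty")
  cols <- c("embryo_id", "karyotype", "haplotype_mutation",
            "direct_mutation", "concordant", "vote_mut", "vote_wt",
            "recombination", "inconsistent_markers", "sex_inferred",
            "sex_mismatch", "reason")
  cols <- c(intersect(cols, colnames(report)),
            setdiff(colnames(report), cols))
  report <- report[, cols, drop = FALSE]
  if (format == "tsv") {
    if (is.null(file)) {
      lines <- c(paste(cols, collapse = "\t"),
                 apply(report, 1L, paste, collapse = "\t"))
      return(invisible(lines))
    }
    write.table(report, file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(file))
  }
  fmt <- apply(report, 2L, as.character)
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = 1L,
                                       dimnames = list(NULL, cols))
  lines <- c(paste0("| ", paste(cols, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(cols)), collapse = "|"),
                    "|"),
             apply(fmt, 1L, function(r)
               paste0("| ", paste(r, collapse = " | "), " |")))
  if (is.null(file)) return(invisible(lines))
  writeLines(lines, file)
  invisible(file)
}
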