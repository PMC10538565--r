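# Plain-text interchange: VCF (phased carrier + unphased partner/embryos),
# read-allele TSV, bin-count TSV, SEG segments, and the marker-matrix
# report layout.

#' Write family and embryo genotypes as VCF
#'
#' One VCF with the carrier phased (\code{GT} with \code{|}, \code{PS} set
#' to the phase-block start position), the partner and embryos unphased.
#' The single-base deletion site is written with symbolic ALT
#' \code{<DEL>}.  Allele-dropout states appear as partial genotypes
#' (\code{"./1"} style).
#'
#' @param truth a \code{\link{FamilyTruth}}.
#' @param file output path.
#' @param phased optional \code{\link{PhasedTargetRegion}} supplying the
#'   carrier phase (defaults to the truth phase) and phase blocks.
#' @param embryos optional list from \code{\link{simulateEmbryos}} (their
#'   observations are added as samples).
#' @return \code{file}, invisibly.
#' @export
writeFamilyVcf <- function(truth, file, phased = NULL, embryos = NULL) {
  stopifnot(is(truth, "FamilyTruth"))
  if (is.null(phased)) phased <- truthPhase(truth)
  m <- truth@markers
  idx <- match(m$pos, phased@positions)

  gtCarrier <- vapply(seq_len(nrow(m)), function(i) {
    j <- idx[i]
    if (is.na(j) || is.na(phased@hap1[j])) return("./.:.")
    blockStart <- min(phased@positions[phased@blockId ==
                                         phased@blockId[j]])
    sprintf("%d|%d:%d", phased@hap1[j], phased@hap2[j], blockStart)
  }, character(1))

  codeAllele <- function(a, ref) {
    ifelse(is.na(a), ".", ifelse(a == "." , ".",
                                 ifelse(a == ref, "0", "1")))
  }
  gtPartner <- vapply(seq_len(nrow(m)), function(i) {
    a1 <- codeAllele(m$partner1[i], m$ref[i])
    a2 <- codeAllele(m$partner2[i], m$ref[i])
    if (is.na(m$partner2[i])) paste0(a1, ":.")
    else paste0(a1, "/", a2, ":.")
  }, character(1))

  samples <- c(carrier = NA, partner = NA)
  gtCols <- list(carrier = gtCarrier, partner = gtPartner)
  if (!is.null(embryos)) {
    for (e in embryos) {
      obs <- e$observation
      gtE <- vapply(seq_len(nrow(m)), function(i) {
        g <- obs@genotypes[match(m$pos[i], obs@positions)]
        parts <- strsplit(g, "/", fixed = TRUE)[[1]]
        paste0(paste(codeAllele(parts, m$ref[i]), collapse = "/"), ":.")
      }, character(1))
      gtCols[[obs@id]] <- gtE
    }
  }

  alt <- ifelse(m$alt == "-", "<DEL>", m$alt)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", truth@chrom),
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=PS,Number=1,Type=Integer,",
                  "Description=\"Phase set\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(gtCols)), collapse = "\t"))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(truth@chrom, m$pos[i], ".", m$ref[i], alt[i], ".", "PASS",
            ".", "GT:PS", vapply(gtCols, `[`, character(1), i)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Write / read a read-allele observation table
#'
#' TSV columns: \code{read_id, chrom, start, end, qscore, truth_hap, obs}
#' where \code{obs} is semicolon-separated \code{pos:alleleCode} pairs
#' (0 = ref, 1 = alt).
#'
#' @param reads a \code{\link{SimReadSet}}.
#' @param file path.
#' @return \code{writeReadTsv}: \code{file}, invisibly;
#'   \code{readReadTsv}: a \code{\link{SimReadSet}}.
#' @export
writeReadTsv <- function(reads, file) {
  stopifnot(is(reads, "SimReadSet"))
  obsStr <- vapply(seq_len(nrow(reads@reads)), function(r) {
    j <- which(!is.na(reads@obs[r, ]))
    paste(sprintf("%d:%d", as.integer(reads@positions[j]),
                  reads@obs[r, j]), collapse = ";")
  }, character(1))
  df <- data.frame(read_id = reads@reads$id, chrom = reads@chrom,
                   start = reads@reads$start, end = reads@reads$end,
                   qscore = reads@reads$qscore,
                   truth_hap = reads@reads$truthHap, obs = obsStr)
  mutPos <- if (!is.na(reads@mutationIndex))
    as.integer(reads@positions[reads@mutationIndex]) else NA_integer_
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# positions=%s",
                       paste(as.integer(reads@positions), collapse = ",")),
               sprintf("# mutation_pos=%s", mutPos)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(file)
}

#' @rdname writeReadTsv
#' @export
readReadTsv <- function(file) {
  hdr <- readLines(file, n = 2L)
  pos <- as.numeric(strsplit(sub("^# positions=", "", hdr[1]), ",")[[1]])
  mutPos <- suppressWarnings(as.numeric(sub("^# mutation_pos=", "",
                                            hdr[2])))
  df <- read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  obs <- matrix(NA_integer_, nrow(df), length(pos))
  for (r in seq_len(nrow(df))) {
    if (!nzchar(df$obs[r]) || is.na(df$obs[r])) next
    kv <- strsplit(strsplit(df$obs[r], ";", fixed = TRUE)[[1]], ":",
                   fixed = TRUE)
    p <- as.numeric(vapply(kv, `[`, character(1), 1))
    a <- as.integer(vapply(kv, `[`, character(1), 2))
    obs[r, match(p, pos)] <- a
  }
  reads <- DataFrame(id = df$read_id, start = df$start, end = df$end,
                     qscore = df$qscore, truthHap = df$truth_hap)
  new("SimReadSet", reads = reads, obs = obs, positions = pos,
      chrom = df$chrom[1],
      mutationIndex = if (is.na(mutPos)) NA_integer_
                      else as.integer(match(mutPos, pos)))
}

#' Write / read a bin-count track as TSV
#'
#' Columns \code{chrom, start, end, count, gc} plus \code{normalized}
#' when present.
#'
#' @param track a \code{\link{BinCountTrack}}.
#' @param file path.
#' @param genome chromosome lengths for re-reading (defaults to the
#'   maximum end per chromosome when absent from the file).
#' @return \code{writeBinTsv}: \code{file}, invisibly;
#'   \code{readBinTsv}: a \code{\link{BinCountTrack}}.
#' @export
writeBinTsv <- function(track, file) {
  stopifnot(is(track, "BinCountTrack"))
  gr <- track@bins
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
                   end = end(gr), count = mcols(gr)$count,
                   gc = mcols(gr)$gc)
  if ("normalized" %in% colnames(mcols(gr)))
    df$normalized <- mcols(gr)$normalized
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeBinTsv
#' @export
readBinTsv <- function(file, genome = NULL) {
  df <- read.table(file, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (is.null(genome))
    genome <- tapply(df$end, df$chrom, max)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                seqinfo = Seqinfo(names(genome),
                                  seqlengths = as.numeric(genome)))
  mcols(gr)$count <- df$count
  mcols(gr)$gc <- df$gc
  if ("normalized" %in% colnames(df))
    mcols(gr)$normalized <- df$normalized
  new("BinCountTrack", bins = gr,
      binSizeBp = max(df$end - df$start + 1))
}

#' Write segments in SEG format
#'
#' @param segments segment \code{GRanges} from \code{\link{segmentCBS}}.
#' @param file path.
#' @param sample sample identifier for the first column.
#' @return \code{file}, invisibly.
#' @export
writeSeg <- function(segments, file, sample = "sample") {
  df <- data.frame(ID = sample,
                   chrom = as.character(seqnames(segments)),
                   loc.start = start(segments),
                   loc.end = end(segments),
                   num.mark = mcols(segments)$nBins,
                   seg.mean = round(mcols(segments)$meanRatio, 4),
                   copy.number = mcols(segments)$copyNumber)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the per-marker embryo matrix (report layout)
#'
#' Rows are panel markers (labelled by side and distance from the gene in
#' kb); columns are the carrier's two haplotypes, the partner, and one
#' column per embryo holding the assignment at that marker; missing
#' observations are written as \code{0}.
#'
#' @param panel a \code{\link{MarkerPanel}}.
#' @param calls list of \code{\link{EmbryoCall}} objects.
#' @param file path.
#' @return \code{file}, invisibly.
#' @export
writeMarkerMatrix <- function(panel, calls, file) {
  mk <- panel@markers
  lab <- sprintf("%s_%dkb", ifelse(mk$side == "upstream", "up", "dn"),
                 round(mk$distanceBp / 1000))
  df <- data.frame(marker = lab, pos = mk$pos,
                   hap_mut = mk$mutAllele, hap_wt = mk$wtAllele,
                   partner = ifelse(is.na(mk$partner2), mk$partner1,
                                    paste0(mk$partner1, "/", mk$partner2)))
  for (cl in calls) {
    a <- cl@assignments
    df[[cl@id]] <- ifelse(a == "missing", "0", a)
  }
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
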