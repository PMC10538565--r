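# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring caller RNG state
#' @noRd
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive k reproducible sub-seeds (< 2^31) from one master seed
#' @noRd
deriveSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max, k))
}

#' hg19 chromosome lengths
#'
#' Standard hg19/GRCh37 chromosome sizes used to tile the genome into 1 Mb
#' bins.  Returned as a named numeric vector suitable for
#' \code{\link{simulateBinCounts}} and for building \code{Seqinfo} objects.
#'
#' @param chroms chromosomes to return, default chr1-22, chrX, chrY.
#' @return named numeric vector of chromosome lengths in bp.
#' @examples
#' hg19ChromLengths(c("chrX", "chrY"))
#' @export
hg19ChromLengths <- function(chroms = paste0("chr", c(1:22, "X", "Y"))) {
  len <- c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
           chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
           chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
           chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
           chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
           chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
           chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
           chr22 = 51304566, chrX = 155270560, chrY = 59373566)
  bad <- setdiff(chroms, names(len))
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  len[chroms]
}

#' @noRd
isSexChrom <- function(chrom) {
  sub("^chr", "", as.character(chrom)) %in% c("X", "Y")
}

#' Three-letter amino acid code ("*" -> "Ter")
#' @noRd
aa3 <- function(aa) {
  aa <- as.character(aa)
  out <- Biostrings::AMINO_ACID_CODE[aa]
  out[aa == "*"] <- "Ter"
  unname(out)
}

#' @noRd
checkScalarCount <- function(x, name, minimum = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < minimum)
    stop("'", name, "' must be a single number >= ", minimum)
  invisible(x)
}
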