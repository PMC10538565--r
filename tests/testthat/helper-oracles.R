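# Independent oracles and fixture builders shared across tests.

# Exhaustive minimum-error-correction cost over all read bipartitions,
# written independently of the package's solver (plain loops).
bruteMinMec <- function(m) {
  nR <- nrow(m)
  groupCost <- function(grp) {
    cost <- 0
    for (g in 1:2) for (j in seq_len(ncol(m))) {
      v <- m[grp == g, j]
      v <- v[!is.na(v)]
      if (length(v)) cost <- cost + min(sum(v == 0L), sum(v == 1L))
    }
    cost
  }
  if (nR == 1L) return(groupCost(rep(1L, 1L)))
  best <- Inf
  for (code in 0:(2^(nR - 1L) - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(nR - 1L)]
    best <- min(best, groupCost(c(1L, 1L + bits)))
  }
  best
}

# Plain-R reference for the maximal circular-arc t statistic.
refBestArc <- function(x) {
  n <- length(x)
  best <- -Inf
  bi <- bj <- 0L
  for (i in 0:(n - 1L)) for (j in (i + 1L):n) {
    k <- j - i
    if (k == n) next
    arc <- x[(i + 1L):j]
    rest <- x[-((i + 1L):j)]
    t <- abs(mean(arc) - mean(rest)) / sqrt(1 / k + 1 / (n - k))
    if (t > best) { best <- t; bi <- i; bj <- j }
  }
  list(stat = best, i = bi, j = bj)
}

# Codon-table translation independent of Biostrings::translate().
refTranslate <- function(s) {
  n <- nchar(s) %/% 3L
  codons <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# Random sparse allele matrix with every row covering >= 1 site.
randomAlleleMatrix <- function(nR, nC, density = 0.7) {
  repeat {
    m <- matrix(sample(c(0L, 1L, NA), nR * nC, replace = TRUE,
                       prob = c(density / 2, density / 2, 1 - density)),
                nR, nC)
    if (all(rowSums(!is.na(m)) > 0L)) return(m)
  }
}

asRam <- function(m, chrom = "chrX", mutationIndex = NA_integer_) {
  new("ReadAlleleMatrix", mat = m,
      positions = as.numeric(seq_len(ncol(m)) * 1000),
      chrom = chrom, mutationIndex = as.integer(mutationIndex))
}

# Hand-built read set for QC fixtures.
makeReadSet <- function(start, end, qscore, obs, positions,
                        chrom = "chrX", mutationIndex = NA_integer_) {
  n <- length(start)
  new("SimReadSet",
      reads = S4Vectors::DataFrame(
        id = sprintf("r%02d", seq_len(n)),
        start = start, end = end, qscore = qscore,
        truthHap = rep("mut", n)),
      obs = obs, positions = positions, chrom = chrom,
      mutationIndex = as.integer(mutationIndex))
}

toyGenome2 <- c(chr1 = 120e6, chr2 = 120e6)
toyGenome4 <- c(chr1 = 300e6, chr2 = 300e6, chr3 = 240e6, chr4 = 200e6)
# adds a small target chromosome (~4% of bins), mirroring the geometry of
# one aneuploid chromosome in a whole genome
toyGenome5 <- c(toyGenome4, chr5 = 40e6)
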