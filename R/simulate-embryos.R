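#' Simulate embryo biopsies: inheritance, dropout and genotypes
#'
#' Each embryo inherits one carrier haplotype (fair coin), optionally with a
#' single recombination breakpoint uniform in the window, plus one partner
#' allele per marker (none on X-linked loci for XY embryos).  Observed
#' genotypes emulate whole-genome-amplified trophectoderm biopsies: each
#' true allele drops out independently with probability \code{adoRate}.  In
#' the default \code{"missing"} mode a dropped allele is recorded as
#' missing (\code{"."}); mode \code{"homozygote"} instead reports the
#' surviving allele as an apparently homozygous call, the classic
#' misdiagnosis signature of single-cell amplification.  A direct
#' mutation-site assay result consistent with the inherited haplotype
#' (unless itself dropped) is included.
#'
#' @param truth a \code{\link{FamilyTruth}}.
#' @param n number of embryos (>= 1).
#' @param adoRate allele dropout probability in [0, 1).
#' @param recombProb per-embryo probability of one crossover in the window.
#' @param cnvSpec \code{NULL}, or a list of length \code{n} whose elements
#'   are \code{NULL} or a \code{data.frame(chrom, start, end, copy)};
#'   intervals on the same chromosome must not overlap.
#' @param sexes optional character vector ("XX"/"XY") of length \code{n};
#'   drawn fairly at random when \code{NULL}.
#' @param adoMode "missing" (default) or "homozygote" (dropout shown as a
#'   false homozygous call).
#' @param seed integer seed.
#' @return list of length \code{n}; each element is
#'   \code{list(truth = EmbryoTruth, observation = EmbryoObservation)}.
#' @examples
#' fam <- simulateFamily(seed = 1)
#' em <- simulateEmbryos(fam, n = 8, adoRate = 0.05, seed = 3)
#' em[[1]]$observation@directCall
#' @export
simulateEmbryos <- function(truth, n = 8, adoRate = 0.05, recombProb = 0,
                            cnvSpec = NULL, sexes = NULL,
                            adoMode = c("missing", "homozygote"), seed = 1) {
  stopifnot(is(truth, "FamilyTruth"))
  checkScalarCount(n, "n")
  n <- as.integer(n)
  if (adoRate < 0 || adoRate >= 1) stop("adoRate must lie in [0, 1)")
  if (recombProb < 0 || recombProb > 1) stop("recombProb must lie in [0, 1]")
  adoMode <- match.arg(adoMode)
  if (!is.null(sexes)) {
    stopifnot(length(sexes) == n, all(sexes %in% c("XX", "XY")))
  }
  if (!is.null(cnvSpec)) {
    if (!is.list(cnvSpec) || length(cnvSpec) != n)
      stop("cnvSpec must be a list of length n")
    lapply(cnvSpec, .validateCnvEvents)
  }

  m <- truth@markers
  pos <- m$pos
  mutIdx <- which(m$isMutation)
  winStart <- truth@geneStart - truth@windowBp
  winEnd <- truth@geneEnd + truth@windowBp

  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      sex <- if (is.null(sexes)) sample(c("XY", "XX"), 1) else sexes[i]
      baseHap <- sample(c("mut", "wt"), 1)
      bp <- numeric(0)
      hapBy <- rep(baseHap, length(pos))
      if (runif(1) < recombProb) {
        bp <- floor(runif(1, winStart, winEnd))
        other <- if (baseHap == "mut") "wt" else "mut"
        hapBy[pos > bp] <- other
      }
      maternal <- ifelse(hapBy == "mut", m$hapMut, m$hapWt)
      hemizygous <- truth@xLinked && sex == "XY"
      paternal <- if (hemizygous) rep(NA_character_, length(pos))
                  else ifelse(!is.na(m$partner2) & runif(length(pos)) < 0.5,
                              m$partner2, m$partner1)

      dropM <- runif(length(pos)) < adoRate
      dropP <- runif(length(pos)) < adoRate
      geno <- .renderGenotype(maternal, paternal, dropM, dropP,
                              hemizygous, adoMode)

      inherited <- hapBy[mutIdx]
      directCall <- if (dropM[mutIdx]) "missing"
                    else if (inherited == "mut") "mut" else "wt"

      events <- if (is.null(cnvSpec) || is.null(cnvSpec[[i]]))
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), copy = integer(0))
      else as.data.frame(cnvSpec[[i]])

      id <- sprintf("E%d", i)
      list(
        truth = new("EmbryoTruth", id = id, sex = sex, hapByMarker = hapBy,
                    inheritedHap = inherited, breakpoint = bp,
                    paternalAllele = paternal, cnvEvents = events,
                    positions = pos),
        observation = new("EmbryoObservation", id = id, sex = sex,
                          positions = pos, genotypes = geno,
                          directCall = directCall))
    })
  })
}

#' @noRd
.renderGenotype <- function(maternal, paternal, dropM, dropP,
                            hemizygous, adoMode) {
  if (hemizygous) {
    # single X allele: dropout makes the site fully missing
    return(ifelse(dropM, ".", maternal))
  }
  a1 <- ifelse(dropM, ".", maternal)
  a2 <- ifelse(dropP, ".", paternal)
  if (adoMode == "homozygote") {
    oneDrop <- xor(dropM, dropP)
    a1 <- ifelse(oneDrop & dropM, a2, a1)
    a2 <- ifelse(oneDrop & dropP, a1, a2)
  }
  # canonical order: allele letters sorted, "." last
  lo <- ifelse(a1 == "." | (a2 != "." & a2 < a1), a2, a1)
  hi <- ifelse(lo == a1, a2, a1)
  paste(lo, hi, sep = "/")
}

#' @noRd
.validateCnvEvents <- function(ev) {
  if (is.null(ev)) return(invisible(NULL))
  ev <- as.data.frame(ev)
  need <- c("chrom", "start", "end", "copy")
  if (!all(need %in% colnames(ev)))
    stop("cnv events need columns: ", paste(need, collapse = ", "))
  if (any(ev$end < ev$start)) stop("cnv event end < start")
  if (any(ev$copy < 0)) stop("cnv copy numbers must be >= 0")
  for (ch in unique(ev$chrom)) {
    e <- ev[ev$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping cnv events on ", ch)
  }
  invisible(NULL)
}
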