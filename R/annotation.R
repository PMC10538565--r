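# Coding-consequence nomenclature and ACMG evidence combination.

#' Codon number of a coding-sequence position
#'
#' @param cdsPosition 1-based nucleotide index into the coding sequence.
#' @return \code{ceiling(cdsPosition / 3)}, the 1-based codon (residue)
#'   number.
#' @examples
#' codonIndex(1496)  # 499
#' @export
codonIndex <- function(cdsPosition) {
  if (any(!is.finite(cdsPosition)) || any(cdsPosition < 1) ||
      any(cdsPosition != floor(cdsPosition)))
    stop("cdsPosition must be a positive integer index")
  as.integer(ceiling(cdsPosition / 3))
}

#' HGVS protein consequence of a single-base CDS deletion
#'
#' Translates the reference codon at the deletion site to name the
#' reference residue, deletes the base, re-translates in the shifted frame
#' from that codon, and reports the first genuinely differing residue and
#' the distance to the first stop in the new frame:
#' \code{p.<Ref><N><New>fs*<K>} with the stop codon counted as position K
#' of the new reading frame (the first changed residue is position 1).  A
#' deletion whose first changed codon is itself a stop is reported as a
#' nonsense change \code{p.<Ref><N>*}; a shifted frame with no downstream
#' stop yields \code{fs*?}.
#'
#' @param cds coding sequence: character string, \code{DNAString}, or a
#'   single-record \code{DNAStringSet} (e.g. from
#'   \code{\link[Biostrings]{readDNAStringSet}}); length must be a
#'   multiple of 3.
#' @param cdsPosition 1-based position of the deleted base.
#' @param ref optional reference base for a consistency check.
#' @return the HGVS protein string.
#' @examples
#' frameshiftConsequence("ATGGGTAAACCCTAA", 4)
#' @export
frameshiftConsequence <- function(cds, cdsPosition, ref = NULL) {
  if (is(cds, "DNAStringSet")) {
    stopifnot(length(cds) == 1L)
    cds <- cds[[1L]]
  }
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be a multiple of 3")
  if (cdsPosition < 1 || cdsPosition > n)
    stop("cdsPosition outside the CDS")
  base <- substr(cds, cdsPosition, cdsPosition)
  if (!is.null(ref) && toupper(ref) != base)
    stop("reference base mismatch at cdsPosition: CDS has ", base)

  refProt <- .translateCds(cds)
  mut <- paste0(substr(cds, 1, cdsPosition - 1),
                substr(cds, cdsPosition + 1, n))
  c0 <- codonIndex(cdsPosition)
  mutTail <- .translateCds(substr(mut, 3 * (c0 - 1) + 1, nchar(mut)))

  # first residue (from the variant codon on) where the shifted frame
  # differs from the reference protein
  iDiff <- NA_integer_
  for (k in seq_len(nchar(mutTail))) {
    refIdx <- c0 + k - 1L
    refAA <- if (refIdx <= nchar(refProt))
      substr(refProt, refIdx, refIdx) else ""
    newAA <- substr(mutTail, k, k)
    if (newAA != refAA) { iDiff <- k; break }
  }
  if (is.na(iDiff))
    stop("shifted frame never diverges from the reference protein")
  posN <- c0 + iDiff - 1L
  refAA <- substr(refProt, posN, posN)
  newAA <- substr(mutTail, iDiff, iDiff)
  if (newAA == "*")
    return(sprintf("p.%s%d*", aa3(refAA), posN))
  stopRel <- regexpr("*", substr(mutTail, iDiff, nchar(mutTail)),
                     fixed = TRUE)
  if (stopRel < 0)
    return(sprintf("p.%s%d%sfs*?", aa3(refAA), posN, aa3(newAA)))
  sprintf("p.%s%d%sfs*%d", aa3(refAA), posN, aa3(newAA), as.integer(stopRel))
}

#' @noRd
.translateCds <- function(s) {
  ncod <- nchar(s) %/% 3
  if (ncod == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1, 3 * ncod)),
    no.init.codon = TRUE, if.fuzzy.codon = "X"))
}

#' Combine ACMG evidence codes into a five-tier classification
#'
#' Applies the published combining rules for the standard evidence
#' vocabulary (PVS1; PS1-4; PM1-6; PP1-5; BA1; BS1-4; BP1-7).  When both a
#' pathogenic-tier and a benign-tier rule fire, the evidence is
#' conflicting and the variant stays a VUS.
#'
#' @param evidence character vector of ACMG codes (may be empty).
#' @return one of "Pathogenic", "Likely pathogenic", "VUS",
#'   "Likely benign", "Benign".
#' @examples
#' combineAcmg(c("PVS1", "PM2", "PM6"))  # Pathogenic
#' combineAcmg("PM2")                    # VUS
#' @export
combineAcmg <- function(evidence = character(0)) {
  evidence <- unique(toupper(as.character(evidence)))
  okPattern <- "^(PVS1|PS[1-4]|PM[1-6]|PP[1-5]|BA1|BS[1-4]|BP[1-7])$"
  bad <- evidence[!grepl(okPattern, evidence)]
  if (length(bad))
    stop("unknown ACMG code(s): ", paste(bad, collapse = ", "))

  nPVS <- sum(evidence == "PVS1")
  nPS <- sum(grepl("^PS", evidence))
  nPM <- sum(grepl("^PM", evidence))
  nPP <- sum(grepl("^PP", evidence))
  nBA <- sum(evidence == "BA1")
  nBS <- sum(grepl("^BS", evidence))
  nBP <- sum(grepl("^BP", evidence))

  pathogenic <-
    (nPVS >= 1 && (nPS >= 1 || nPM >= 2 || (nPM == 1 && nPP == 1) ||
                   nPP >= 2)) ||
    nPS >= 2 ||
    (nPS == 1 && (nPM >= 3 || (nPM == 2 && nPP >= 2) ||
                  (nPM == 1 && nPP >= 4)))
  likelyPathogenic <-
    (nPVS >= 1 && nPM == 1) ||
    (nPS == 1 && nPM >= 1 && nPM <= 2) ||
    (nPS == 1 && nPP >= 2) ||
    nPM >= 3 ||
    (nPM == 2 && nPP >= 2) ||
    (nPM == 1 && nPP >= 4)
  benign <- nBA >= 1 || nBS >= 2
  likelyBenign <- (nBS == 1 && nBP == 1) || nBP >= 2

  anyPath <- pathogenic || likelyPathogenic
  anyBen <- benign || likelyBenign
  if (anyPath && anyBen) return("VUS")
  if (pathogenic) return("Pathogenic")
  if (likelyPathogenic) return("Likely pathogenic")
  if (benign) return("Benign")
  if (likelyBenign) return("Likely benign")
  "VUS"
}
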