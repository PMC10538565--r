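# Accessor generics, methods and show() methods.

#' @name accessors
#' @title Accessors for denovoPGT classes
#' @description Slot access for the package's S4 containers.
#' @param x an object of the documented class.
#' @return \code{markers} returns the marker \code{DataFrame};
#'   \code{positions} the site coordinates; \code{hap1}/\code{hap2} the
#'   phased allele codes; \code{mutationHap} the mutation's haplotype label;
#'   \code{phaseBlocks} the per-site block ids; \code{blockSupport} the
#'   read support between adjacent sites; \code{binCounts} the bin
#'   \code{GRanges}; \code{diagnosis} the embryo diagnosis string;
#'   \code{assignments} the per-marker assignments.
NULL

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("hap1", function(x) standardGeneric("hap1"))
#' @rdname accessors
#' @export
setGeneric("hap2", function(x) standardGeneric("hap2"))
#' @rdname accessors
#' @export
setGeneric("mutationHap", function(x) standardGeneric("mutationHap"))
#' @rdname accessors
#' @export
setGeneric("phaseBlocks", function(x) standardGeneric("phaseBlocks"))
#' @rdname accessors
#' @export
setGeneric("blockSupport", function(x) standardGeneric("blockSupport"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setMethod("markers", "FamilyTruth", function(x) x@markers)
#' @rdname accessors
#' @export
setMethod("markers", "MarkerPanel", function(x) x@markers)
#' @rdname accessors
#' @export
setMethod("positions", "FamilyTruth", function(x) x@markers$pos)
#' @rdname accessors
#' @export
setMethod("positions", "SimReadSet", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("positions", "ReadAlleleMatrix", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("positions", "PhasedTargetRegion", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("positions", "EmbryoObservation", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("hap1", "PhasedTargetRegion", function(x) x@hap1)
#' @rdname accessors
#' @export
setMethod("hap2", "PhasedTargetRegion", function(x) x@hap2)
#' @rdname accessors
#' @export
setMethod("mutationHap", "PhasedTargetRegion", function(x) x@mutationHap)
#' @rdname accessors
#' @export
setMethod("phaseBlocks", "PhasedTargetRegion", function(x) x@blockId)
#' @rdname accessors
#' @export
setMethod("blockSupport", "PhasedTargetRegion", function(x) x@blockSupport)
#' @rdname accessors
#' @export
setMethod("binCounts", "BinCountTrack", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("diagnosis", "EmbryoCall", function(x) x@diagnosis)
#' @rdname accessors
#' @export
setMethod("assignments", "EmbryoCall", function(x) x@assignments)

setMethod("show", "FamilyTruth", function(object) {
  m <- object@markers
  cat("FamilyTruth on", object@chrom, "\n")
  cat("  gene:", object@geneStart, "-", object@geneEnd,
      " mutation at", object@mutationPos, "\n")
  cat(" ", nrow(m), "het markers within +/-",
      object@windowBp / 1e6, "Mb;",
      if (object@xLinked) "X-linked (hemizygous partner)" else "autosomal",
      "\n")
})

setMethod("show", "SimReadSet", function(object) {
  cat("SimReadSet:", nrow(object@reads), "reads over",
      length(object@positions), "sites on", object@chrom, "\n")
  if (nrow(object@reads)) {
    len <- object@reads$end - object@reads$start + 1
    cat("  mean length", round(mean(len)), "bp; mean qscore",
        round(mean(object@reads$qscore), 2), "\n")
  }
})

setMethod("show", "ReadAlleleMatrix", function(object) {
  cat("ReadAlleleMatrix:", nrow(object@mat), "reads x",
      ncol(object@mat), "het sites\n")
})

setMethod("show", "PhasedTargetRegion", function(object) {
  cat("PhasedTargetRegion on", object@chrom, "(",
      object@window[1], "-", object@window[2], ")\n")
  cat(" ", length(object@positions), "sites in",
      length(unique(object@blockId)), "phase block(s); mutation on",
      object@mutationHap, "; MEC cost", object@mecCost, "\n")
})

setMethod("show", "MarkerPanel", function(object) {
  m <- object@markers
  cat("MarkerPanel:", nrow(m), "informative SNPs (",
      sum(m$side == "upstream"), "upstream /",
      sum(m$side == "downstream"), "downstream ) on", object@chrom, "\n")
})

setMethod("show", "BinCountTrack", function(object) {
  cat("BinCountTrack:", length(object@bins), "bins of",
      object@binSizeBp / 1e6, "Mb over",
      length(unique(as.character(seqnames(object@bins)))),
      "chromosome(s)\n")
  if ("normalized" %in% colnames(mcols(object@bins)))
    cat("  normalized ratios present\n")
})

setMethod("show", "EmbryoCall", function(object) {
  cat("EmbryoCall", object@id, ":", object@diagnosis,
      sprintf("(mut %d / wt %d votes)", object@voteMut, object@voteWt), "\n")
  if (length(object@recombination))
    cat("  candidate recombination in (",
        object@recombination[1], ",", object@recombination[2], ")\n")
  if (nzchar(object@reason)) cat("  reason:", object@reason, "\n")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig with", length(object@params), "parameters\n")
  p <- object@params
  scal <- vapply(p, function(v) is.atomic(v) && length(v) == 1L, logical(1))
  kv <- vapply(p[scal], function(v) format(v), character(1))
  cat(paste0("  ", names(kv), " = ", kv, collapse = "\n"), "\n")
})
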