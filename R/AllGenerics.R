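#' @name paleowgd-accessors
#' @title Accessors for paleowgd S4 classes
#'
#' @description Slot accessors. Slots are never reached into directly by user
#' code; these functions are the supported surface.
#'
#' @param x an object of the documented class.
#' @return the slot value described per method.
NULL

#' @rdname paleowgd-accessors
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("anchorTable", function(x) standardGeneric("anchorTable"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("ksValues", function(x) standardGeneric("ksValues"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("peakMode", function(x) standardGeneric("peakMode"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("correctionCoefficient", function(x) standardGeneric("correctionCoefficient"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("eventAgeMya", function(x) standardGeneric("eventAgeMya"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("substitutionRate", function(x) standardGeneric("substitutionRate"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("modalDepth", function(x) standardGeneric("modalDepth"))

#' @rdname paleowgd-accessors
#' @export
setGeneric("depthHistogram", function(x) standardGeneric("depthHistogram"))

#' @rdname paleowgd-accessors
#' @export
setMethod("species", "GenomeAnnotation", function(x) x@species)

#' @rdname paleowgd-accessors
#' @export
setMethod("geneTable", "GenomeAnnotation", function(x) {
  g <- x@genes
  data.frame(
    gene_id = S4Vectors::mcols(g)$gene_id,
    species = x@species,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    rank = S4Vectors::mcols(g)$rank,
    stringsAsFactors = FALSE)
})

#' @rdname paleowgd-accessors
#' @export
setMethod("blockTable", "SyntenyBlocks", function(x) x@blocks)

#' @rdname paleowgd-accessors
#' @export
setMethod("anchorTable", "SyntenyBlocks", function(x) x@anchors)

#' @rdname paleowgd-accessors
#' @export
setMethod("ksValues", "KsSample", function(x) x@values)

#' @rdname paleowgd-accessors
#' @export
setMethod("peakMode", "PeakEstimate", function(x) x@mode)

#' @rdname paleowgd-accessors
#' @export
setMethod("correctionCoefficient", "RateCorrection", function(x) x@coefficient)

#' @rdname paleowgd-accessors
#' @export
setMethod("eventAgeMya", "DatingResult", function(x) x@timeMya)

#' @rdname paleowgd-accessors
#' @export
setMethod("substitutionRate", "DatingResult", function(x) x@rate)

#' @rdname paleowgd-accessors
#' @export
setMethod("modalDepth", "DepthProfile", function(x) x@modalDepth)

#' @rdname paleowgd-accessors
#' @export
setMethod("depthHistogram", "DepthProfile", function(x) x@histogram)

setMethod("show", "GenomeAnnotation", function(object) {
  g <- object@genes
  cat(sprintf("GenomeAnnotation: species '%s', %d genes on %d chromosome(s)\n",
              object@species, length(g),
              length(unique(as.character(GenomicRanges::seqnames(g))))))
})

setMethod("show", "SyntenyBlocks", function(object) {
  cat(sprintf("SyntenyBlocks: %d block(s), %d anchor(s) [%s vs %s]\n",
              nrow(object@blocks), nrow(object@anchors),
              object@speciesA, object@speciesB))
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile: %d genes, modal nonzero depth %s\n",
              nrow(object@depths),
              ifelse(is.na(object@modalDepth), "NA", object@modalDepth)))
  print(object@histogram)
})

setMethod("show", "KsSample", function(object) {
  cat(sprintf("KsSample '%s': n = %d in [%.3g, %.3g] (%d dropped)\n",
              object@label, length(object@values),
              object@filterRange[1], object@filterRange[2], object@nDropped))
})

setMethod("show", "PeakEstimate", function(object) {
  cat(sprintf("PeakEstimate (%s): mode Ks = %.4f\n", object@method, object@mode))
  if (nrow(object@components)) {
    cat("components (log-Ks scale):\n")
    print(object@components, digits = 4)
  }
})

setMethod("show", "RateCorrection", function(object) {
  cat(sprintf("RateCorrection: C = %.4f (reference peak %.4f / other peak %.4f)\n",
              object@coefficient, object@referencePeak, object@otherPeak))
})

setMethod("show", "DatingResult", function(object) {
  cat(sprintf("DatingResult: t = %.2f MY (peak Ks %.4f, r = %.4g subst/site/MY)\n",
              object@timeMya, object@eventPeak, object@rate))
})

setMethod("show", "TopologySummary", function(object) {
  cat(sprintf(
    "TopologySummary: %d trees; shared %d (%.1f%%), independent %d (%.1f%%), other %d; shared/(shared+independent) = %.1f%%\n",
    object@nTotal, object@nShared, object@pctShared, object@nIndependent,
    object@pctIndependent, object@nOther, object@sharedRatio))
})

setMethod("show", "KaryotypeModel", function(object) {
  cat(sprintf(
    "KaryotypeModel: %d ancestral -> WGD -> %d -> +%d fissions -%d fusions -> %d extant\n",
    object@nAncestral, object@nPostWgd, object@nFissions, object@nFusions,
    object@nExtant))
})

setMethod("show", "SegmentGraph", function(object) {
  cat(sprintf("SegmentGraph: %d segment(s), %d edge(s) over %d chromosome(s)\n",
              nrow(object@segments), nrow(object@edges),
              length(object@chromGenes)))
})

setMethod("show", "SimulationPlan", function(object) {
  cat(sprintf(
    "SimulationPlan: seed %d; ancestor %d x %d genes; retention %.2f; Ks mode %.3f (sigma %.2f); %d fissions, %d fusions, %d inversions; pShared %.2f\n",
    object@seed, object@nChromosomes, object@genesPerChromosome,
    object@wgdRetention, object@ksMode, object@ksSigma, object@nFissions,
    object@nFusions, object@nInversions, object@pShared))
})
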