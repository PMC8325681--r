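#' @import methods
#' @importFrom stats density rnorm rexp rpois runif rbinom median setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Genome annotation: gene coordinates and gene-order ranks
#'
#' Container for the gene complement of one genome. Genes are held as a
#' \linkS4class{GRanges} whose metadata columns carry the stable gene
#' identifier and the 0-based gene-order rank along each chromosome. All
#' synteny arithmetic in this package operates on ranks (gene order), not on
#' base pairs; coordinates are kept 1-based inclusive as in GFF3.
#'
#' @slot species single species tag, e.g. \code{"css"}.
#' @slot genes \code{GRanges} with mcols \code{gene_id} (character, unique)
#'   and \code{rank} (integer, dense 0..n-1 within each chromosome after
#'   sorting by start, ties broken by \code{gene_id}).
#'
#' @seealso [genomeAnnotation()], [readGenePositions()]
#' @export
setClass("GenomeAnnotation",
  slots = c(species = "character", genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  if (length(object@species) != 1L || is.na(object@species) ||
      !nzchar(object@species))
    msg <- c(msg, "'species' must be a single non-empty string")
  mc <- S4Vectors::mcols(object@genes)
  if (!all(c("gene_id", "rank") %in% colnames(mc))) {
    msg <- c(msg, "genes must carry 'gene_id' and 'rank' metadata columns")
  } else {
    if (anyDuplicated(mc$gene_id))
      msg <- c(msg, "duplicated gene_id")
    chrom <- as.character(GenomicRanges::seqnames(object@genes))
    for (ch in unique(chrom)) {
      r <- sort(mc$rank[chrom == ch])
      if (!identical(as.integer(r), seq_along(r) - 1L)) {
        msg <- c(msg, sprintf("ranks on chromosome '%s' are not dense 0..n-1", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Collinear synteny blocks
#'
#' Result of anchor chaining: a block table and the per-anchor table that
#' supports it. Within a block, anchor ranks are strictly increasing on the
#' first genome and strictly increasing (collinear) or strictly decreasing
#' (inverted) on the second.
#'
#' @slot blocks data.frame: block_id, chrom_a, start_rank_a, end_rank_a,
#'   chrom_b, start_rank_b, end_rank_b, n_anchors, orientation, score.
#' @slot anchors data.frame: block_id, gene_a, gene_b, chrom_a, rank_a,
#'   chrom_b, rank_b, ks.
#' @slot speciesA,speciesB species tags of the two genomes (equal for
#'   self-synteny).
#' @export
setClass("SyntenyBlocks",
  slots = c(blocks = "data.frame", anchors = "data.frame",
            speciesA = "character", speciesB = "character"))

setValidity("SyntenyBlocks", function(object) {
  a <- object@anchors
  b <- object@blocks
  if (nrow(b) && !all(b$n_anchors >= 1L))
    return("blocks with no anchors")
  if (nrow(a)) {
    for (id in unique(a$block_id)) {
      sub <- a[a$block_id == id, ]
      sub <- sub[order(sub$rank_a), ]
      if (any(diff(sub$rank_a) <= 0))
        return(sprintf("block %s not strictly increasing in rank_a", id))
      db <- diff(sub$rank_b)
      if (!(all(db > 0) || all(db < 0)))
        return(sprintf("block %s not strictly monotone in rank_b", id))
    }
  }
  TRUE
})

#' Syntenic depth profile
#'
#' Per-gene coverage of a query genome by synteny blocks against one target
#' genome. The modal nonzero depth is the statistic behind syntenic-depth
#' ratios (2:1, 2:2, 2:4) used as WGD evidence.
#'
#' @slot depths data.frame: gene_id, chrom, rank, depth.
#' @slot modalDepth modal depth over genes with depth > 0 (NA if none).
#' @slot histogram named integer vector, depth value -> gene count
#'   (includes depth 0); sums to the number of genes considered.
#' @export
setClass("DepthProfile",
  slots = c(depths = "data.frame", modalDepth = "numeric",
            histogram = "integer"))

setValidity("DepthProfile", function(object) {
  if (sum(object@histogram) != nrow(object@depths))
    return("histogram does not sum to the number of genes")
  if (any(object@depths$depth < 0)) return("negative depth")
  TRUE
})

#' A filtered sample of Ks values
#'
#' @slot label sample label (species or species pair).
#' @slot values finite Ks values inside the filter range.
#' @slot filterRange length-2 numeric (lo, hi).
#' @slot nDropped number of values removed (undefined or out of range).
#' @export
setClass("KsSample",
  slots = c(label = "character", values = "numeric",
            filterRange = "numeric", nDropped = "integer"))

setValidity("KsSample", function(object) {
  if (length(object@filterRange) != 2L ||
      object@filterRange[1] > object@filterRange[2])
    return("filterRange must be (lo, hi) with lo <= hi")
  v <- object@values
  if (length(v) == 0L) return("empty Ks sample")
  if (any(!is.finite(v))) return("non-finite Ks values")
  if (any(v < object@filterRange[1] | v > object@filterRange[2]))
    return("values outside filterRange")
  TRUE
})

#' Location of a Ks distribution peak
#'
#' @slot mode peak location on the Ks scale.
#' @slot method "kde" or "gmm".
#' @slot components for gmm: data.frame weight, location (mean of log Ks),
#'   scale (sd of log Ks); empty for kde.
#' @slot stat Silverman bandwidth (kde) or the selected model's BIC (gmm).
#' @export
setClass("PeakEstimate",
  slots = c(mode = "numeric", method = "character",
            components = "data.frame", stat = "numeric"))

setValidity("PeakEstimate", function(object) {
  if (!object@method %in% c("kde", "gmm")) return("method must be kde or gmm")
  if (object@method == "gmm" && nrow(object@components) &&
      abs(sum(object@components$weight) - 1) > 1e-9)
    return("gmm weights must sum to 1")
  TRUE
})

#' Cross-species substitution-rate correction
#'
#' Multiplicative coefficient C aligning another lineage's Ks scale to a
#' reference lineage via their shared divergence peak against a common
#' outgroup: C = reference peak / other peak, so that
#' Ks_ref = Ks_other * C at the shared split.
#'
#' @slot referencePeak,otherPeak split-peak Ks of the two lineages against
#'   the common outgroup.
#' @slot coefficient C = referencePeak / otherPeak.
#' @export
setClass("RateCorrection",
  slots = c(referencePeak = "numeric", otherPeak = "numeric",
            coefficient = "numeric"))

setValidity("RateCorrection", function(object) {
  if (object@coefficient <= 0) return("coefficient must be > 0")
  if (abs(object@coefficient -
          object@referencePeak / object@otherPeak) > 1e-9)
    return("coefficient != referencePeak / otherPeak")
  TRUE
})

#' Molecular dating result under Ks = 2rt
#'
#' @slot rate r, synonymous substitutions per site per million years per
#'   lineage, calibrated as r = Ks_cal / (2 T_cal).
#' @slot timeMya event age t = peak / (2 r), million years.
#' @slot calKs,calT the calibration pair (split-peak Ks, split age in MY).
#' @slot eventPeak the dated Ks peak.
#' @export
setClass("DatingResult",
  slots = c(rate = "numeric", timeMya = "numeric", calKs = "numeric",
            calT = "numeric", eventPeak = "numeric"))

setValidity("DatingResult", function(object) {
  if (object@timeMya < 0) return("negative time")
  if (abs(object@rate - object@calKs / (2 * object@calT)) > 1e-12)
    return("rate inconsistent with calibration")
  if (abs(object@timeMya - object@eventPeak / (2 * object@rate)) > 1e-9)
    return("time inconsistent with rate and peak")
  TRUE
})

#' Summary of gene-tree topology calls
#'
#' @slot nShared trees where the focal duplication precedes the
#'   focal/partner speciation (duplication shared).
#' @slot nIndependent trees where the focal paralogs coalesce before any
#'   partner joins (lineage-specific duplication).
#' @slot nOther undecidable or other topologies.
#' @slot nTotal total trees; equals the sum of the three counts.
#' @slot pctShared,pctIndependent percentages of nTotal.
#' @slot sharedRatio 100 * nShared / (nShared + nIndependent).
#' @export
setClass("TopologySummary",
  slots = c(nShared = "integer", nIndependent = "integer", nOther = "integer",
            nTotal = "integer", pctShared = "numeric",
            pctIndependent = "numeric", sharedRatio = "numeric"))

setValidity("TopologySummary", function(object) {
  if (object@nTotal != object@nShared + object@nIndependent + object@nOther)
    return("counts do not sum to nTotal")
  if (any(c(object@nShared, object@nIndependent, object@nOther) < 0))
    return("negative count")
  TRUE
})

#' Karyotype evolution model
#'
#' Bookkeeping of chromosome numbers across a WGD: an ancestor with
#' \code{nAncestral} chromosomes doubles to \code{2 * nAncestral}, then
#' fissions add and fusions subtract one chromosome each, reaching
#' \code{nExtant}.
#'
#' @slot nAncestral,nPostWgd,nFissions,nFusions,nExtant non-negative integers
#'   satisfying nPostWgd = 2 nAncestral and
#'   nExtant = nPostWgd + nFissions - nFusions.
#' @export
setClass("KaryotypeModel",
  slots = c(nAncestral = "integer", nPostWgd = "integer",
            nFissions = "integer", nFusions = "integer", nExtant = "integer"))

setValidity("KaryotypeModel", function(object) {
  if (any(c(object@nAncestral, object@nFissions, object@nFusions,
            object@nExtant) < 0))
    return("counts must be >= 0")
  if (object@nPostWgd != 2L * object@nAncestral)
    return("nPostWgd != 2 * nAncestral")
  lhs <- object@nExtant
  rhs <- object@nPostWgd + object@nFissions - object@nFusions
  if (lhs != rhs)
    return(sprintf("karyotype bookkeeping violated: nExtant = %d but 2*%d + %d - %d = %d",
                   lhs, object@nAncestral, object@nFissions, object@nFusions, rhs))
  TRUE
})

#' Segment graph from self-synteny
#'
#' Nodes are chromosome segments (rank intervals) delimited by the rank spans
#' of large self-synteny blocks; edges link the two sides of each block,
#' weighted by anchor count. Chromosome gene counts are carried along for
#' junction calibration during ancestral-count inference.
#'
#' @slot segments data.frame: segment_id, chrom, start_rank, end_rank.
#' @slot edges data.frame: seg1, seg2, weight.
#' @slot chromGenes named integer, genes per chromosome.
#' @export
setClass("SegmentGraph",
  slots = c(segments = "data.frame", edges = "data.frame",
            chromGenes = "integer"))

setValidity("SegmentGraph", function(object) {
  e <- object@edges
  if (nrow(e) && any(e$seg1 == e$seg2)) return("self-edge in segment graph")
  s <- object@segments
  if (nrow(s) && any(s$start_rank > s$end_rank)) return("inverted segment")
  TRUE
})

#' Simulation plan for a WGD genome
#'
#' Declares the full history the simulator replays: a diploid ancestor of
#' \code{nChromosomes} x \code{genesPerChromosome} genes, one WGD with
#' per-duplicate retention probability \code{wgdRetention}, then chromosome
#' fissions, fusions and inversions. Ks for retained WGD paralog pairs is
#' lognormal with mode \code{ksMode} (on the Ks scale; equal to
#' exp(meanlog)) and log-scale sd \code{ksSigma}; small-scale duplicates get
#' exponential background Ks with rate \code{backgroundRate}. Gene trees are
#' simulated shared with probability \code{pShared}.
#'
#' @slot seed mandatory RNG seed; there is no unseeded randomness anywhere.
#' @slot nChromosomes,genesPerChromosome ancestor dimensions.
#' @slot wgdRetention probability in (0, 1] that a duplicated gene keeps
#'   both copies.
#' @slot ksMode,ksSigma lognormal WGD-pair Ks parameters.
#' @slot backgroundRate exponential rate for background (tandem/proximal/
#'   dispersed) pair Ks.
#' @slot nFissions,nFusions,nInversions post-WGD rearrangement counts.
#' @slot pShared probability a simulated gene tree shows the shared-WGD
#'   topology.
#' @export
setClass("SimulationPlan",
  slots = c(seed = "integer", nChromosomes = "integer",
            genesPerChromosome = "integer", wgdRetention = "numeric",
            ksMode = "numeric", ksSigma = "numeric",
            backgroundRate = "numeric", nFissions = "integer",
            nFusions = "integer", nInversions = "integer",
            pShared = "numeric"))

setValidity("SimulationPlan", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (object@nChromosomes < 1L || object@genesPerChromosome < 2L)
    msg <- c(msg, "ancestor must have >= 1 chromosome and >= 2 genes each")
  if (object@wgdRetention <= 0 || object@wgdRetention > 1)
    msg <- c(msg, "wgdRetention must be in (0, 1]")
  if (object@ksMode <= 0 || object@ksSigma <= 0)
    msg <- c(msg, "ksMode and ksSigma must be > 0")
  if (object@backgroundRate <= 0) msg <- c(msg, "backgroundRate must be > 0")
  if (any(c(object@nFissions, object@nFusions, object@nInversions) < 0))
    msg <- c(msg, "rearrangement counts must be >= 0")
  if (object@pShared < 0 || object@pShared > 1)
    msg <- c(msg, "pShared must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
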