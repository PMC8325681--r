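# Duplicate gene pair mode classification (DupGen_finder-style), so that Ks
# distributions can be restricted to WGD-derived pairs. Precedence:
# wgd > tandem > proximal > dispersed. Transposed duplicates (which need an
# outgroup) are not modelled; such pairs fall into dispersed.

#' Classify duplicate gene pairs by duplication mode
#'
#' A pair is \code{wgd} when it is an anchor of a self-synteny block;
#' \code{tandem} when both genes sit on the same chromosome at adjacent
#' ranks, or (in the default "array" mode) separated only by genes of the
#' same homolog family; \code{proximal} when on the same chromosome with
#' rank distance in (1, \code{proximalWindow}]; otherwise \code{dispersed}.
#' Families used by the array rule are the connected components of the full
#' homolog-pair graph.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param pairs data.frame with id_a, id_b; both genes must belong to
#'   \code{genome}.
#' @param selfBlocks \linkS4class{SyntenyBlocks} from [selfSynteny()] on the
#'   same pair set.
#' @param proximalWindow maximum rank distance for proximal pairs
#'   (default 10).
#' @param tandemMode "array" (tandem across runs of same-family genes) or
#'   "strict" (adjacent ranks only).
#' @return data.frame: id_a, id_b, mode plus chrom/rank columns of both
#'   genes.
#' @export
classifyDuplicates <- function(genome, pairs, selfBlocks,
                               proximalWindow = 10L,
                               tandemMode = c("array", "strict")) {
  tandemMode <- match.arg(tandemMode)
  g <- geneTable(genome)
  pairs <- normalizePairs(pairs[, c("id_a", "id_b"), drop = FALSE])
  ia <- match(pairs$id_a, g$gene_id)
  ib <- match(pairs$id_b, g$gene_id)
  if (any(is.na(ia) | is.na(ib)))
    stop("pair with genes not in this genome/species")

  an <- anchorTable(selfBlocks)
  anchor_keys <- character(0)
  if (nrow(an))
    anchor_keys <- paste(pmin(an$gene_a, an$gene_b),
                         pmax(an$gene_a, an$gene_b), sep = "\r")
  keys <- paste(pairs$id_a, pairs$id_b, sep = "\r")

  same_chrom <- g$chrom[ia] == g$chrom[ib]
  dr <- abs(g$rank[ia] - g$rank[ib])

  tandem <- same_chrom & dr == 1L
  if (tandemMode == "array" && nrow(pairs)) {
    # family membership from the homolog-pair graph
    gr <- igraph::graph_from_data_frame(pairs[, c("id_a", "id_b")],
                                        directed = FALSE)
    fam <- igraph::components(gr)$membership
    gene_fam <- fam[g$gene_id]
    names(gene_fam) <- g$gene_id
    cand <- which(same_chrom & dr > 1L & dr <= proximalWindow & !tandem)
    for (i in cand) {
      ch <- g$chrom[ia[i]]
      lo <- min(g$rank[ia[i]], g$rank[ib[i]])
      hi <- max(g$rank[ia[i]], g$rank[ib[i]])
      between <- g$gene_id[g$chrom == ch & g$rank > lo & g$rank < hi]
      f <- fam[[pairs$id_a[i]]]
      bf <- gene_fam[between]
      if (length(between) && all(!is.na(bf) & bf == f)) tandem[i] <- TRUE
    }
  }

  mode <- rep("dispersed", nrow(pairs))
  mode[same_chrom & dr > 1L & dr <= proximalWindow] <- "proximal"
  mode[tandem] <- "tandem"
  mode[keys %in% anchor_keys] <- "wgd"

  data.frame(id_a = pairs$id_a, id_b = pairs$id_b, mode = mode,
             chrom_a = g$chrom[ia], rank_a = g$rank[ia],
             chrom_b = g$chrom[ib], rank_b = g$rank[ib],
             stringsAsFactors = FALSE)
}

#' Count duplicate pairs per mode
#'
#' @param dups output of [classifyDuplicates()].
#' @return named integer vector over the four modes; sums to the number of
#'   pairs.
#' @export
modeSummary <- function(dups) {
  modes <- c("wgd", "tandem", "proximal", "dispersed")
  counts <- vapply(modes, function(m) sum(dups$mode == m), integer(1))
  stats::setNames(counts, modes)
}
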