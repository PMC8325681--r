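# Ancestral karyotype inference from self-synteny and fission/fusion
# bookkeeping. Large self-synteny blocks are taken as chromosome fragments
# doubled by the WGD; greedy maximum-weight matching pairs the two sides of
# each duplicated region, and matched pairs are merged across chromosome
# seams into ancestral linkage groups. A 1<->2 synteny junction is locally
# the same pattern whether one copy fissioned or two copies fused, so seams
# are classified by chromosome gene content calibrated on intact duplicate
# pairs: junctions on oversized chromosomes are fusion seams (kept apart),
# the rest are fission seams (merged).

#' Build a segment graph from self-synteny blocks
#'
#' Each block of at least \code{minAnchors} anchors contributes its two rank
#' intervals as segments and one edge weighted by anchor count. Segments on
#' the same chromosome are merged when their rank intervals overlap by more
#' than half of either interval.
#'
#' @param blocks \linkS4class{SyntenyBlocks} from [selfSynteny()].
#' @param genome the \linkS4class{GenomeAnnotation} the blocks were computed
#'   on.
#' @param minAnchors minimum anchors for a block to count as a "large
#'   fragment" (default 5).
#' @return a \linkS4class{SegmentGraph}.
#' @export
buildSegmentGraph <- function(blocks, genome, minAnchors = 5L) {
  bl <- blockTable(blocks)
  bl <- bl[bl$n_anchors >= minAnchors, , drop = FALSE]
  if (nrow(bl) == 0L)
    stop("no self-synteny block with >= ", minAnchors, " anchors")
  raw <- rbind(
    data.frame(block = bl$block_id, side = "a", chrom = bl$chrom_a,
               lo = bl$start_rank_a, hi = bl$end_rank_a,
               weight = bl$n_anchors, stringsAsFactors = FALSE),
    data.frame(block = bl$block_id, side = "b", chrom = bl$chrom_b,
               lo = bl$start_rank_b, hi = bl$end_rank_b,
               weight = bl$n_anchors, stringsAsFactors = FALSE))
  # union-find merge of >50%-overlapping intervals per chromosome
  parent <- seq_len(nrow(raw))
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (ch in unique(raw$chrom)) {
    idx <- which(raw$chrom == ch)
    if (length(idx) < 2L) next
    for (u in seq_along(idx)[-1]) {
      for (v in seq_len(u - 1L)) {
        i <- idx[u]; j <- idx[v]
        ov <- min(raw$hi[i], raw$hi[j]) - max(raw$lo[i], raw$lo[j]) + 1L
        if (ov <= 0L) next
        li <- raw$hi[i] - raw$lo[i] + 1L
        lj <- raw$hi[j] - raw$lo[j] + 1L
        if (ov > 0.5 * li || ov > 0.5 * lj)
          parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(nrow(raw)), find, integer(1))
  segid <- match(comp, unique(comp))
  segments <- do.call(rbind, lapply(split(seq_len(nrow(raw)), segid),
    function(ii) data.frame(chrom = raw$chrom[ii[1]],
                            start_rank = min(raw$lo[ii]),
                            end_rank = max(raw$hi[ii]),
                            stringsAsFactors = FALSE)))
  segments <- cbind(segment_id = seq_len(nrow(segments)), segments)
  rownames(segments) <- NULL
  e1 <- segid[raw$side == "a"]
  e2 <- segid[raw$side == "b"]
  w <- raw$weight[raw$side == "a"]
  keep <- e1 != e2
  edges <- data.frame(seg1 = pmin(e1, e2)[keep], seg2 = pmax(e1, e2)[keep],
                      weight = w[keep])
  edges <- stats::aggregate(weight ~ seg1 + seg2, data = edges, FUN = sum)
  edges <- edges[order(-edges$weight, edges$seg1, edges$seg2), , drop = FALSE]
  rownames(edges) <- NULL
  g <- geneTable(genome)
  chromGenes <- vapply(split(g$gene_id, g$chrom), length, integer(1))
  methods::new("SegmentGraph", segments = segments, edges = edges,
               chromGenes = chromGenes)
}

#' Infer the ancestral chromosome count
#'
#' Segments are paired greedily by descending edge weight into WGD duplicate
#' pairs. Pairs are then merged across chromosome seams: where two matched
#' segments are consecutive on one chromosome, the seam is a fission seam
#' (the two pairs descend from one ancestral chromosome whose other copy
#' split) unless the chromosome carrying the seam is oversized relative to
#' the typical ancestral chromosome content, in which case it is a fusion
#' seam joining distinct ancestral chromosomes. Typical content is
#' calibrated as the median gene count of chromosomes in clean two-segment
#' duplicate relationships, falling back to the genome-wide median.
#' Unmatched segments are kept as singleton groups with a warning.
#'
#' @param graph a \linkS4class{SegmentGraph}.
#' @param fusionFactor a chromosome counts as oversized (fusion product)
#'   when its gene content is at least this multiple of the typical content
#'   (default 1.5).
#' @return list: \code{nAncestral} (integer) and \code{groups} (list of
#'   integer vectors of segment ids).
#' @export
inferAncestralCount <- function(graph, fusionFactor = 1.5) {
  seg <- graph@segments
  edges <- graph@edges
  if (nrow(seg) == 0L || nrow(edges) == 0L) stop("empty segment graph")

  matched <- rep(NA_integer_, nrow(seg))  # segment -> pair id
  npair <- 0L
  for (k in seq_len(nrow(edges))) {
    s1 <- edges$seg1[k]; s2 <- edges$seg2[k]
    if (is.na(matched[s1]) && is.na(matched[s2])) {
      npair <- npair + 1L
      matched[c(s1, s2)] <- npair
    }
  }
  # an unmatched segment is usually a leftover fragment of its chromosome's
  # duplicate relation: attach it to the nearest matched segment on the same
  # chromosome; truly isolated segments become singleton groups
  unm <- which(is.na(matched))
  for (s in unm) {
    onchrom <- which(seg$chrom == seg$chrom[s] & !is.na(matched))
    if (length(onchrom)) {
      d <- abs(seg$start_rank[onchrom] - seg$start_rank[s])
      matched[s] <- matched[onchrom[which.min(d)]]
    }
  }
  if (anyNA(matched)) {
    iso <- which(is.na(matched))
    warning(length(iso), " unpaired segment(s) kept as singleton group(s)")
    for (s in iso) {
      npair <- npair + 1L
      matched[s] <- npair
    }
  }

  # typical ancestral chromosome content from clean duplicate pairs:
  # chromosomes that carry exactly one matched segment
  segs_per_chrom <- table(seg$chrom)
  clean <- names(segs_per_chrom)[segs_per_chrom == 1L]
  cg <- graph@chromGenes
  typical <- if (length(clean) >= 2L) stats::median(cg[clean])
             else stats::median(cg)

  # union-find over pairs
  parent <- seq_len(npair)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union2 <- function(i, j) parent[find(i)] <<- find(j)

  for (ch in unique(seg$chrom)) {
    ii <- which(seg$chrom == ch)
    if (length(ii) < 2L) next
    ii <- ii[order(seg$start_rank[ii])]
    fused <- is.finite(typical) && cg[[ch]] >= fusionFactor * typical
    for (k in seq_len(length(ii) - 1L)) {
      p1 <- matched[ii[k]]
      p2 <- matched[ii[k + 1L]]
      if (p1 == p2) next
      # same partner chromosome: fragments of one relation, always merge
      partner_chrom <- function(pid, ch) {
        ss <- which(matched == pid & seg$chrom != ch)
        if (length(ss)) seg$chrom[ss[1]] else NA_character_
      }
      pc1 <- partner_chrom(p1, ch)
      pc2 <- partner_chrom(p2, ch)
      if (!is.na(pc1) && !is.na(pc2) && pc1 == pc2) {
        union2(p1, p2)
      } else if (!fused) {
        union2(p1, p2)  # fission seam: one ancestral chromosome
      }
      # fusion seam on an oversized chromosome: keep groups apart
    }
  }

  roots <- vapply(seq_len(npair), find, integer(1))
  groups <- lapply(split(seq_len(npair), roots), function(pids)
    sort(which(matched %in% pids)))
  names(groups) <- NULL
  list(nAncestral = length(groups), groups = groups)
}

#' Validate fission/fusion bookkeeping across a WGD
#'
#' Checks the balance equation
#' nExtant == 2 * nAncestral + nFissions - nFusions and returns the model;
#' violations raise an error naming both sides.
#'
#' @param nAncestral,nExtant,nFissions,nFusions non-negative integer counts.
#' @return a \linkS4class{KaryotypeModel}.
#' @examples
#' accountEvents(9, 15, nFissions = 3, nFusions = 6)  # 18 + 3 - 6 = 15
#' @export
accountEvents <- function(nAncestral, nExtant, nFissions = 0L,
                          nFusions = 0L) {
  methods::new("KaryotypeModel",
               nAncestral = as.integer(nAncestral),
               nPostWgd = 2L * as.integer(nAncestral),
               nFissions = as.integer(nFissions),
               nFusions = as.integer(nFusions),
               nExtant = as.integer(nExtant))
}
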