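# Collinearity chaining in gene-rank space (MCscan-style): anchors are sorted
# by rank on genome A and chained by dynamic programming over rank on genome
# B under a gap constraint; maximal chains are extracted greedily in
# descending score order so that no anchor belongs to two blocks. Both
# collinear and inverted (anti-diagonal) chains are reported.

# Resolve a pair list against two annotations into an anchor table.
# Pairs whose two ids cannot be assigned one to each genome are dropped.
.anchorTable <- function(pairs, genomeA, genomeB) {
  ga <- geneTable(genomeA)
  gb <- geneTable(genomeB)
  ia <- match(pairs$id_a, ga$gene_id)
  ib <- match(pairs$id_b, gb$gene_id)
  # allow the pair order to be swapped relative to the two genomes
  ja <- match(pairs$id_b, ga$gene_id)
  jb <- match(pairs$id_a, gb$gene_id)
  use_swapped <- (is.na(ia) | is.na(ib)) & !is.na(ja) & !is.na(jb)
  ia[use_swapped] <- ja[use_swapped]
  ib[use_swapped] <- jb[use_swapped]
  keep <- !is.na(ia) & !is.na(ib)
  ks <- if ("ks" %in% names(pairs)) pairs$ks[keep]
        else rep(NA_real_, sum(keep))
  out <- data.frame(
    gene_a = ga$gene_id[ia[keep]], gene_b = gb$gene_id[ib[keep]],
    chrom_a = ga$chrom[ia[keep]], rank_a = ga$rank[ia[keep]],
    chrom_b = gb$chrom[ib[keep]], rank_b = gb$rank[ib[keep]],
    ks = ks, stringsAsFactors = FALSE)
  out[!duplicated(out[, c("gene_a", "gene_b")]), , drop = FALSE]
}

# Best chain among the anchors of one chromosome pair and orientation.
# anchors must be sorted by (rank_a, rank_b); returns integer indices into
# that ordering (the unique maximum-length chain that is lexicographically
# smallest in its index sequence), or integer(0).
.bestChain <- function(ra, rb, maxGap, inverted) {
  n <- length(ra)
  if (n == 0L) return(integer(0))
  len <- rep(1L, n)
  nxt <- rep(NA_integer_, n)
  if (n >= 2L) {
    for (i in (n - 1L):1L) {
      best <- 0L
      bestj <- NA_integer_
      for (j in (i + 1L):n) {
        da <- ra[j] - ra[i]
        if (da <= 0L) next
        if (da > maxGap) break  # ra is nondecreasing beyond j
        db <- if (inverted) rb[i] - rb[j] else rb[j] - rb[i]
        if (db <= 0L || db > maxGap) next
        if (len[j] > best) {  # ties keep the smallest j (first encountered)
          best <- len[j]
          bestj <- j
        }
      }
      if (!is.na(bestj)) {
        len[i] <- 1L + best
        nxt[i] <- bestj
      }
    }
  }
  start <- which(len == max(len))[1L]
  chain <- integer(0)
  i <- start
  while (!is.na(i)) {
    chain <- c(chain, i)
    i <- nxt[i]
  }
  chain
}

#' Chain homologous gene pairs into collinear synteny blocks
#'
#' Anchors are grouped by chromosome pair, sorted by rank on the first
#' genome, and chained by dynamic programming over rank on the second genome
#' under the gap constraint |delta rank| <= \code{maxGap} on both axes, in
#' both collinear and inverted orientation. Non-overlapping chains are
#' extracted greedily in descending score (anchor count) order; equal scores
#' are broken by the (chrom_a, min rank_a, chrom_b, min rank_b) tuple, then
#' collinear before inverted. Each anchor is assigned to at most one block;
#' chains shorter than \code{minBlockSize} are discarded.
#'
#' @param pairs data.frame with id_a, id_b (optional ks column, carried onto
#'   anchors).
#' @param genomeA,genomeB \linkS4class{GenomeAnnotation} objects.
#' @param maxGap maximum rank gap between consecutive anchors (default 25).
#' @param minBlockSize minimum anchors per block (default 5).
#' @return a \linkS4class{SyntenyBlocks} object.
#' @export
chainAnchors <- function(pairs, genomeA, genomeB, maxGap = 25L,
                         minBlockSize = 5L) {
  stopifnot(maxGap >= 1L, minBlockSize >= 1L)
  anchors <- .anchorTable(pairs, genomeA, genomeB)
  .chainAnchorTable(anchors, species(genomeA), species(genomeB),
                    maxGap, minBlockSize)
}

.chainAnchorTable <- function(anchors, spA, spB, maxGap, minBlockSize) {
  empty <- function() methods::new(
    "SyntenyBlocks",
    blocks = data.frame(block_id = character(), chrom_a = character(),
                        start_rank_a = integer(), end_rank_a = integer(),
                        chrom_b = character(), start_rank_b = integer(),
                        end_rank_b = integer(), n_anchors = integer(),
                        orientation = character(), score = numeric(),
                        stringsAsFactors = FALSE),
    anchors = data.frame(block_id = character(), gene_a = character(),
                         gene_b = character(), chrom_a = character(),
                         rank_a = integer(), chrom_b = character(),
                         rank_b = integer(), ks = numeric(),
                         stringsAsFactors = FALSE),
    speciesA = spA, speciesB = spB)
  if (nrow(anchors) == 0L) return(empty())
  anchors <- anchors[order(anchors$chrom_a, anchors$chrom_b,
                           anchors$rank_a, anchors$rank_b), , drop = FALSE]
  rownames(anchors) <- NULL
  anchors$.group <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  groups <- split(seq_len(nrow(anchors)), anchors$.group)

  used <- rep(FALSE, nrow(anchors))
  # candidate chains per (group, orientation); recomputed lazily
  cand <- list()
  computeCand <- function(gidx) {
    live <- gidx[!used[gidx]]
    out <- list()
    for (inv in c(FALSE, TRUE)) {
      ch <- .bestChain(anchors$rank_a[live], anchors$rank_b[live],
                       maxGap, inv)
      if (length(ch))
        out[[if (inv) "inverted" else "collinear"]] <- live[ch]
    }
    out
  }
  for (g in names(groups)) cand[[g]] <- computeCand(groups[[g]])

  blocks <- list()
  anchor_rows <- list()
  bid <- 0L
  repeat {
    # pick the global best candidate
    best <- NULL
    for (g in names(cand)) {
      for (ori in names(cand[[g]])) {
        ch <- cand[[g]][[ori]]
        if (length(ch) < minBlockSize) next
        key <- list(
          n = length(ch),
          chrom_a = anchors$chrom_a[ch[1L]],
          min_ra = min(anchors$rank_a[ch]),
          chrom_b = anchors$chrom_b[ch[1L]],
          min_rb = min(anchors$rank_b[ch]),
          ori = ori, chain = ch, group = g)
        better <- is.null(best) ||
          key$n > best$n ||
          (key$n == best$n && (
            key$chrom_a < best$chrom_a ||
            (key$chrom_a == best$chrom_a && (
              key$min_ra < best$min_ra ||
              (key$min_ra == best$min_ra && (
                key$chrom_b < best$chrom_b ||
                (key$chrom_b == best$chrom_b && (
                  key$min_rb < best$min_rb ||
                  (key$min_rb == best$min_rb && key$ori < best$ori)))))))))
        if (better) best <- key
      }
    }
    if (is.null(best)) break
    bid <- bid + 1L
    id <- sprintf("b%04d", bid)
    ch <- best$chain
    used[ch] <- TRUE
    blocks[[id]] <- data.frame(
      block_id = id, chrom_a = best$chrom_a,
      start_rank_a = min(anchors$rank_a[ch]),
      end_rank_a = max(anchors$rank_a[ch]),
      chrom_b = best$chrom_b,
      start_rank_b = min(anchors$rank_b[ch]),
      end_rank_b = max(anchors$rank_b[ch]),
      n_anchors = length(ch), orientation = best$ori,
      score = as.numeric(length(ch)), stringsAsFactors = FALSE)
    rows <- anchors[ch, c("gene_a", "gene_b", "chrom_a", "rank_a",
                          "chrom_b", "rank_b", "ks")]
    rows <- cbind(block_id = id, rows, stringsAsFactors = FALSE)
    anchor_rows[[id]] <- rows
    cand[[best$group]] <- computeCand(groups[[best$group]])
  }
  if (length(blocks) == 0L) return(empty())
  bl <- do.call(rbind, blocks)
  an <- do.call(rbind, anchor_rows)
  rownames(bl) <- rownames(an) <- NULL
  methods::new("SyntenyBlocks", blocks = bl, anchors = an,
               speciesA = spA, speciesB = spB)
}

#' Self-synteny: collinear duplicate blocks within one genome
#'
#' Pairs are canonicalized so the (chrom, rank)-lower gene is on the A side;
#' trivial self-matches and anchors on or near the main diagonal of a single
#' chromosome (|rank_a - rank_b| < \code{minBlockSize} with chrom_a ==
#' chrom_b, i.e. tandem arrays) are suppressed before chaining.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param pairs data.frame with id_a, id_b (both in \code{genome}), optional
#'   ks.
#' @inheritParams chainAnchors
#' @return a \linkS4class{SyntenyBlocks} with speciesA == speciesB.
#' @export
selfSynteny <- function(genome, pairs, maxGap = 25L, minBlockSize = 5L) {
  pairs <- pairs[pairs$id_a != pairs$id_b, , drop = FALSE]
  anchors <- .anchorTable(pairs, genome, genome)
  if (nrow(anchors)) {
    swap <- anchors$chrom_b < anchors$chrom_a |
      (anchors$chrom_b == anchors$chrom_a & anchors$rank_b < anchors$rank_a)
    anchors[swap, c("gene_a", "gene_b", "chrom_a", "chrom_b",
                    "rank_a", "rank_b")] <-
      anchors[swap, c("gene_b", "gene_a", "chrom_b", "chrom_a",
                      "rank_b", "rank_a")]
    near_diag <- anchors$chrom_a == anchors$chrom_b &
      abs(anchors$rank_a - anchors$rank_b) < minBlockSize
    anchors <- anchors[!near_diag, , drop = FALSE]
  }
  .chainAnchorTable(anchors, species(genome), species(genome),
                    maxGap, minBlockSize)
}

#' Syntenic depth profile of a query genome
#'
#' For every gene of the query genome, the depth is the number of distinct
#' blocks whose anchor rank span on the query side covers the gene's rank.
#' For self-synteny both block sides contribute spans. The summary statistic
#' is the modal nonzero depth (smallest mode on ties).
#'
#' @param blocks a \linkS4class{SyntenyBlocks}.
#' @param queryGenome the \linkS4class{GenomeAnnotation} whose genes are
#'   profiled; its species must match one side of \code{blocks}.
#' @return a \linkS4class{DepthProfile}.
#' @export
depthProfile <- function(blocks, queryGenome) {
  sp <- species(queryGenome)
  self_syn <- blocks@speciesA == blocks@speciesB
  sides <- character(0)
  if (blocks@speciesA == sp) sides <- c(sides, "a")
  if (blocks@speciesB == sp && (self_syn || length(sides) == 0L))
    sides <- c(sides, "b")
  if (length(sides) == 0L)
    stop("query species '", sp, "' matches neither side of the blocks")
  bl <- blockTable(blocks)
  spans <- do.call(rbind, lapply(sides, function(s) {
    if (nrow(bl) == 0L) return(NULL)
    data.frame(chrom = bl[[paste0("chrom_", s)]],
               lo = bl[[paste0("start_rank_", s)]],
               hi = bl[[paste0("end_rank_", s)]],
               stringsAsFactors = FALSE)
  }))
  genes <- geneTable(queryGenome)
  depth <- integer(nrow(genes))
  if (!is.null(spans) && nrow(spans)) {
    for (ch in unique(spans$chrom)) {
      sel <- genes$chrom == ch
      if (!any(sel)) next
      sp_ch <- spans[spans$chrom == ch, , drop = FALSE]
      depth[sel] <- IRanges::countOverlaps(
        IRanges::IRanges(genes$rank[sel] + 1L, genes$rank[sel] + 1L),
        IRanges::IRanges(sp_ch$lo + 1L, sp_ch$hi + 1L))
    }
  }
  depths <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                       rank = genes$rank, depth = depth,
                       stringsAsFactors = FALSE)
  hist <- table(depth)
  histogram <- stats::setNames(as.integer(hist), names(hist))
  nz <- depth[depth > 0]
  modal <- if (length(nz)) {
    tz <- table(nz)
    as.numeric(names(tz)[which.max(tz)])
  } else NA_real_
  methods::new("DepthProfile", depths = depths, modalDepth = modal,
               histogram = histogram)
}

#' Anchor coordinate table for dot plots
#'
#' One row per anchor: chrom_a, rank_a, chrom_b, rank_b, block_id,
#' orientation. An empty blocks object yields a zero-row table with the same
#' columns.
#'
#' @param blocks a \linkS4class{SyntenyBlocks}.
#' @param path optional path; when given the table is also written as TSV
#'   (with header).
#' @return the data.frame, invisibly when \code{path} is given.
#' @export
dotplotTable <- function(blocks, path = NULL) {
  an <- anchorTable(blocks)
  ori <- blockTable(blocks)$orientation[match(an$block_id,
                                              blockTable(blocks)$block_id)]
  out <- data.frame(chrom_a = an$chrom_a, rank_a = an$rank_a,
                    chrom_b = an$chrom_b, rank_b = an$rank_b,
                    block_id = an$block_id,
                    orientation = if (length(ori)) ori else character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    return(invisible(out))
  }
  out
}
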