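# Independent oracles used to cross-check the package implementations.
# These are deliberately written as plain brute-force enumerations, sharing
# no code with the package internals.

.GC <- Biostrings::GENETIC_CODE

# --- brute-force NG86 ------------------------------------------------------

oracleSites <- function(codon) {
  sp <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == sp[pos]) next
      v <- sp
      v[pos] <- b
      vc <- paste(v, collapse = "")
      if (.GC[[vc]] != "*" && .GC[[vc]] == .GC[[codon]]) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# all orderings of a vector, recursively
.allOrders <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .allOrders(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

oracleDiffs <- function(ca, cb) {
  sa <- strsplit(ca, "")[[1]]
  sb <- strsplit(cb, "")[[1]]
  dpos <- which(sa != sb)
  if (length(dpos) == 0L) return(c(sd = 0, nd = 0))
  paths <- list()
  for (ord in .allOrders(dpos)) {
    cur <- sa
    sd <- 0
    nd <- 0
    bad <- FALSE
    for (pos in ord) {
      prev <- paste(cur, collapse = "")
      cur[pos] <- sb[pos]
      nxt <- paste(cur, collapse = "")
      if (.GC[[nxt]] == "*") {
        bad <- TRUE
        nd <- nd + 1
      } else if (.GC[[prev]] == .GC[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    paths[[length(paths) + 1L]] <- list(sd = sd, nd = nd, bad = bad)
  }
  good <- Filter(function(p) !p$bad, paths)
  use <- if (length(good)) good else paths
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

oracleKaKs <- function(seqA, seqB) {
  ca <- substring(seqA, seq(1, nchar(seqA), 3), seq(3, nchar(seqA), 3))
  cb <- substring(seqB, seq(1, nchar(seqB), 3), seq(3, nchar(seqB), 3))
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ok[ok] <- vapply(which(ok), function(i)
    .GC[[ca[i]]] != "*" && .GC[[cb[i]]] != "*", logical(1))
  ca <- ca[ok]
  cb <- cb[ok]
  S <- 0
  Sd <- 0
  Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (oracleSites(ca[i])[["s"]] + oracleSites(cb[i])[["s"]]) / 2
    d <- oracleDiffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  N <- 3 * length(ca) - S
  jc <- function(p) {
    a <- 1 - 4 / 3 * p
    if (a <= 0) NA_real_ else -3 / 4 * log(a)
  }
  list(ks = if (S > 0) jc(Sd / S) else NA_real_, ka = jc(Nd / N),
       S = S, N = N, Sd = Sd, Nd = Nd)
}

# random stop-free codon sequence
randomCds <- function(n_codons) {
  sense <- names(.GC)[.GC != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# --- exhaustive chain search ----------------------------------------------

# Greedy extraction where each round's best chain is found by exhaustive
# subset enumeration (n <= 12 anchors on a single chromosome pair). Mirrors
# the declared tie-break: length desc, then min rank_a, min rank_b, then
# collinear before inverted, then lexicographically smallest index sequence.
oracleChainBlocks <- function(ra, rb, maxGap, minBlockSize) {
  ord <- order(ra, rb)
  ra <- ra[ord]
  rb <- rb[ord]
  n <- length(ra)
  alive <- rep(TRUE, n)
  validChain <- function(idx, inverted) {
    if (length(idx) < 2L) return(length(idx) == 1L)
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]
      j <- idx[k + 1L]
      da <- ra[j] - ra[i]
      if (da <= 0 || da > maxGap) return(FALSE)
      db <- if (inverted) rb[i] - rb[j] else rb[j] - rb[i]
      if (db <= 0 || db > maxGap) return(FALSE)
    }
    TRUE
  }
  # per orientation: the maximum-length valid chain with lexicographically
  # smallest index sequence (= what a deterministic DP reconstructs)
  bestForOrientation <- function(live, inverted) {
    best <- NULL
    for (mask in seq_len(2^length(live) - 1L)) {
      idx <- live[bitwAnd(mask, 2^(seq_along(live) - 1L)) > 0]
      if (!validChain(idx, inverted)) next
      if (is.null(best) || length(idx) > length(best)) best <- idx
      else if (length(idx) == length(best)) {
        cmp <- which(idx != best)
        if (length(cmp) && idx[cmp[1]] < best[cmp[1]]) best <- idx
      }
    }
    best
  }
  blocks <- list()
  repeat {
    live <- which(alive)
    if (length(live) == 0L) break
    cand <- list()
    for (inverted in c(FALSE, TRUE)) {
      ch <- bestForOrientation(live, inverted)
      if (!is.null(ch))
        cand[[length(cand) + 1L]] <- list(
          n = length(ch), min_ra = min(ra[ch]), min_rb = min(rb[ch]),
          inv = inverted, idx = ch)
    }
    if (length(cand) == 0L) break
    best <- cand[[1L]]
    for (key in cand[-1L]) {
      better <- key$n > best$n ||
        (key$n == best$n && (key$min_ra < best$min_ra ||
          (key$min_ra == best$min_ra && (key$min_rb < best$min_rb ||
            (key$min_rb == best$min_rb && !key$inv && best$inv)))))
      if (better) best <- key
    }
    if (best$n < minBlockSize) break
    alive[best$idx] <- FALSE
    blocks[[length(blocks) + 1L]] <-
      sort(ord[best$idx])  # membership in original anchor numbering
  }
  blocks
}

# --- duplicate-mode rules, restated independently -------------------------

oracleDupModes <- function(geneTab, pairs, anchorPairs, window = 10L) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  anchors <- key(anchorPairs$gene_a, anchorPairs$gene_b)
  out <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- geneTab[geneTab$gene_id == pairs$id_a[i], ]
    b <- geneTab[geneTab$gene_id == pairs$id_b[i], ]
    if (key(pairs$id_a[i], pairs$id_b[i]) %in% anchors) out[i] <- "wgd"
    else if (a$chrom == b$chrom && abs(a$rank - b$rank) == 1) out[i] <- "tandem"
    else if (a$chrom == b$chrom && abs(a$rank - b$rank) <= window)
      out[i] <- "proximal"
    else out[i] <- "dispersed"
  }
  out
}

# order-normalize + dedupe a pair table (self-pairs silently removed)
normalizePairsForTest <- function(tab) {
  tab <- tab[tab$id_a != tab$id_b, , drop = FALSE]
  swap <- tab$id_a > tab$id_b
  tmp <- tab$id_a[swap]
  tab$id_a[swap] <- tab$id_b[swap]
  tab$id_b[swap] <- tmp
  tab <- tab[!duplicated(tab[, c("id_a", "id_b")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# --- small fixture builders ------------------------------------------------

toyGenome <- function(n_chrom = 1L, genes_per_chrom = 20L, species = "sp") {
  rows <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
    data.frame(
      gene_id = sprintf("%s_c%d_g%02d", species, ci, seq_len(genes_per_chrom)),
      chrom = sprintf("chr%d", ci),
      start = (seq_len(genes_per_chrom) - 1L) * 1000L + 1L,
      end = (seq_len(genes_per_chrom) - 1L) * 1000L + 900L,
      strand = "+", stringsAsFactors = FALSE)
  }))
  genomeAnnotation(rows, species)
}
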