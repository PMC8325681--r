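# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor multiple-hit correction.
#
# Site counting and pathway-averaged difference counting are precomputed for
# all 64 x 64 codon pairs at namespace load; computeKaKs() is then a pure
# table lookup, vectorized over codons.

.ng <- new.env(parent = emptyenv())

.ngBases <- c("A", "C", "G", "T")

# All orderings of 1..k positions, k = 1..3.
.ngPerms <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

.ngInit <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- unname(code)
  stop_codon <- aa == "*"
  n <- length(codons)

  # Per-codon synonymous site count: for each position, the fraction of the 3
  # single-nucleotide changes that preserve the amino acid. Changes to stop
  # codons count as nonsynonymous.
  syn <- rep(NA_real_, n)
  splitc <- strsplit(codons, "")
  for (i in seq_len(n)) {
    if (stop_codon[i]) next
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(.ngBases, splitc[[i]][pos])) {
        v <- splitc[[i]]
        v[pos] <- b
        vc <- paste(v, collapse = "")
        if (code[[vc]] != "*" && code[[vc]] == aa[i]) s <- s + 1 / 3
      }
    }
    syn[i] <- s
  }

  # Pathway-averaged synonymous/nonsynonymous difference counts for every
  # ordered codon pair. Pathways through stop codons are excluded; if every
  # pathway passes through a stop, all are included with stop-producing steps
  # counted as nonsynonymous (documented fallback).
  sd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd <- sd
  for (i in seq_len(n)) {
    if (stop_codon[i]) next
    for (j in seq_len(n)) {
      if (stop_codon[j]) next
      diffpos <- which(splitc[[i]] != splitc[[j]])
      k <- length(diffpos)
      if (k == 0L) {
        sd[i, j] <- 0
        nd[i, j] <- 0
        next
      }
      paths <- lapply(.ngPerms[[k]], function(ord) {
        cur <- splitc[[i]]
        s <- 0
        ns <- 0
        through_stop <- FALSE
        for (pos in diffpos[ord]) {
          prev <- paste(cur, collapse = "")
          cur[pos] <- splitc[[j]][pos]
          nxt <- paste(cur, collapse = "")
          if (code[[nxt]] == "*") {
            through_stop <- TRUE
            ns <- ns + 1
          } else if (code[[prev]] == "*") {
            ns <- ns + 1
          } else if (code[[prev]] == code[[nxt]]) {
            s <- s + 1
          } else {
            ns <- ns + 1
          }
        }
        list(s = s, ns = ns, through_stop = through_stop)
      })
      ok <- !vapply(paths, `[[`, logical(1), "through_stop")
      use <- if (any(ok)) paths[ok] else paths
      sd[i, j] <- mean(vapply(use, `[[`, numeric(1), "s"))
      nd[i, j] <- mean(vapply(use, `[[`, numeric(1), "ns"))
    }
  }

  .ng$codons <- codons
  .ng$aa <- stats::setNames(aa, codons)
  .ng$syn <- stats::setNames(syn, codons)
  .ng$sd <- sd
  .ng$nd <- nd
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) .ngInit()

.ngEnsure <- function() {
  if (is.null(.ng$sd)) .ngInit()
}

.checkCodon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("codon must be a single 3-mer string")
  codon <- toupper(codon)
  if (!codon %in% .ng$codons || grepl("[^ACGT]", codon))
    stop("ambiguous or non-nucleotide codon: ", codon)
  if (.ng$aa[[codon]] == "*")
    stop("stop codon not allowed: ", codon)
  codon
}

#' NG86 synonymous/nonsynonymous site counts for one codon
#'
#' For each codon position, the number of the three possible single-nucleotide
#' changes that are synonymous, divided by 3, accumulates into the synonymous
#' site count s; changes producing a stop codon count as nonsynonymous. The
#' counts satisfy s + n == 3 exactly.
#'
#' @param codon a gapless 3-mer over ACGT, not a stop codon.
#' @return named numeric \code{c(s = ..., n = ...)}.
#' @examples
#' countSites("GGT")  # fourfold third position: s = 1
#' @export
countSites <- function(codon) {
  .ngEnsure()
  codon <- .checkCodon(codon)
  s <- .ng$syn[[codon]]
  c(s = s, n = 3 - s)
}

#' NG86 pathway-averaged difference counts for a codon pair
#'
#' For codons differing at k positions, the synonymous and nonsynonymous
#' difference counts are averaged over all k! orderings of the single-base
#' changes. Orderings passing through a stop codon are excluded from the
#' average; when every ordering does, all are retained with stop-producing
#' steps counted as nonsynonymous.
#'
#' @param codonA,codonB gapless non-stop 3-mers over ACGT.
#' @return named numeric \code{c(sd = ..., nd = ...)}; sd + nd equals the
#'   number of differing positions.
#' @examples
#' countDifferences("GGT", "GGC")  # single synonymous change
#' @export
countDifferences <- function(codonA, codonB) {
  .ngEnsure()
  codonA <- .checkCodon(codonA)
  codonB <- .checkCodon(codonB)
  c(sd = .ng$sd[codonA, codonB], nd = .ng$nd[codonA, codonB])
}

# Split a sequence string into codons; returns character vector.
.toCodons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' NG86 Ka/Ks for one codon-aligned sequence pair
#'
#' Codons containing gaps, ambiguity codes, or a stop in either sequence are
#' removed pairwise. Site counts S and N are averaged over the two sequences;
#' proportions ps = Sd/S and pn = Nd/N are Jukes-Cantor corrected:
#' Ks = -(3/4) log(1 - (4/3) ps), Ka likewise. Saturated values
#' (log argument <= 0, i.e. ps >= 3/4) are returned as NA with a status flag
#' rather than dropped.
#'
#' @param seqA,seqB equal-length codon-aligned nucleotide strings (alphabet
#'   ACGT plus "-" for alignment gaps).
#' @return one-row data.frame: ka, ks, ratio, s_sites, n_sites, s_diffs,
#'   n_diffs, codons_used, status. status is "ok", "saturated" (Ks
#'   undefined), "no_syn_sites" or "no_codons" (error-free sentinel rows are
#'   not produced: zero usable codons is an error).
#' @examples
#' computeKaKs(strrep("GGT", 9), paste0(strrep("GGT", 8), "GGC"))
#' @export
computeKaKs <- function(seqA, seqB) {
  .ngEnsure()
  if (nchar(seqA) != nchar(seqB))
    stop("sequences must be codon-aligned to equal length")
  ca <- .toCodons(seqA)
  cb <- .toCodons(seqB)
  valid <- ca %in% .ng$codons & cb %in% .ng$codons &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  valid[valid] <- .ng$aa[ca[valid]] != "*" & .ng$aa[cb[valid]] != "*"
  ca <- ca[valid]
  cb <- cb[valid]
  if (length(ca) == 0L) stop("zero usable codons after filtering")
  S <- (sum(.ng$syn[ca]) + sum(.ng$syn[cb])) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(.ng$sd[cbind(ca, cb)])
  Nd <- sum(.ng$nd[cbind(ca, cb)])
  status <- "ok"
  if (S <= 0) {
    ks <- NA_real_
    status <- "no_syn_sites"
  } else {
    ps <- Sd / S
    arg <- 1 - 4 / 3 * ps
    if (arg <= 0) {
      ks <- NA_real_
      status <- "saturated"
    } else ks <- -3 / 4 * log(arg)
  }
  pn <- Nd / N
  argn <- 1 - 4 / 3 * pn
  ka <- if (argn <= 0) NA_real_ else -3 / 4 * log(argn)
  if (is.na(ka) && status == "ok") status <- "saturated"
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  data.frame(ka = ka, ks = ks, ratio = ratio, s_sites = S, n_sites = N,
             s_diffs = Sd, n_diffs = Nd, codons_used = length(ca),
             status = status, stringsAsFactors = FALSE)
}

#' NG86 Ka/Ks for a list of pairs against a sequence set
#'
#' @param pairs data.frame with id_a, id_b.
#' @param cds named character vector or \code{DNAStringSet} of coding
#'   sequences.
#' @return data.frame: id_a, id_b plus the [computeKaKs()] columns; pairs
#'   whose sequences are missing or unusable get NA values and a status of
#'   "missing_sequence" or "no_codons".
#' @export
kaksPairs <- function(pairs, cds) {
  if (methods::is(cds, "XStringSet")) cds <- as.character(cds)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$id_a[i]
    b <- pairs$id_b[i]
    if (!a %in% names(cds) || !b %in% names(cds))
      return(data.frame(ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                        s_sites = NA_real_, n_sites = NA_real_,
                        s_diffs = NA_real_, n_diffs = NA_real_,
                        codons_used = 0L, status = "missing_sequence",
                        stringsAsFactors = FALSE))
    tryCatch(computeKaKs(cds[[a]], cds[[b]]),
             error = function(e)
               data.frame(ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                          s_sites = NA_real_, n_sites = NA_real_,
                          s_diffs = NA_real_, n_diffs = NA_real_,
                          codons_used = 0L, status = "no_codons",
                          stringsAsFactors = FALSE))
  })
  cbind(pairs[, c("id_a", "id_b")], do.call(rbind, res))
}
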