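# Rooted gene-tree classification: does the focal duplication precede the
# focal/partner speciation (shared WGD) or postdate it (lineage-specific
# WGD)? Classification is purely topological; branch lengths are ignored.

#' Species tags of tip labels
#'
#' The species is the prefix of the tip label before the first occurrence of
#' the delimiter, e.g. "Cs_gene42" -> "Cs".
#'
#' @param labels character vector of tip labels.
#' @param delimiter delimiter string (default "_").
#' @return character vector of species tags.
#' @export
tipSpecies <- function(labels, delimiter = "_") {
  vapply(strsplit(labels, delimiter, fixed = TRUE), `[[`, character(1), 1L)
}

#' Root a gene tree on its outgroup
#'
#' The tree is rooted on the edge separating all outgroup-species tips from
#' all ingroup tips. An outgroup that is not monophyletic under any rooting
#' is an error (callers classifying trees catch it and fall back to an
#' "other" call).
#'
#' @param tree a \code{phylo}.
#' @param outgroupSpecies character vector of outgroup species tags.
#' @param delimiter tip label delimiter, see [tipSpecies()].
#' @return a rooted \code{phylo}.
#' @export
rootWithOutgroup <- function(tree, outgroupSpecies, delimiter = "_") {
  sp <- tipSpecies(tree$tip.label, delimiter)
  og <- tree$tip.label[sp %in% outgroupSpecies]
  if (length(og) == 0L) stop("no outgroup tip in tree")
  if (length(og) == length(tree$tip.label))
    stop("all tips are outgroup tips")
  ape::root(tree, outgroup = og, resolve.root = TRUE)
}

# tip labels under an internal node (or the tip itself)
.cladeTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Classify one gene tree as shared or independent WGD
#'
#' The tree is rooted on the outgroup; with M the most recent common
#' ancestor of the two focal-species tips (the WGD paralog pair), the call
#' is \code{shared} when the two child subtrees of M holding the focal tips
#' each contain at least one partner-species tip (the duplication precedes
#' the focal/partner speciation); \code{independent} when the subtree under
#' M contains focal-species tips only; and \code{other} otherwise, including
#' every precondition failure (not exactly two focal tips, no partner or
#' outgroup tip, non-monophyletic outgroup, ambiguous polytomy).
#'
#' @param tree a \code{phylo} (rooted or not; rooting is redone on the
#'   outgroup).
#' @param focalSpecies single focal species tag (the WGD lineage assayed).
#' @param partnerSpecies character vector of candidate sharing lineages; any
#'   one of them satisfying the condition suffices.
#' @param outgroupSpecies character vector of outgroup species tags.
#' @param delimiter tip label delimiter.
#' @return list with elements \code{call} ("shared"/"independent"/"other"),
#'   \code{reason}, and \code{focal_tips}.
#' @export
classifyWgdTopology <- function(tree, focalSpecies, partnerSpecies,
                                outgroupSpecies, delimiter = "_") {
  other <- function(reason)
    list(call = "other", reason = reason, focal_tips = character(0))
  sp <- tipSpecies(tree$tip.label, delimiter)
  focal_tips <- tree$tip.label[sp == focalSpecies]
  if (length(focal_tips) != 2L)
    return(other(sprintf("expected 2 focal tips, found %d", length(focal_tips))))
  if (!any(sp %in% partnerSpecies)) return(other("no partner tip"))
  if (!any(sp %in% outgroupSpecies)) return(other("no outgroup tip"))
  rooted <- tryCatch(rootWithOutgroup(tree, outgroupSpecies, delimiter),
                     error = function(e) NULL)
  if (is.null(rooted)) return(other("outgroup not monophyletic"))
  m <- ape::getMRCA(rooted, focal_tips)
  clade <- .cladeTips(rooted, m)
  clade_sp <- tipSpecies(clade, delimiter)
  if (all(clade_sp == focalSpecies))
    return(list(call = "independent", reason = "focal-only clade under MRCA",
                focal_tips = focal_tips))
  children <- rooted$edge[rooted$edge[, 1] == m, 2]
  child_tips <- lapply(children, .cladeTips, tree = rooted)
  holds_focal <- vapply(child_tips, function(tt) any(tt %in% focal_tips),
                        logical(1))
  focal_children <- child_tips[holds_focal]
  if (length(focal_children) != 2L)
    return(other("ambiguous polytomy at focal MRCA"))
  has_partner <- vapply(focal_children, function(tt)
    any(tipSpecies(tt, delimiter) %in% partnerSpecies), logical(1))
  if (all(has_partner))
    return(list(call = "shared",
                reason = "both focal subtrees carry a partner tip",
                focal_tips = focal_tips))
  other("partner tips do not bracket the duplication")
}

#' Classify a list of gene trees
#'
#' @param trees list of \code{phylo} objects (named or not).
#' @inheritParams classifyWgdTopology
#' @return data.frame: tree_id, call, reason.
#' @export
classifyTrees <- function(trees, focalSpecies, partnerSpecies,
                          outgroupSpecies, delimiter = "_") {
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("tree%05d", seq_along(trees))
  calls <- lapply(trees, classifyWgdTopology, focalSpecies = focalSpecies,
                  partnerSpecies = partnerSpecies,
                  outgroupSpecies = outgroupSpecies, delimiter = delimiter)
  data.frame(tree_id = ids,
             call = vapply(calls, `[[`, character(1), "call"),
             reason = vapply(calls, `[[`, character(1), "reason"),
             stringsAsFactors = FALSE)
}

#' Summarize topology calls
#'
#' Percentages are computed on the full tree count; the shared ratio is
#' 100 * shared / (shared + independent), the statistic used to weigh
#' shared-WGD support against lineage-specific support. Values are kept at
#' full precision; rounding is a presentation concern.
#'
#' @param calls data.frame from [classifyTrees()] or a character vector of
#'   calls.
#' @return a \linkS4class{TopologySummary}.
#' @export
summarizeCalls <- function(calls) {
  v <- if (is.data.frame(calls)) calls$call else calls
  ns <- sum(v == "shared")
  ni <- sum(v == "independent")
  no <- sum(v == "other")
  nt <- length(v)
  if (ns + ni + no != nt) stop("unknown call values present")
  pct <- function(x) if (nt == 0L) 0 else 100 * x / nt
  sr <- if (ns + ni == 0L) NaN else 100 * ns / (ns + ni)
  methods::new("TopologySummary", nShared = as.integer(ns),
               nIndependent = as.integer(ni), nOther = as.integer(no),
               nTotal = as.integer(nt), pctShared = pct(ns),
               pctIndependent = pct(ni), sharedRatio = sr)
}

#' Build a TopologySummary from counts
#'
#' Convenience for published count tables where individual trees are not
#' available.
#'
#' @param nShared,nIndependent,nOther integer counts.
#' @return a \linkS4class{TopologySummary}.
#' @export
topologySummaryFromCounts <- function(nShared, nIndependent, nOther = 0L) {
  summarizeCalls(c(rep("shared", nShared), rep("independent", nIndependent),
                   rep("other", nOther)))
}
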