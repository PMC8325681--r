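# Seeded simulator: a diploid ancestor, one WGD with partial retention,
# post-WGD fissions/fusions/inversions, paralog Ks from stated mixtures,
# codon pairs evolved at target Ka/Ks, and gene trees with a set fraction of
# duplication-before-speciation topologies. Every emitted object carries its
# ground truth; identical plan + seed gives byte-identical output.

#' Construct a simulation plan
#'
#' Defaults replay the tea-plant WGD history: a 9-chromosome ancestor,
#' whole-genome duplication with 50% duplicate retention, 3 fissions and 6
#' fusions (reaching 15 extant chromosomes), WGD-pair Ks lognormal with mode
#' 0.425, and a shared-topology fraction of 0.685.
#'
#' @param seed mandatory integer seed.
#' @param nChromosomes,genesPerChromosome ancestor dimensions (9 x 200).
#' @param wgdRetention per-gene probability of retaining both duplicates.
#' @param ksMode,ksSigma lognormal Ks parameters of WGD pairs (mode on the
#'   Ks scale; sigma on the log scale).
#' @param backgroundRate exponential rate of background small-scale
#'   duplicate Ks.
#' @param nFissions,nFusions,nInversions post-WGD rearrangement counts.
#' @param pShared probability that a simulated gene tree shows the
#'   shared-WGD topology.
#' @return a \linkS4class{SimulationPlan}.
#' @export
simulationPlan <- function(seed, nChromosomes = 9L, genesPerChromosome = 200L,
                           wgdRetention = 0.5, ksMode = 0.425,
                           ksSigma = 0.2, backgroundRate = 1,
                           nFissions = 3L, nFusions = 6L, nInversions = 3L,
                           pShared = 0.685) {
  if (missing(seed)) stop("seed is mandatory")
  methods::new("SimulationPlan", seed = as.integer(seed),
               nChromosomes = as.integer(nChromosomes),
               genesPerChromosome = as.integer(genesPerChromosome),
               wgdRetention = wgdRetention, ksMode = ksMode,
               ksSigma = ksSigma, backgroundRate = backgroundRate,
               nFissions = as.integer(nFissions),
               nFusions = as.integer(nFusions),
               nInversions = as.integer(nInversions), pShared = pShared)
}

# sample() that never falls into the 1:n scalar trap
.resample <- function(x, n = 1L) x[sample.int(length(x), n)]

# deterministic ancestor layout: list of chromosomes, each a vector of
# ancestral gene indices 1..(nChrom * genesPerChrom)
.ancestorLayout <- function(plan) {
  nc <- plan@nChromosomes
  gpc <- plan@genesPerChromosome
  lapply(seq_len(nc), function(i) ((i - 1L) * gpc + 1L):(i * gpc))
}

# lay out a chromosome list as a gene table (900 bp genes, 100 bp spacers)
.layoutGenome <- function(chroms, gene_ids, species) {
  rows <- lapply(seq_along(chroms), function(ci) {
    ids <- gene_ids[abs(chroms[[ci]])]
    pos <- seq_along(ids)
    data.frame(gene_id = ids,
               chrom = sprintf("%s_chr%02d", species, ci),
               start = (pos - 1L) * 1000L + 1L,
               end = (pos - 1L) * 1000L + 900L,
               strand = ifelse(chroms[[ci]] < 0L, "-", "+"),
               stringsAsFactors = FALSE)
  })
  genomeAnnotation(do.call(rbind, rows), species)
}

#' Simulate a post-WGD genome with recorded ground truth
#'
#' The ancestor of \code{nChromosomes x genesPerChromosome} genes is
#' duplicated in full; each duplicate copy is then deleted independently
#' with probability 1 - \code{wgdRetention}. Fissions (split at a uniform
#' random rank), fusions (concatenation of two random chromosomes) and
#' inversions (reversal of a random rank interval, flipping strand) are
#' applied after the WGD. Retained paralog pairs are emitted with lognormal
#' Ks; tandem, proximal and dispersed background pairs (2%, 1% and 2% of
#' gene count) are sprinkled with exponential Ks.
#'
#' @param plan a \linkS4class{SimulationPlan}.
#' @param species species tag of the simulated genome (default "css").
#' @return list: \code{annotation} (\linkS4class{GenomeAnnotation}),
#'   \code{pairs} (data.frame id_a, id_b, ks, true_mode), and \code{truth}
#'   (list: nAncestral, nFissions, nFusions, nInversions, nExtant,
#'   retainedPairs, ancestralGene named map).
#' @export
simulateWgdGenome <- function(plan, species = "css") {
  methods::validObject(plan)
  set.seed(plan@seed)
  nc <- plan@nChromosomes
  gpc <- plan@genesPerChromosome
  nAnc <- nc * gpc

  # WGD: two copies of each ancestral gene; gene index space 1..2*nAnc,
  # copy 2 of ancestral gene j is j + nAnc
  chroms <- c(.ancestorLayout(plan),
              lapply(.ancestorLayout(plan), function(v) v + nAnc))

  # retention: each ancestral gene loses one random copy with prob 1 - rho
  lose <- runif(nAnc) > plan@wgdRetention
  side <- rbinom(nAnc, 1L, 0.5)  # 0: drop copy 1, 1: drop copy 2
  drop_idx <- c((1:nAnc)[lose & side == 0L], ((1:nAnc) + nAnc)[lose & side == 1L])
  chroms <- lapply(chroms, function(v) v[!abs(v) %in% drop_idx])

  # rearrangements (post-WGD): fissions, fusions, inversions
  for (k in seq_len(plan@nFissions)) {
    sizes <- vapply(chroms, length, integer(1))
    eligible <- which(sizes >= 10L)
    ci <- .resample(eligible)
    at <- .resample(5:(sizes[ci] - 5L))
    chroms <- c(chroms[-ci],
                list(chroms[[ci]][1:at]),
                list(chroms[[ci]][(at + 1L):sizes[ci]]))
  }
  for (k in seq_len(plan@nFusions)) {
    if (length(chroms) < 2L) break
    ij <- sample.int(length(chroms), 2L)
    fused <- c(chroms[[ij[1]]], chroms[[ij[2]]])
    chroms <- c(chroms[-ij], list(fused))
  }
  for (k in seq_len(plan@nInversions)) {
    sizes <- vapply(chroms, length, integer(1))
    eligible <- which(sizes >= 4L)
    ci <- .resample(eligible)
    bounds <- sort(sample.int(sizes[ci], 2L))
    v <- chroms[[ci]]
    v[bounds[1]:bounds[2]] <- -rev(v[bounds[1]:bounds[2]])
    chroms[[ci]] <- v
  }
  # deterministic chromosome order by smallest ancestral gene content
  chroms <- chroms[order(vapply(chroms, function(v) min(abs(v)), integer(1)))]

  gene_ids <- sprintf("%sg%05d", species, seq_len(2L * nAnc))
  annot <- .layoutGenome(chroms, gene_ids, species)

  # retained WGD paralog pairs
  present <- sort(unique(abs(unlist(chroms))))
  both <- intersect(present[present <= nAnc], present[present > nAnc] - nAnc)
  wgd_pairs <- data.frame(id_a = gene_ids[both], id_b = gene_ids[both + nAnc],
                          ks = exp(rnorm(length(both), log(plan@ksMode),
                                         plan@ksSigma)),
                          true_mode = "wgd", stringsAsFactors = FALSE)

  # background small-scale duplicates planted on the extant gene order
  gt <- geneTable(annot)
  usable <- rep(TRUE, nrow(gt))
  pick_pair <- function(kind) {
    for (try in 1:50) {
      i <- .resample(which(usable))
      j <- switch(kind,
        tandem = {
          cand <- which(usable & gt$chrom == gt$chrom[i] &
                        abs(gt$rank - gt$rank[i]) == 1L)
          if (length(cand)) cand[1L] else NA_integer_
        },
        proximal = {
          cand <- which(usable & gt$chrom == gt$chrom[i] &
                        abs(gt$rank - gt$rank[i]) > 1L &
                        abs(gt$rank - gt$rank[i]) <= 10L)
          if (length(cand)) .resample(cand) else NA_integer_
        },
        dispersed = {
          cand <- which(usable & gt$chrom != gt$chrom[i])
          if (length(cand)) .resample(cand) else NA_integer_
        })
      if (!is.na(j)) {
        usable[c(i, j)] <<- FALSE
        return(c(i, j))
      }
    }
    NULL
  }
  n_genes <- nrow(gt)
  counts <- c(tandem = max(1L, round(0.02 * n_genes)),
              proximal = max(1L, round(0.01 * n_genes)),
              dispersed = max(1L, round(0.02 * n_genes)))
  bg <- list()
  for (kind in names(counts)) {
    for (k in seq_len(counts[[kind]])) {
      ij <- pick_pair(kind)
      if (is.null(ij)) next
      bg[[length(bg) + 1L]] <- data.frame(
        id_a = gt$gene_id[ij[1]], id_b = gt$gene_id[ij[2]],
        ks = rexp(1L, plan@backgroundRate), true_mode = kind,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- rbind(wgd_pairs, do.call(rbind, bg))
  # order-normalize ids without touching ks/mode assignment
  swap <- pairs$id_a > pairs$id_b
  tmp <- pairs$id_a[swap]
  pairs$id_a[swap] <- pairs$id_b[swap]
  pairs$id_b[swap] <- tmp
  rownames(pairs) <- NULL

  ancestralGene <- stats::setNames(
    c(seq_len(nAnc), seq_len(nAnc)), gene_ids)
  list(annotation = annot, pairs = pairs,
       truth = list(nAncestral = nc, nFissions = plan@nFissions,
                    nFusions = plan@nFusions,
                    nInversions = plan@nInversions,
                    nExtant = length(chroms),
                    retainedPairs = nrow(wgd_pairs),
                    ancestralGene = ancestralGene),
       plan = plan, species = species)
}

#' Simulate a pre-WGD outgroup genome and ortholog pairs
#'
#' The outgroup is the unduplicated ancestor of the simulated WGD genome
#' (same chromosome count and gene order, no WGD). Each outgroup gene is
#' orthologous to every retained copy of its ancestral gene in the WGD
#' genome; ortholog Ks is lognormal around \code{divergenceKs}. This yields
#' the 2:1 syntenic depth signature of one extra WGD.
#'
#' @param sim result of [simulateWgdGenome()].
#' @param divergenceKs split-peak Ks between the two lineages (> 0).
#' @param sigma log-scale sd of ortholog Ks (default 0.15).
#' @param species outgroup species tag (default "vv").
#' @return list: \code{annotation} (outgroup
#'   \linkS4class{GenomeAnnotation}) and \code{orthologs} (data.frame id_a
#'   = WGD-genome gene, id_b = outgroup gene, ks).
#' @export
simulateOutgroupGenome <- function(sim, divergenceKs, sigma = 0.15,
                                   species = "vv") {
  if (!is.finite(divergenceKs) || divergenceKs <= 0)
    stop("divergenceKs must be > 0")
  plan <- sim$plan
  set.seed(plan@seed + 1L)
  nAnc <- plan@nChromosomes * plan@genesPerChromosome
  og_ids <- sprintf("%sg%05d", species, seq_len(nAnc))
  annot <- .layoutGenome(.ancestorLayout(plan), og_ids, species)
  present <- geneTable(sim$annotation)$gene_id
  anc <- sim$truth$ancestralGene[present]
  orth <- data.frame(id_a = present, id_b = og_ids[anc],
                     ks = exp(rnorm(length(present), log(divergenceKs),
                                    sigma)),
                     stringsAsFactors = FALSE)
  list(annotation = annot, orthologs = orth)
}

#' Evolve codon-aligned sequence pairs at target Ka/Ks
#'
#' Random stop-free codon sequences receive synonymous and nonsynonymous
#' substitutions whose expected observed densities equal the Jukes-Cantor
#' inversion of the targets (ps = 3/4 (1 - exp(-4/3 Ks)) per synonymous
#' site, and likewise for Ka), so the NG86 estimator is unbiased in
#' expectation. At most one change of each kind is applied per codon, which
#' bounds the usable target range; saturation-risk targets are an error.
#'
#' @param nPairs number of pairs.
#' @param nCodons codons per sequence (default 300).
#' @param targetKs,targetKa target divergences (>= 0; the implied per-codon
#'   substitution probability must stay below 1).
#' @param seed RNG seed.
#' @return list of length \code{nPairs}; each element is
#'   \code{list(id_a, id_b, seq_a, seq_b)}.
#' @export
evolveCodonPairs <- function(nPairs, nCodons = 300L, targetKs = 0.4,
                             targetKa = 0, seed = 1L) {
  .ngEnsure()
  if (targetKs < 0 || targetKa < 0) stop("targets must be >= 0")
  ps <- 3 / 4 * (1 - exp(-4 / 3 * targetKs))
  pn <- 3 / 4 * (1 - exp(-4 / 3 * targetKa))
  if (ps >= 0.7 || pn >= 0.7)
    stop("saturation-risk target (implied site divergence >= 0.7)")
  set.seed(seed)
  sense <- .ng$codons[.ng$aa != "*"]
  syn <- .ng$syn

  # per-codon lists of synonymous / nonsynonymous single-change variants
  variants <- lapply(sense, function(cd) {
    v <- character(0); cls <- character(0)
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (b in setdiff(.ngBases, sp[pos])) {
      w <- sp; w[pos] <- b
      wc <- paste(w, collapse = "")
      if (.ng$aa[[wc]] == "*") next
      v <- c(v, wc)
      cls <- c(cls, if (.ng$aa[[wc]] == .ng$aa[[cd]]) "s" else "n")
    }
    list(syn = v[cls == "s"], nonsyn = v[cls == "n"])
  })
  names(variants) <- sense

  out <- vector("list", nPairs)
  for (p in seq_len(nPairs)) {
    cods <- sample(sense, nCodons, replace = TRUE)
    mut <- cods
    # synonymous hits: per codon prob ps * s_codon (expected diffs ps * S)
    if (ps > 0) {
      prob <- pmin(1, ps * syn[cods])
      hit <- runif(nCodons) < prob
      for (i in which(hit)) {
        vs <- variants[[cods[i]]]$syn
        if (length(vs)) mut[i] <- vs[sample.int(length(vs), 1L)]
      }
    }
    if (pn > 0) {
      prob <- pmin(1, pn * (3 - syn[cods]))
      hit <- runif(nCodons) < prob
      for (i in which(hit)) {
        vs <- variants[[mut[i]]]$nonsyn
        if (length(vs)) mut[i] <- vs[sample.int(length(vs), 1L)]
      }
    }
    out[[p]] <- list(id_a = sprintf("sim%04d_a", p),
                     id_b = sprintf("sim%04d_b", p),
                     seq_a = paste(cods, collapse = ""),
                     seq_b = paste(mut, collapse = ""))
  }
  out
}

#' Simulate rooted gene trees with known topology class
#'
#' Shared trees have topology (((F1,P1),(F2,P2)),O) — the focal duplication
#' precedes the focal/partner speciation; independent trees have
#' (((F1,F2),P1),O). With noise rate \code{epsilon}, a tree has two random
#' tip labels swapped, degrading it to a different (usually "other") class.
#'
#' @param n number of trees.
#' @param pShared probability of the shared topology.
#' @param focalSpecies,partnerSpecies,outgroupSpecies species tags; one
#'   partner and one outgroup species are drawn per tree.
#' @param seed RNG seed.
#' @param epsilon per-tree label-swap noise rate (default 0).
#' @return list: \code{trees} (list of \code{phylo}), \code{truth}
#'   (character vector "shared"/"independent").
#' @export
simulateGeneTrees <- function(n, pShared, focalSpecies = "Cs",
                              partnerSpecies = c("Ac", "Rs"),
                              outgroupSpecies = "Vv", seed = 1L,
                              epsilon = 0) {
  stopifnot(pShared >= 0, pShared <= 1, epsilon >= 0, epsilon <= 1)
  set.seed(seed)
  shared <- runif(n) < pShared
  trees <- vector("list", n)
  cnt <- 0L
  for (i in seq_len(n)) {
    cnt <- cnt + 1L
    f1 <- sprintf("%s_g%da", focalSpecies, cnt)
    f2 <- sprintf("%s_g%db", focalSpecies, cnt)
    p1sp <- sample(partnerSpecies, 1L)
    p2sp <- sample(partnerSpecies, 1L)
    p1 <- sprintf("%s_g%dc", p1sp, cnt)
    p2 <- sprintf("%s_g%dd", p2sp, cnt)
    o1 <- sprintf("%s_g%de", sample(outgroupSpecies, 1L), cnt)
    txt <- if (shared[i])
      sprintf("(((%s,%s),(%s,%s)),%s);", f1, p1, f2, p2, o1)
    else
      sprintf("(((%s,%s),%s),%s);", f1, f2, p1, o1)
    tr <- ape::read.tree(text = txt)
    if (epsilon > 0 && runif(1) < epsilon) {
      ij <- sample.int(length(tr$tip.label), 2L)
      tr$tip.label[ij] <- tr$tip.label[rev(ij)]
    }
    trees[[i]] <- tr
  }
  list(trees = trees,
       truth = ifelse(shared, "shared", "independent"))
}
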