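# End-to-end orchestration on simulated data: synteny -> duplicate
# classification -> NG86 Ka/Ks -> Ks distribution (peaks, rate correction,
# dating) -> gene-tree topologies -> karyotype. Every random draw descends
# from the single seed in the config, so a config fully determines the
# report.

#' Default pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param plan a \linkS4class{SimulationPlan}; defaults to
#'   \code{simulationPlan(seed)}.
#' @param divergenceKs true split-peak Ks between the focal lineage and the
#'   outgroup (default 0.781).
#' @param calibration list(ksCal, tMya) for dating, or NULL to skip the
#'   dating stage (default: Ks 0.781 at 118 MY).
#' @param rateFactor relative synonymous rate of the partner lineage used to
#'   exercise the rate correction (its split peak is divergenceKs *
#'   rateFactor; default 1.25).
#' @param maxGap,minBlockSize synteny chaining parameters.
#' @param ksFilter c(lo, hi) Ks filter range.
#' @param peakMethod "gmm" or "kde".
#' @param nSeqPairs number of codon pairs evolved per Ks sample when
#'   estimating Ks through sequences (default 300).
#' @param nCodons codons per simulated sequence (default 300).
#' @param nTrees number of simulated gene trees (default 1000).
#' @return a config list accepted by [runPipeline()].
#' @export
pipelineConfig <- function(seed, plan = simulationPlan(seed),
                           divergenceKs = 0.781,
                           calibration = list(ksCal = 0.781, tMya = 118),
                           rateFactor = 1.25, maxGap = 25L,
                           minBlockSize = 5L, ksFilter = c(0.01, 3.0),
                           peakMethod = c("gmm", "kde"), nSeqPairs = 300L,
                           nCodons = 300L, nTrees = 1000L) {
  list(seed = as.integer(seed), plan = plan, divergenceKs = divergenceKs,
       calibration = calibration, rateFactor = rateFactor,
       maxGap = as.integer(maxGap), minBlockSize = as.integer(minBlockSize),
       ksFilter = ksFilter, peakMethod = match.arg(peakMethod),
       nSeqPairs = as.integer(nSeqPairs), nCodons = as.integer(nCodons),
       nTrees = as.integer(nTrees))
}

# estimate a Ks peak by evolving codon pairs at given true Ks values and
# running the NG86 estimator over them
.ksPeakThroughSequences <- function(true_ks, n_pairs, n_codons, label,
                                    filter, method, seed) {
  use <- true_ks[is.finite(true_ks)]
  if (length(use) > n_pairs) {
    set.seed(seed)
    use <- .resample(use, n_pairs)
  }
  est <- numeric(length(use))
  for (i in seq_along(use)) {
    p <- evolveCodonPairs(1L, n_codons, targetKs = min(use[i], 2.0),
                          targetKa = 0.05, seed = seed + i)[[1L]]
    est[i] <- computeKaKs(p$seq_a, p$seq_b)$ks
  }
  sample <- buildKsSample(est, label, filter[1], filter[2])
  list(sample = sample,
       peak = estimatePeak(sample, method = method, seed = seed),
       mean_abs_error = mean(abs(est - use), na.rm = TRUE))
}

#' Run the full WGD inference chain on simulated data
#'
#' Executes: genome + outgroup simulation, self-synteny and cross-species
#' synteny with depth profiles, duplicate-mode classification, NG86 Ka/Ks on
#' sequences evolved at the simulated true Ks, Ks-distribution peaks with
#' rate correction and Ks = 2rt dating, gene-tree topology classification,
#' and karyotype reconstruction with fission/fusion bookkeeping. Any stage
#' failure aborts with the stage name; if \code{calibration} is NULL the
#' dating section is marked skipped.
#'
#' @param config list from [pipelineConfig()].
#' @param verbose log stage progress to stderr.
#' @return a report list with one section per stage; serialize with
#'   [writeReport()].
#' @export
runPipeline <- function(config, verbose = FALSE) {
  say <- function(stage) if (verbose) message("[paleowgd] stage: ", stage)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(seed = config$seed)

  say("simulate")
  sim <- stage("simulate", simulateWgdGenome(config$plan))
  og <- stage("simulate", simulateOutgroupGenome(sim, config$divergenceKs))
  report$simulation <- list(
    n_genes = nrow(geneTable(sim$annotation)),
    n_extant_chromosomes = sim$truth$nExtant,
    n_retained_wgd_pairs = sim$truth$retainedPairs)

  say("synteny")
  self_blocks <- stage("synteny", selfSynteny(
    sim$annotation, sim$pairs, config$maxGap, config$minBlockSize))
  cross_blocks <- stage("synteny", chainAnchors(
    data.frame(id_a = og$orthologs$id_a, id_b = og$orthologs$id_b,
               ks = og$orthologs$ks, stringsAsFactors = FALSE),
    sim$annotation, og$annotation, config$maxGap, config$minBlockSize))
  depth_self <- stage("synteny", depthProfile(self_blocks, sim$annotation))
  depth_query <- stage("synteny", depthProfile(cross_blocks, og$annotation))
  depth_reverse <- stage("synteny", depthProfile(cross_blocks, sim$annotation))
  report$synteny <- list(
    n_self_blocks = nrow(blockTable(self_blocks)),
    n_self_anchors = nrow(anchorTable(self_blocks)),
    n_cross_blocks = nrow(blockTable(cross_blocks)),
    n_cross_anchors = nrow(anchorTable(cross_blocks)),
    modal_depth_self = modalDepth(depth_self),
    modal_depth_outgroup_vs_wgd = modalDepth(depth_query),
    modal_depth_wgd_vs_outgroup = modalDepth(depth_reverse))

  say("duplicate classification")
  dups <- stage("dup_classifier", classifyDuplicates(
    sim$annotation, sim$pairs, self_blocks))
  truth_mode <- sim$pairs$true_mode[match(
    paste(dups$id_a, dups$id_b), paste(sim$pairs$id_a, sim$pairs$id_b))]
  report$duplicates <- list(
    mode_counts = as.list(modeSummary(dups)),
    planted_mode_accuracy = mean(dups$mode == truth_mode, na.rm = TRUE))

  say("kaks + ks distribution")
  wgd_keys <- paste(dups$id_a[dups$mode == "wgd"],
                    dups$id_b[dups$mode == "wgd"])
  wgd_true_ks <- sim$pairs$ks[match(wgd_keys,
                                    paste(sim$pairs$id_a, sim$pairs$id_b))]
  wgd_est <- stage("kaks", .ksPeakThroughSequences(
    wgd_true_ks, config$nSeqPairs, config$nCodons, "wgd_pairs",
    config$ksFilter, config$peakMethod, config$seed + 1000L))
  split_est <- stage("kaks", .ksPeakThroughSequences(
    og$orthologs$ks, config$nSeqPairs, config$nCodons, "focal_vs_outgroup",
    config$ksFilter, config$peakMethod, config$seed + 2000L))
  report$ks <- list(
    wgd_peak = peakMode(wgd_est$peak),
    split_peak = peakMode(split_est$peak),
    ng86_mean_abs_error = wgd_est$mean_abs_error,
    n_wgd_sample = length(ksValues(wgd_est$sample)),
    n_split_sample = length(ksValues(split_est$sample)))

  say("rate correction")
  # a partner lineage evolving rateFactor times faster: its split peak
  # against the same outgroup is divergenceKs * rateFactor
  set.seed(config$seed + 3000L)
  partner_split <- buildKsSample(
    exp(rnorm(2000L, log(config$divergenceKs * config$rateFactor), 0.15)),
    "partner_vs_outgroup", config$ksFilter[1], config$ksFilter[2])
  partner_peak <- estimatePeak(partner_split, method = config$peakMethod,
                               seed = config$seed + 3000L)
  corr <- stage("rate_correction",
                rateCorrection(split_est$peak, partner_peak))
  report$rate_correction <- list(
    reference_split_peak = peakMode(split_est$peak),
    partner_split_peak = peakMode(partner_peak),
    coefficient = correctionCoefficient(corr))

  say("dating")
  if (is.null(config$calibration)) {
    report$dating <- list(skipped = TRUE)
  } else {
    dat <- stage("dating", dateEvent(peakMode(wgd_est$peak),
                                     config$calibration$ksCal,
                                     config$calibration$tMya))
    report$dating <- list(
      event_peak = peakMode(wgd_est$peak),
      calibration_ks = config$calibration$ksCal,
      calibration_t_mya = config$calibration$tMya,
      rate = substitutionRate(dat),
      wgd_age_mya = eventAgeMya(dat))
  }

  say("tree topology")
  trees <- stage("tree_topology", simulateGeneTrees(
    config$nTrees, config$plan@pShared, seed = config$seed + 4000L))
  calls <- stage("tree_topology", classifyTrees(
    trees$trees, "Cs", c("Ac", "Rs"), "Vv"))
  ts <- summarizeCalls(calls)
  report$trees <- list(
    n_total = ts@nTotal, n_shared = ts@nShared,
    n_independent = ts@nIndependent, n_other = ts@nOther,
    pct_shared = ts@pctShared, pct_independent = ts@pctIndependent,
    shared_ratio = ts@sharedRatio,
    accuracy = mean(calls$call == trees$truth))

  say("chromosome evolution")
  seg <- stage("chromosome_evolution",
               buildSegmentGraph(self_blocks, sim$annotation))
  anc <- stage("chromosome_evolution",
               suppressWarnings(inferAncestralCount(seg)))
  karyo <- tryCatch(
    accountEvents(anc$nAncestral, sim$truth$nExtant,
                  sim$truth$nFissions, sim$truth$nFusions),
    error = function(e) NULL)
  report$karyotype <- list(
    inferred_ancestral = anc$nAncestral,
    true_ancestral = sim$truth$nAncestral,
    n_extant = sim$truth$nExtant,
    n_fissions = sim$truth$nFissions,
    n_fusions = sim$truth$nFusions,
    bookkeeping_consistent = !is.null(karyo))
  report
}

#' Serialize a pipeline report as canonical JSON
#'
#' The same report always yields the same bytes (no timestamps, fixed digit
#' handling), so reports can be compared by hash.
#'
#' @param report list from [runPipeline()].
#' @param path optional output path.
#' @return the JSON string, invisibly when \code{path} is given.
#' @export
writeReport <- function(report, path = NULL) {
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
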