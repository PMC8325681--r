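# Ks distribution construction, peak location, cross-species rate
# correction and Ks = 2rt molecular dating. All density machinery operates
# on log(Ks): Ks is positive and right-skewed, and Gaussian kernels and
# mixtures behave on the log scale.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Build a filtered Ks sample
#'
#' Undefined (NA/NaN/Inf) and out-of-range values are dropped; the number of
#' dropped values is recorded. The default range (0.01, 3) excludes
#' allelic/near-zero pairs and saturated estimates.
#'
#' @param ks numeric vector of Ks values (NAs allowed).
#' @param label sample label.
#' @param lo,hi inclusive filter range.
#' @return a \linkS4class{KsSample}; all values filtered out is an error.
#' @export
buildKsSample <- function(ks, label = "sample", lo = 0.01, hi = 3.0) {
  keep <- is.finite(ks) & ks >= lo & ks <= hi
  dropped <- length(ks) - sum(keep)
  if (!any(keep))
    stop("all ", length(ks), " Ks values filtered out in [", lo, ", ", hi, "]")
  methods::new("KsSample", label = label, values = as.numeric(ks[keep]),
               filterRange = c(lo, hi), nDropped = as.integer(dropped))
}

#' Locate the peak of a Ks distribution
#'
#' kde: Gaussian kernel density of log(Ks) with Silverman's bandwidth on a
#' 512-point grid; the mode is the grid argmax mapped back to the Ks scale.
#' gmm: Gaussian mixtures (unequal variances) fitted to log(Ks) by EM for
#' k = 1..\code{kMax} components, selected by BIC; the mode is
#' exp(location) of the heaviest component. Samples smaller than 50 fall
#' back from gmm to kde with a warning. Results are deterministic given
#' \code{seed}.
#'
#' @param sample a \linkS4class{KsSample}.
#' @param method "kde" or "gmm".
#' @param kMax maximum number of mixture components (default 4).
#' @param seed RNG seed for EM initialization reproducibility.
#' @return a \linkS4class{PeakEstimate}.
#' @export
estimatePeak <- function(sample, method = c("kde", "gmm"), kMax = 4L,
                         seed = 1L) {
  method <- match.arg(method)
  v <- log(ksValues(sample))
  if (method == "gmm" && length(v) < 50L) {
    warning("sample too small for gmm (n = ", length(v), "); falling back to kde")
    method <- "kde"
  }
  if (method == "kde") {
    if (length(unique(v)) == 1L)
      return(methods::new("PeakEstimate", mode = exp(v[1]), method = "kde",
                          components = data.frame(), stat = 0))
    d <- stats::density(v, bw = "nrd0", n = 512L)
    mode <- exp(d$x[which.max(d$y)])
    return(methods::new("PeakEstimate", mode = mode, method = "kde",
                        components = data.frame(), stat = d$bw))
  }
  set.seed(seed)
  bic <- mclust::mclustBIC(v, G = seq_len(kMax), modelNames = "V",
                           verbose = FALSE)
  fit <- mclust::Mclust(v, x = bic, verbose = FALSE)
  if (is.null(fit))
    stop("gmm fit failed")
  p <- fit$parameters
  comp <- data.frame(weight = p$pro, location = as.numeric(p$mean),
                     scale = sqrt(as.numeric(p$variance$sigmasq)))
  if (nrow(comp) > 1L && length(comp$scale) < nrow(comp))
    comp$scale <- rep(comp$scale[1], nrow(comp))
  heavy <- which.max(comp$weight)
  methods::new("PeakEstimate", mode = exp(comp$location[heavy]),
               method = "gmm", components = comp, stat = max(fit$BIC, na.rm = TRUE))
}

#' Number of mixture components selected by BIC
#'
#' @param peak a gmm \linkS4class{PeakEstimate}.
#' @return integer component count (1 for kde estimates).
#' @export
nComponents <- function(peak) {
  if (peak@method == "kde") return(1L)
  nrow(peak@components)
}

#' Cross-species substitution-rate correction coefficient
#'
#' Two lineages that diverged from a common outgroup at the same time should
#' show the same split-peak Ks; when they do not, the faster lineage's Ks
#' scale is rescaled by C = reference split peak / other split peak, so that
#' reference = other * C at the shared split.
#'
#' @param referenceSplit,otherSplit \linkS4class{PeakEstimate}s of the two
#'   lineages' split peaks against the common outgroup.
#' @return a \linkS4class{RateCorrection}.
#' @export
rateCorrection <- function(referenceSplit, otherSplit) {
  ref <- peakMode(referenceSplit)
  oth <- peakMode(otherSplit)
  if (!is.finite(oth) || oth <= 0) stop("other split peak must be > 0")
  if (!is.finite(ref) || ref <= 0) stop("reference split peak must be > 0")
  methods::new("RateCorrection", referencePeak = ref, otherPeak = oth,
               coefficient = ref / oth)
}

#' Rescale a Ks sample by a rate-correction coefficient
#'
#' Every value is multiplied by C; the filter range is unchanged and the
#' label is annotated. Values pushed outside the filter range by the
#' rescaling are kept (the range documents the original filtering).
#'
#' @param sample a \linkS4class{KsSample}.
#' @param corr a \linkS4class{RateCorrection}.
#' @return a rescaled \linkS4class{KsSample}.
#' @export
applyCorrection <- function(sample, corr) {
  C <- correctionCoefficient(corr)
  out <- sample
  out@values <- sample@values * C
  out@label <- paste0(sample@label, "_corrected")
  rng <- out@filterRange
  out@filterRange <- c(min(rng[1] * C, rng[1]), max(rng[2] * C, rng[2]))
  methods::validObject(out)
  out
}

#' Date an event peak by Ks = 2rt
#'
#' The per-lineage synonymous rate is calibrated from a known divergence:
#' r = Ks_cal / (2 T_cal); the event age is then t = peak / (2 r), i.e.
#' t = peak * T_cal / Ks_cal.
#'
#' @param eventPeak Ks peak of the event to date (> 0).
#' @param calKs split-peak Ks of the calibration divergence (> 0).
#' @param calT age of the calibration divergence in million years (> 0).
#' @return a \linkS4class{DatingResult}.
#' @examples
#' eventAgeMya(dateEvent(0.425, calKs = 0.781, calT = 118))
#' @export
dateEvent <- function(eventPeak, calKs, calT) {
  if (!all(is.finite(c(eventPeak, calKs, calT))) ||
      any(c(eventPeak, calKs, calT) <= 0))
    stop("eventPeak, calKs and calT must all be > 0")
  r <- calKs / (2 * calT)
  methods::new("DatingResult", rate = r, timeMya = eventPeak / (2 * r),
               calKs = calKs, calT = calT, eventPeak = eventPeak)
}
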