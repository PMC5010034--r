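# Down-sampling normalization of sequencing depth across methylomes.

#' Common 4-CpG segments across samples
#'
#' Segments covered by at least `minDepth` reads in all samples, with the
#' per-segment minimum depth D_min.
#'
#' @param clusterSets list of [PatternClusterSet-class], one per sample
#'   (names used as sample ids, else [sampleId()]).
#' @param minDepth minimum depth in every sample (default 10).
#' @return data.frame with `key`, one depth column per sample, and
#'   `dmin`. A warning is emitted when the intersection is empty.
#' @export
commonSegments <- function(clusterSets, minDepth = 10) {
  stopifnot(length(clusterSets) >= 2)
  ids <- names(clusterSets)
  if (is.null(ids)) ids <- vapply(clusterSets, sampleId, "")
  depthTabs <- lapply(clusterSets, function(cs) {
    d <- clusterDepths(cs)
    stats::setNames(d, segmentKeys(cs))[d >= minDepth]
  })
  keys <- Reduce(intersect, lapply(depthTabs, names))
  if (!length(keys)) {
    warning("no segment is covered at >= ", minDepth, "x in all samples")
    out <- data.frame(key = character(0))
    for (id in ids) out[[id]] <- numeric(0)
    out$dmin <- numeric(0)
    return(out)
  }
  out <- data.frame(key = keys)
  for (i in seq_along(ids)) out[[ids[i]]] <- unname(depthTabs[[i]][keys])
  out$dmin <- do.call(pmin, out[ids])
  out
}

#' Randomly down-sample one cluster to a target depth
#'
#' Uniform subset of reads without replacement; operates on the
#' canonicalised pattern multiset so the result is invariant to pattern
#' input order.
#'
#' @param counts named pattern-count vector.
#' @param targetDepth subsample size; must not exceed the depth.
#' @param seed RNG seed.
#' @return named pattern-count vector of total `targetDepth`.
#' @export
downsampleCluster <- function(counts, targetDepth, seed = 1) {
  n <- sum(counts)
  if (targetDepth > n) stop("targetDepth exceeds cluster depth")
  if (targetDepth == n) return(counts[order(names(counts))])
  counts <- counts[order(names(counts))]
  lab <- rep(names(counts), counts)
  pick <- withSeed(seed, function() sample.int(n, targetDepth))
  tab <- table(lab[pick])
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-segment pCSM detection probability under down-sampling
#'
#' Repeats the down-sampling of a cluster to `targetDepth` and records
#' the fraction of repeats in which the segment is called bipolar. With
#' `classifier = "prefilter"` only the prefilter (depth + concurrent
#' MMMM/UUUU) is applied to each subsample; with `"full"` (default) the
#' mixture classifier is re-run as well.
#'
#' @param counts named pattern-count vector.
#' @param targetDepth subsample depth (D_min).
#' @param nRepeats number of repeats (default 100).
#' @param seed master seed; repeat r uses a derived stream.
#' @param classifier `"full"` or `"prefilter"`.
#' @param minDepth prefilter depth (default 10).
#' @param ... further arguments to [classifyBipolar()]'s single-cluster
#'   machinery (method, thresholds, sweeps).
#' @return detection probability in \[0, 1\].
#' @export
detectionProbability <- function(counts, targetDepth, nRepeats = 100,
                                 seed = 1, classifier = c("full", "prefilter"),
                                 minDepth = 10, method = "dp_gibbs",
                                 hypoMax = 0.25, hyperMin = 0.75,
                                 wMin = 0.10, alpha = 1,
                                 basePrior = c(0.5, 0.5), sweeps = 200,
                                 burnin = 100, maxDepth = 500) {
  classifier <- match.arg(classifier)
  hits <- 0L
  for (r in seq_len(nRepeats)) {
    sub <- downsampleCluster(counts, targetDepth,
                             seed = deriveSeed(seed, paste0("rep", r)))
    ok <- passesPrefilter(sub, minDepth)
    if (ok && classifier == "full") {
      res <- classifyOneCluster(sub,
        seed = deriveSeed(seed, paste0("cls", r)), method = method,
        hypoMax = hypoMax, hyperMin = hyperMin, wMin = wMin, alpha = alpha,
        basePrior = basePrior, sweeps = sweeps, burnin = burnin,
        maxDepth = maxDepth)
      ok <- res$isBipolar
    }
    if (ok) hits <- hits + 1L
  }
  hits / nRepeats
}

#' Depth-normalized pCSM frequency per sample
#'
#' For every common segment, each sample's cluster is down-sampled to the
#' segment's D_min `nRepeats` times and the detection probability
#' recorded; the normalized frequency is the mean detection probability
#' over common segments (alternatively the fraction of segments with
#' probability above `threshold`).
#'
#' @param clusterSets named list of [PatternClusterSet-class].
#' @param minDepth coverage requirement (default 10).
#' @param nRepeats down-sampling repeats (default 100).
#' @param seed master seed; each (segment, sample) gets a derived stream.
#' @param aggregate `"mean"` (default) or `"threshold"`.
#' @param threshold probability cut for `"threshold"` aggregation.
#' @param ... passed to [detectionProbability()].
#' @return list with `frequencies` (named numeric per sample) and
#'   `detection` (data.frame key x sample of probabilities).
#' @export
normalizedFrequency <- function(clusterSets, minDepth = 10, nRepeats = 100,
                                seed = 1, aggregate = c("mean", "threshold"),
                                threshold = 0.5, ...) {
  aggregate <- match.arg(aggregate)
  ids <- names(clusterSets)
  if (is.null(ids)) {
    ids <- vapply(clusterSets, sampleId, "")
    names(clusterSets) <- ids
  }
  common <- commonSegments(clusterSets, minDepth)
  det <- data.frame(key = common$key)
  for (id in ids) {
    cs <- clusterSets[[id]]
    keyIdx <- match(common$key, segmentKeys(cs))
    det[[id]] <- vapply(seq_len(nrow(common)), function(i) {
      detectionProbability(
        patternCounts(cs)[[keyIdx[i]]], common$dmin[i], nRepeats,
        seed = deriveSeed(seed, paste0(common$key[i], "|", id)),
        minDepth = minDepth, ...)
    }, numeric(1))
  }
  freq <- vapply(ids, function(id) {
    if (!nrow(det)) return(undefinedValue())
    if (aggregate == "mean") mean(det[[id]])
    else mean(det[[id]] > threshold)
  }, numeric(1))
  list(frequencies = freq, detection = det)
}
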