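# Bipolar (cell-subset specific) methylation detection.

# methylated-CpG count per read, expanded from a pattern-count vector in
# canonical (lexicographic pattern) order, so every downstream step is
# invariant to pattern input order
expandKCounts <- function(counts) {
  counts <- counts[order(names(counts))]
  kPer <- vapply(names(counts), function(p)
    sum(strsplit(p, "")[[1]] == "M"), integer(1))
  rep(kPer, counts)
}

#' Bipolar prefilter
#'
#' A cluster is eligible for bipolar classification iff its depth is at
#' least `minDepth` and it contains at least one completely methylated
#' (MMMM) and one completely unmethylated (UUUU) read concurrently.
#'
#' @param clusters a [PatternClusterSet-class] or a single named
#'   pattern-count vector.
#' @param minDepth minimum read depth (default 10).
#' @return logical vector, one element per cluster.
#' @export
passesPrefilter <- function(clusters, minDepth = 10) {
  cl <- if (is(clusters, "PatternClusterSet")) patternCounts(clusters)
        else list(clusters)
  vapply(cl, function(cc) {
    sum(cc) >= minDepth &&
      !is.na(cc["MMMM"]) && cc[["MMMM"]] >= 1L &&
      !is.na(cc["UUUU"]) && cc[["UUUU"]] >= 1L
  }, logical(1))
}

fitDpGibbs <- function(k, nTrials, alpha, basePrior, sweeps, burnin,
                       hypoMax, hyperMin, wMin, seed) {
  withSeed(seed, function()
    .dpGibbsFit(as.integer(k), nTrials, alpha, basePrior[1], basePrior[2],
                sweeps, burnin, hypoMax, hyperMin, wMin))
}

# Finite binomial-mixture EM with K components; deterministic quantile
# initialisation. Returns means, weights and log-likelihood.
fitBinomMixEm <- function(k, nTrials, K, maxIter = 500, tol = 1e-9) {
  n <- length(k)
  p <- stats::quantile(k / nTrials, probs = (seq_len(K) - 0.5) / K,
                       names = FALSE, type = 7)
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  w <- rep(1 / K, K)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    lg <- vapply(seq_len(K), function(j)
      log(w[j]) + stats::dbinom(k, nTrials, p[j], log = TRUE), numeric(n))
    lg <- matrix(lg, nrow = n)
    mx <- apply(lg, 1, max)
    post <- exp(lg - mx)
    rs <- rowSums(post)
    llNew <- sum(mx + log(rs))
    post <- post / rs
    w <- colMeans(post)
    p <- colSums(post * k) / (nTrials * colSums(post))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    if (is.finite(ll) && abs(llNew - ll) < tol) { ll <- llNew; break }
    ll <- llNew
  }
  list(means = p, weights = w, loglik = ll)
}

fitEmBic <- function(k, nTrials, kMax = 3) {
  n <- length(k)
  fits <- lapply(seq_len(kMax), function(K) fitBinomMixEm(k, nTrials, K))
  bic <- vapply(seq_len(kMax), function(K)
    -2 * fits[[K]]$loglik + (2 * K - 1) * log(n), numeric(1))
  fits[[which.min(bic)]]
}

# Exhaustive grid ML for a two-component binomial mixture plus a
# likelihood-ratio gate against the one-component fit; test oracle path.
fitLrtOracle <- function(k, nTrials, grid = seq(0, 1, by = 0.01),
                         wGrid = seq(0.05, 0.95, by = 0.05),
                         lrtCut = stats::qchisq(0.95, df = 2)) {
  n <- length(k)
  tab <- tabulate(k + 1L, nbins = nTrials + 1L)
  kk <- 0:nTrials
  lik1p <- function(p) sum(tab * stats::dbinom(kk, nTrials, p, log = TRUE))
  p1hat <- min(max(mean(k) / nTrials, 1e-9), 1 - 1e-9)
  ll1 <- lik1p(p1hat)
  dmat <- vapply(grid, function(p)
    stats::dbinom(kk, nTrials, p), numeric(nTrials + 1L))
  best <- list(ll = -Inf)
  for (iw in seq_along(wGrid)) {
    w <- wGrid[iw]
    mix <- w * dmat  # n_k x n_p
    for (i in seq_along(grid)) {
      dens <- mix[, i] + (1 - w) * dmat
      llv <- colSums(tab * log(pmax(dens, 1e-300)))
      j <- which.max(llv)
      if (llv[j] > best$ll)
        best <- list(ll = llv[j], means = c(grid[i], grid[j]),
                     weights = c(w, 1 - w))
    }
  }
  if (2 * (best$ll - ll1) > lrtCut)
    list(means = best$means, weights = best$weights, loglik = best$ll)
  else
    list(means = p1hat, weights = 1, loglik = ll1)
}

#' Classify 4-CpG clusters as bipolar
#'
#' Fits a mixture model over the per-read methylated-CpG counts
#' (k in 0..4) of each prefilter-passing cluster and calls the cluster
#' bipolar when the fit contains both a hypomethylated component
#' (mean <= `hypoMax`) and a hypermethylated component
#' (mean >= `hyperMin`), each with weight >= `wMin`.
#'
#' Methods: `dp_gibbs` (default) is a Dirichlet-process mixture of
#' Beta-Binomial components fit by collapsed Gibbs sampling; the bipolar
#' condition is evaluated on each post-burn-in sweep and the cluster is
#' called bipolar when the posterior fraction of qualifying sweeps is at
#' least 0.5. `em_bic` fits finite binomial mixtures (K = 1..3) by EM
#' with BIC selection, fully deterministic. `lrt_oracle` is an
#' exhaustive-grid two-component maximum-likelihood fit gated by a
#' likelihood-ratio test, intended as an independent reference path.
#'
#' All methods operate on the canonicalised pattern multiset, so results
#' are invariant to pattern input order; `dp_gibbs` derives one RNG
#' stream per (segment, sample) from `seed`.
#'
#' @param clusters a [PatternClusterSet-class].
#' @param seed master seed (dp_gibbs and depth-cap subsampling).
#' @param method one of `"dp_gibbs"`, `"em_bic"`, `"lrt_oracle"`.
#' @param minDepth prefilter depth (default 10).
#' @param hypoMax,hyperMin,wMin bipolarity thresholds (defaults 0.25,
#'   0.75, 0.10).
#' @param alpha DP concentration (default 1).
#' @param basePrior Beta base-measure parameters (default c(0.5, 0.5)).
#' @param sweeps,burnin Gibbs sweeps and burn-in (defaults 200, 100).
#' @param maxDepth clusters deeper than this are subsampled (seeded)
#'   before fitting (default 500).
#' @return a [GenomicRanges::GRanges], one range per cluster, with
#'   metadata columns `depth`, `eligible` (depth >= `minDepth`),
#'   `prefilterPass` (depth plus concurrent MMMM/UUUU), `isBipolar`,
#'   `nComponents`, `hypoWeight`, `hyperWeight`, `componentMeans` and
#'   `componentWeights` (comma-separated), `method`, `sampleId`.
#' @export
classifyBipolar <- function(clusters, seed = 1,
                            method = c("dp_gibbs", "em_bic", "lrt_oracle"),
                            minDepth = 10, hypoMax = 0.25, hyperMin = 0.75,
                            wMin = 0.10, alpha = 1, basePrior = c(0.5, 0.5),
                            sweeps = 200, burnin = 100, maxDepth = 500) {
  method <- match.arg(method)
  stopifnot(is(clusters, "PatternClusterSet"))
  n <- length(clusters)
  depth <- clusterDepths(clusters)
  eligible <- depth >= minDepth
  prefilter <- passesPrefilter(clusters, minDepth)
  keys <- segmentKeys(clusters)
  out <- clusterSegments(clusters)
  isBip <- logical(n); nComp <- integer(n)
  hypoW <- numeric(n); hyperW <- numeric(n)
  cmeans <- character(n); cweights <- character(n)
  for (i in seq_len(n)) {
    if (!prefilter[i]) { isBip[i] <- FALSE; nComp[i] <- NA_integer_
      hypoW[i] <- NA_real_; hyperW[i] <- NA_real_
      cmeans[i] <- NA_character_; cweights[i] <- NA_character_; next }
    res <- classifyOneCluster(
      patternCounts(clusters)[[i]],
      seed = deriveSeed(seed, paste0(keys[i], "|", sampleId(clusters))),
      method = method, hypoMax = hypoMax, hyperMin = hyperMin, wMin = wMin,
      alpha = alpha, basePrior = basePrior, sweeps = sweeps,
      burnin = burnin, maxDepth = maxDepth)
    isBip[i] <- res$isBipolar
    nComp[i] <- length(res$means)
    hypoW[i] <- res$hypoWeight; hyperW[i] <- res$hyperWeight
    cmeans[i] <- paste(sprintf("%.4f", res$means), collapse = ",")
    cweights[i] <- paste(sprintf("%.4f", res$weights), collapse = ",")
  }
  S4Vectors::mcols(out) <- cbind(S4Vectors::mcols(out), S4Vectors::DataFrame(
    depth = as.integer(depth), eligible = eligible,
    prefilterPass = prefilter,
    isBipolar = isBip, nComponents = nComp, hypoWeight = hypoW,
    hyperWeight = hyperW, componentMeans = cmeans,
    componentWeights = cweights, method = method,
    sampleId = sampleId(clusters)))
  out
}

# one cluster; `counts` is a named pattern-count vector that passed the
# prefilter (contract)
classifyOneCluster <- function(counts, seed, method, hypoMax, hyperMin,
                               wMin, alpha, basePrior, sweeps, burnin,
                               maxDepth) {
  if (!passesPrefilter(counts))
    stop("classifyOneCluster called on a cluster failing the prefilter")
  k <- expandKCounts(counts)
  if (length(k) > maxDepth)
    k <- withSeed(seed + 1L, function() sort(sample(k, maxDepth)))
  nTrials <- 4L
  if (method == "dp_gibbs") {
    fit <- fitDpGibbs(k, nTrials, alpha, basePrior, sweeps, burnin,
                      hypoMax, hyperMin, wMin, seed)
    means <- fit$component_means; weights <- fit$component_weights
    isBip <- fit$bipolar_prob >= 0.5
  } else {
    fit <- if (method == "em_bic") fitEmBic(k, nTrials)
           else fitLrtOracle(k, nTrials)
    means <- fit$means; weights <- fit$weights
    isBip <- any(weights >= wMin & means <= hypoMax) &&
             any(weights >= wMin & means >= hyperMin)
  }
  list(isBipolar = isBip, means = means, weights = weights,
       hypoWeight = sum(weights[means <= hypoMax]),
       hyperWeight = sum(weights[means >= hyperMin]))
}

#' Exclude sex chromosomes and imprinted regions
#'
#' Bipolar segments on excluded chromosomes, or overlapping (>= 1 bp) any
#' imprinted interval, mimic cell-subset specificity through allele- or
#' sex-linked methylation and are removed before pCSM calling.
#'
#' @param calls GRanges of segment calls (from [classifyBipolar()]) or
#'   any GRanges.
#' @param sexChroms chromosomes to drop (default chrX, chrY).
#' @param imprinted GRanges of imprinted regions, or a BED path.
#' @return the filtered GRanges.
#' @export
filterCalls <- function(calls, sexChroms = c("chrX", "chrY"),
                        imprinted = NULL) {
  keep <- !(as.character(GenomicRanges::seqnames(calls)) %in% sexChroms)
  if (!is.null(imprinted)) {
    if (is.character(imprinted)) imprinted <- readBed(imprinted)
    ov <- IRanges::overlapsAny(calls, imprinted, ignore.strand = TRUE)
    keep <- keep & !ov
  }
  calls[keep]
}

#' Merge overlapping bipolar segments into pCSM regions
#'
#' Transitive closure of pairwise-overlapping segment spans, per
#' chromosome; output regions are disjoint and sorted.
#'
#' @param segments GRanges of bipolar segments.
#' @return GRanges of merged regions with an `nSegments` metadata column.
#' @export
mergeRegions <- function(segments) {
  segments <- GenomicRanges::granges(segments)
  GenomeInfoDb::seqlevels(segments) <-
    sort(GenomeInfoDb::seqlevels(segments))
  segments <- GenomicRanges::sort(segments, ignore.strand = TRUE)
  red <- GenomicRanges::reduce(segments, ignore.strand = TRUE,
                               min.gapwidth = 0L)
  S4Vectors::mcols(red)$nSegments <-
    GenomicRanges::countOverlaps(red, segments, ignore.strand = TRUE)
  red
}

#' pCSM frequency
#'
#' Fraction of eligible clusters (depth >= minDepth) that are called
#' bipolar and retained after filtering.
#'
#' @param calls GRanges from [classifyBipolar()], optionally after
#'   [filterCalls()]; must carry `eligible` and `isBipolar`.
#' @param nEligible optionally override the eligible-segment count (e.g.
#'   when `calls` was filtered but the denominator should be unfiltered).
#' @return a fraction in \[0, 1\], or `NA` when no cluster is eligible.
#' @export
pcsmFrequency <- function(calls, nEligible = NULL) {
  if (is.null(nEligible)) nEligible <- sum(S4Vectors::mcols(calls)$eligible)
  if (nEligible == 0) return(undefinedValue())
  sum(S4Vectors::mcols(calls)$eligible &
        S4Vectors::mcols(calls)$isBipolar) / nEligible
}

#' Pearson correlation and clustering of pCSM profiles
#'
#' Profiles are binary bipolar-status vectors over a shared 4-CpG segment
#' universe; for every sample pair the correlation is computed on the
#' segments defined (eligible) in both samples. Samples are then
#' clustered by average-linkage on 1 - r. Zero-variance vectors give `NA`
#' for that pair.
#'
#' @param profiles named list (sample id -> data.frame with columns
#'   `key` (segment key) and `status` (logical)), e.g. built from
#'   [classifyBipolar()] output via [segmentKeys()].
#' @return list with `correlation` (matrix), `hclust`
#'   (a [stats::hclust] object, or NULL if any pairwise r is NA) and
#'   `order` (dendrogram leaf order as sample ids).
#' @export
profileCorrelation <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two profiles")
  ids <- sort(names(profiles))  # lexicographic: deterministic tie-break
  profiles <- profiles[ids]
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- profiles[[i]]; b <- profiles[[j]]
    shared <- intersect(a$key, b$key)
    if (length(shared) < 2)
      stop("fewer than 2 shared segments between ", ids[i], " and ", ids[j])
    x <- as.numeric(a$status[match(shared, a$key)])
    y <- as.numeric(b$status[match(shared, b$key)])
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) undefinedValue()
         else stats::cor(x, y)
    m[i, j] <- m[j, i] <- r
  }
  hc <- NULL; ord <- ids
  if (!anyNA(m)) {
    hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
    ord <- ids[hc$order]
  }
  list(correlation = m, hclust = hc, order = ord)
}

#' Build a pCSM profile from segment calls
#'
#' @param calls GRanges from [classifyBipolar()].
#' @return data.frame with `key` and `status` for eligible segments.
#' @export
csmProfile <- function(calls) {
  mc <- S4Vectors::mcols(calls)
  sel <- mc$eligible
  data.frame(
    key = paste0(as.character(GenomicRanges::seqnames(calls))[sel], ":",
                 mc$cpg1[sel], "-", mc$cpg4[sel]),
    status = mc$isBipolar[sel])
}
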