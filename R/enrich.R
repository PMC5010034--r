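# GWAS-variant enrichment in pCSM regions by circular permutation.

# Disjoint sorted 1-based intervals covering `regions` (matrix with
# columns start,end) padded by `pad` on a circular chromosome of length
# L; wrap-around arcs are split in two.
circularArcs <- function(starts, ends, L, pad) {
  s <- starts - pad; e <- ends + pad
  w <- pmin(e - s + 1, L)
  s0 <- ((s - 1) %% L)  # 0-based
  segs <- list()
  for (i in seq_along(s0)) {
    if (s0[i] + w[i] <= L) {
      segs[[length(segs) + 1L]] <- c(s0[i] + 1, s0[i] + w[i])
    } else {
      segs[[length(segs) + 1L]] <- c(s0[i] + 1, L)
      segs[[length(segs) + 1L]] <- c(1, s0[i] + w[i] - L)
    }
  }
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1]), , drop = FALSE]
  # union
  us <- ue <- numeric(0)
  for (i in seq_len(nrow(m))) {
    if (length(us) && m[i, 1] <= ue[length(ue)] + 1) {
      ue[length(ue)] <- max(ue[length(ue)], m[i, 2])
    } else { us <- c(us, m[i, 1]); ue <- c(ue, m[i, 2]) }
  }
  list(start = us, end = ue)
}

inArcs <- function(pos, arcs) {
  if (!length(arcs$start)) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, arcs$start)
  idx > 0 & pos <= arcs$end[pmax(idx, 1)]
}

countSnpsNearRegions <- function(snpByChrom, arcsByChrom, offsets,
                                 chromLengths) {
  tot <- 0L
  for (chr in names(snpByChrom)) {
    arcs <- arcsByChrom[[chr]]
    if (is.null(arcs)) next
    p <- snpByChrom[[chr]]
    off <- offsets[[chr]]
    if (off != 0) p <- ((p - 1 - off) %% chromLengths[[chr]]) + 1
    tot <- tot + sum(inArcs(p, arcs))
  }
  tot
}

#' GWAS SNP enrichment in pCSM regions (circular permutation)
#'
#' For each trait, counts the unique SNPs lying within `proximity` bp of
#' any pCSM region after a `extension` bp extension on both sides, then
#' builds a null distribution by shifting the regions along the
#' circularized genome (`nIter` iterations; one shared uniform offset per
#' chromosome per iteration by default, preserving region count, lengths
#' and intra-chromosome spacing). The p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + nIter).
#'
#' With `exhaustive = TRUE` (single-chromosome genomes only) every
#' possible shift 0..L-1 is enumerated instead of sampled, giving
#' p = (1 + #\{shift counts >= observed\}) / (1 + L).
#'
#' @param regions GRanges of pCSM regions.
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `trait`.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param nIter permutation iterations (default 10000).
#' @param extension region extension in bp (default 100).
#' @param proximity SNP distance from the extended region, inclusive
#'   (default 100).
#' @param seed RNG seed.
#' @param shiftMode `"joint"` (default; one offset per chromosome) or
#'   `"perRegion"`.
#' @param exhaustive enumerate all shifts instead of sampling.
#' @param sampleIdLabel sample id recorded on the result.
#' @return data.frame with one row per trait: `trait`, `nSnps`,
#'   `observed`, `p`, `nIter`, `sample_id`. Traits with zero SNPs are
#'   skipped with a warning.
#' @export
gwasEnrichment <- function(regions, snps, chromLengths, nIter = 10000,
                           extension = 100, proximity = 100, seed = 1,
                           shiftMode = c("joint", "perRegion"),
                           exhaustive = FALSE, sampleIdLabel = "sample") {
  shiftMode <- match.arg(shiftMode)
  chroms <- names(chromLengths)
  regChrom <- as.character(GenomicRanges::seqnames(regions))
  if (!all(regChrom %in% chroms)) stop("region chromosome missing from chromLengths")
  pad <- extension + proximity
  regByChrom <- split(seq_along(regions), factor(regChrom, levels = chroms))
  arcsByChrom <- lapply(chroms, function(chr) {
    idx <- regByChrom[[chr]]
    if (!length(idx)) return(NULL)
    circularArcs(GenomicRanges::start(regions)[idx],
                 GenomicRanges::end(regions)[idx], chromLengths[[chr]], pad)
  })
  names(arcsByChrom) <- chroms

  traits <- unique(snps$trait)
  out <- list()
  zero <- character(0)
  withSeed(seed, function() {
    for (tr in traits) {
      sub <- unique(snps[snps$trait == tr, c("chrom", "pos")])
      sub <- sub[sub$chrom %in% chroms, , drop = FALSE]
      if (!nrow(sub)) { zero <<- c(zero, tr); next }
      snpByChrom <- split(sub$pos, factor(sub$chrom, levels = chroms))
      snpByChrom <- snpByChrom[lengths(snpByChrom) > 0]
      zeroOff <- stats::setNames(as.list(rep(0, length(chroms))), chroms)
      obs <- countSnpsNearRegions(snpByChrom, arcsByChrom, zeroOff,
                                  chromLengths)
      if (exhaustive) {
        if (length(chroms) != 1)
          stop("exhaustive enumeration supports single-chromosome genomes only")
        L <- chromLengths[[1]]
        nullCounts <- vapply(0:(L - 1), function(d)
          countSnpsNearRegions(snpByChrom, arcsByChrom,
                               stats::setNames(list(d), chroms),
                               chromLengths), numeric(1))
        p <- (1 + sum(nullCounts >= obs)) / (1 + L)
        nEff <- L
      } else if (shiftMode == "joint") {
        nullCounts <- vapply(seq_len(nIter), function(it) {
          offs <- lapply(chroms, function(chr)
            floor(stats::runif(1) * chromLengths[[chr]]))
          names(offs) <- chroms
          countSnpsNearRegions(snpByChrom, arcsByChrom, offs, chromLengths)
        }, numeric(1))
        p <- (1 + sum(nullCounts >= obs)) / (1 + nIter)
        nEff <- nIter
      } else {
        nullCounts <- vapply(seq_len(nIter), function(it) {
          tot <- 0L
          for (chr in names(snpByChrom)) {
            idx <- regByChrom[[chr]]
            if (!length(idx)) next
            L <- chromLengths[[chr]]
            offs <- floor(stats::runif(length(idx)) * L)
            arcs <- circularArcs(
              ((GenomicRanges::start(regions)[idx] - 1 + offs) %% L) + 1,
              ((GenomicRanges::start(regions)[idx] - 1 + offs) %% L) + 1 +
                GenomicRanges::width(regions)[idx] - 1,
              L, pad)
            tot <- tot + sum(inArcs(snpByChrom[[chr]], arcs))
          }
          tot
        }, numeric(1))
        p <- (1 + sum(nullCounts >= obs)) / (1 + nIter)
        nEff <- nIter
      }
      out[[tr]] <<- data.frame(trait = tr, nSnps = nrow(sub),
                               observed = obs, p = p, nIter = nEff,
                               sample_id = sampleIdLabel)
    }
  })
  if (length(zero))
    warning("trait(s) with zero SNPs skipped: ", paste(zero, collapse = ", "))
  if (!length(out))
    return(data.frame(trait = character(0), nSnps = integer(0),
                      observed = integer(0), p = numeric(0),
                      nIter = integer(0), sample_id = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank diseases/traits by recurrent enrichment across samples
#'
#' Traits are ordered in descending order of the number of samples in
#' which their enrichment p-value is significant (p <= alpha, optionally
#' after Benjamini-Hochberg adjustment within each sample), ties broken
#' by ascending mean p.
#'
#' @param results data.frame from [gwasEnrichment()] (rows for several
#'   samples bound together; columns `trait`, `p`, `sample_id`).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame `trait`, `nSignificant`, `meanP`, sorted.
#' @export
rankTraits <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (adjust == "BH") {
    results$p_use <- stats::ave(results$p, results$sample_id,
                                FUN = function(p) stats::p.adjust(p, "BH"))
  } else results$p_use <- results$p
  agg <- do.call(rbind, lapply(split(results, results$trait), function(d)
    data.frame(trait = d$trait[1], nSignificant = sum(d$p_use <= alpha),
               meanP = mean(d$p))))
  agg <- agg[order(-agg$nSignificant, agg$meanP, agg$trait), ]
  rownames(agg) <- NULL
  agg
}
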