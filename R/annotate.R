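# Regulatory-element annotation, gene association, TSS aggregate
# profiles.

#' Promoter intervals (2 kb upstream of TSS), CGI-classified
#'
#' @param tss a stranded GRanges of TSS positions with a `name` metadata
#'   column (gene ids), or a BED path.
#' @param cgi GRanges of CpG islands (or BED path).
#' @param upstream promoter extent (default 2000).
#' @return GRanges of promoters with `name` and `cgiStatus` in
#'   \{"CGI", "nonCGI"\}.
#' @export
promoterSet <- function(tss, cgi, upstream = 2000) {
  if (is.character(tss)) tss <- readBed(tss)
  if (is.character(cgi)) cgi <- readBed(cgi)
  prom <- GenomicRanges::promoters(tss, upstream = upstream, downstream = 0)
  prom <- GenomicRanges::trim(prom)
  S4Vectors::mcols(prom)$cgiStatus <-
    ifelse(IRanges::overlapsAny(prom, cgi, ignore.strand = TRUE),
           "CGI", "nonCGI")
  prom
}

#' Classify regulatory elements from histone peaks
#'
#' Merges all H3K4me1/H3K4me3/H3K27ac peaks into merged-peak regions and
#' labels each by occupancy precedence: H3K4me3 present -> active
#' promoter (split by CGI overlap); else H3K27ac -> active enhancer;
#' else H3K4me1 -> poised enhancer.
#'
#' @param h3k4me1,h3k4me3,h3k27ac peak GRanges (or BED paths).
#' @param cgi CpG-island GRanges (or BED path).
#' @return GRanges of merged-peak regions with an `elementClass` column
#'   in \{active_promoter_CGI, active_promoter_nonCGI, active_enhancer,
#'   poised_enhancer\}.
#' @export
classifyElements <- function(h3k4me1, h3k4me3, h3k27ac, cgi) {
  asGr <- function(x) if (is.character(x)) readBed(x) else x
  h3k4me1 <- asGr(h3k4me1); h3k4me3 <- asGr(h3k4me3)
  h3k27ac <- asGr(h3k27ac); cgi <- asGr(cgi)
  merged <- GenomicRanges::reduce(
    c(GenomicRanges::granges(h3k4me1), GenomicRanges::granges(h3k4me3),
      GenomicRanges::granges(h3k27ac)), ignore.strand = TRUE)
  has1 <- IRanges::overlapsAny(merged, h3k4me1, ignore.strand = TRUE)
  has3 <- IRanges::overlapsAny(merged, h3k4me3, ignore.strand = TRUE)
  hasAc <- IRanges::overlapsAny(merged, h3k27ac, ignore.strand = TRUE)
  hasCgi <- IRanges::overlapsAny(merged, cgi, ignore.strand = TRUE)
  cls <- ifelse(has3, ifelse(hasCgi, "active_promoter_CGI",
                             "active_promoter_nonCGI"),
         ifelse(hasAc, "active_enhancer",
         ifelse(has1, "poised_enhancer", NA_character_)))
  S4Vectors::mcols(merged)$elementClass <- cls
  merged
}

#' Associate pCSM regions with genes
#'
#' Foreground: genes with at least one pCSM segment within `window` bp of
#' their TSS. Background: genes with at least one eligible 4-CpG segment
#' within the same window.
#'
#' @param regions GRanges of pCSM segments/regions.
#' @param tss stranded GRanges of TSSs with gene ids in `name` (or BED
#'   path).
#' @param eligible GRanges of all eligible 4-CpG segments.
#' @param window distance from the TSS (default 10000).
#' @return list with `foreground` and `background` character vectors of
#'   gene ids.
#' @export
associateGenes <- function(regions, tss, eligible, window = 10000) {
  if (is.character(tss)) tss <- readBed(tss)
  tssWin <- GenomicRanges::trim(GenomicRanges::resize(
    GenomicRanges::resize(tss, width = 1, fix = "start"),
    width = 2 * window + 1, fix = "center"))
  fg <- IRanges::overlapsAny(tssWin, regions, ignore.strand = TRUE)
  bg <- IRanges::overlapsAny(tssWin, eligible, ignore.strand = TRUE)
  list(foreground = unique(S4Vectors::mcols(tss)$name[fg]),
       background = unique(S4Vectors::mcols(tss)$name[bg]))
}

#' pCSM frequency profile around TSSs
#'
#' Bins the flank around each TSS (strand-aware; negative bins upstream)
#' and computes, per bin, the fraction of eligible 4-CpG segments whose
#' midpoint falls in the bin that are called bipolar. Bins without
#' eligible segments get `NA`.
#'
#' @param calls GRanges from [classifyBipolar()] (columns `eligible`,
#'   `isBipolar`).
#' @param tss stranded GRanges of TSSs (or BED path).
#' @param flank half-width of the profiled window (default 5000).
#' @param nBins number of bins across \[-flank, +flank\] (default 20).
#' @return data.frame bin, offsetMid (bp relative to TSS), nEligible,
#'   nBipolar, frequency.
#' @export
tssProfile <- function(calls, tss, flank = 5000, nBins = 20) {
  if (is.character(tss)) tss <- readBed(tss)
  mc <- S4Vectors::mcols(calls)
  calls <- calls[mc$eligible]
  bip <- mc$isBipolar[mc$eligible]
  mid <- (GenomicRanges::start(calls) + GenomicRanges::end(calls)) %/% 2L
  midGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(calls),
                                  IRanges::IRanges(mid, width = 1))
  tssPos <- GenomicRanges::start(GenomicRanges::resize(tss, 1, fix = "start"))
  win <- GenomicRanges::trim(GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(pmax(tssPos - flank, 1L), tssPos + flank)))
  hits <- GenomicRanges::findOverlaps(midGr, win, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  off <- mid[qi] - tssPos[si]
  neg <- as.character(GenomicRanges::strand(tss))[si] == "-"
  off[neg] <- -off[neg]
  binW <- 2 * flank / nBins
  bin <- pmin(pmax(ceiling((off + flank) / binW), 1L), nBins)
  out <- data.frame(
    bin = seq_len(nBins),
    offsetMid = -flank + (seq_len(nBins) - 0.5) * binW,
    nEligible = 0L, nBipolar = 0L, frequency = undefinedValue())
  for (b in seq_len(nBins)) {
    sel <- bin == b
    out$nEligible[b] <- sum(sel)
    out$nBipolar[b] <- sum(bip[qi][sel])
    if (out$nEligible[b] > 0)
      out$frequency[b] <- out$nBipolar[b] / out$nEligible[b]
  }
  out
}
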