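#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @useDynLib bipolarMeth, .registration = TRUE
NULL

#' CpGMap: reference CpG coordinates per chromosome
#'
#' Holds, for each chromosome, the sorted 1-based coordinates of the C of
#' every CG dinucleotide on the forward strand, together with the
#' chromosome lengths. All per-read CpG calls and 4-CpG segments are
#' expressed against these coordinates; calls on reverse-strand reads are
#' projected onto the forward C of the same dyad.
#'
#' @slot positions named list, one sorted integer vector per chromosome.
#' @slot lengths named integer vector of chromosome lengths.
#' @export
setClass("CpGMap",
  representation(positions = "list", lengths = "integer"))

setValidity("CpGMap", function(object) {
  msg <- NULL
  if (is.null(names(object@positions)) ||
      !identical(sort(names(object@positions)), sort(names(object@lengths))))
    msg <- c(msg, "positions and lengths must share chromosome names")
  for (chr in names(object@positions)) {
    p <- object@positions[[chr]]
    if (!is.integer(p)) msg <- c(msg, sprintf("positions for %s not integer", chr))
    if (is.unsorted(p, strictly = TRUE)) msg <- c(msg, sprintf("positions for %s not strictly increasing", chr))
    if (length(p) && (p[1] < 1L || p[length(p)] + 1L > object@lengths[[chr]]))
      msg <- c(msg, sprintf("positions for %s outside [1, length-1]", chr))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CpGMap
#'
#' @param positions named list of sorted 1-based integer coordinates of the
#'   C of each forward-strand CG dinucleotide.
#' @param lengths named integer vector of chromosome lengths.
#' @return A [CpGMap-class] object.
#' @export
CpGMap <- function(positions, lengths) {
  positions <- lapply(positions, function(p) as.integer(p))
  new("CpGMap", positions = positions,
      lengths = vapply(lengths, as.integer, integer(1))[names(positions)])
}

#' @describeIn CpGMap-class chromosome names
#' @param x a CpGMap
#' @export
chromNames <- function(x) names(x@positions)

#' @describeIn CpGMap-class chromosome lengths
#' @export
chromLengths <- function(x) x@lengths

#' @describeIn CpGMap-class CpG coordinates for one chromosome (or all,
#'   as a list, when `chrom` is missing)
#' @param chrom chromosome name
#' @export
cpgPositions <- function(x, chrom) {
  if (missing(chrom)) return(x@positions)
  if (!chrom %in% names(x@positions)) return(integer(0))
  x@positions[[chrom]]
}

setMethod("show", "CpGMap", function(object) {
  n <- sum(lengths(object@positions))
  cat("CpGMap with", n, "CpG sites on", length(object@positions),
      "chromosome(s)\n")
  for (chr in utils::head(names(object@positions), 5))
    cat(sprintf("  %s: %d CpGs / %d bp\n", chr,
                length(object@positions[[chr]]), object@lengths[[chr]]))
  if (length(object@positions) > 5) cat("  ...\n")
})

#' PatternClusterSet: 4-CpG segments with per-read methylation patterns
#'
#' The central container of the pCSM workflow. Each element is one 4-CpG
#' segment (four consecutive CpGs of the reference CpG map) together with
#' the multiset of 4-character methylation patterns (over \{M, U\})
#' observed on reads that cover all four CpGs with unambiguous calls.
#'
#' @slot segments a [GenomicRanges::GRanges] spanning first CpG C to last
#'   CpG G, with integer metadata columns `cpg1`..`cpg4` (the four CpG C
#'   coordinates).
#' @slot counts list of named integer vectors; names are 4-character
#'   patterns over M/U, values are read counts.
#' @slot sampleId single sample identifier.
#' @export
setClass("PatternClusterSet",
  representation(segments = "GRanges", counts = "list",
                 sampleId = "character"))

setValidity("PatternClusterSet", function(object) {
  msg <- NULL
  if (length(object@segments) != length(object@counts))
    msg <- c(msg, "segments and counts lengths differ")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  need <- c("cpg1", "cpg2", "cpg3", "cpg4")
  if (!all(need %in% colnames(S4Vectors::mcols(object@segments))))
    msg <- c(msg, "segments must carry cpg1..cpg4 metadata columns")
  bad <- vapply(object@counts, function(cc) {
    !is.integer(cc) || any(cc < 1L) || is.null(names(cc)) ||
      any(nchar(names(cc)) != 4L) || any(grepl("[^MU]", names(cc)))
  }, logical(1))
  if (any(bad))
    msg <- c(msg, "counts must be named positive integer vectors with 4-char M/U names")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PatternClusterSet
#'
#' @param segments GRanges with metadata columns `cpg1`..`cpg4`.
#' @param counts list of named integer pattern-count vectors, parallel to
#'   `segments`.
#' @param sampleId sample identifier.
#' @return A [PatternClusterSet-class].
#' @export
PatternClusterSet <- function(segments, counts, sampleId = "sample") {
  counts <- lapply(counts, function(cc) {
    cc <- vapply(cc, as.integer, integer(1))
    cc[order(names(cc))]
  })
  new("PatternClusterSet", segments = segments, counts = counts,
      sampleId = sampleId)
}

#' @describeIn PatternClusterSet-class segment ranges
#' @param x a PatternClusterSet
#' @export
clusterSegments <- function(x) x@segments

#' @describeIn PatternClusterSet-class pattern-count vectors
#' @export
patternCounts <- function(x) x@counts

#' @describeIn PatternClusterSet-class total read depth per segment
#' @export
clusterDepths <- function(x) vapply(x@counts, sum, numeric(1))

#' @describeIn PatternClusterSet-class sample identifier
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn PatternClusterSet-class number of clusters
#' @export
setMethod("length", "PatternClusterSet", function(x) length(x@counts))

#' @describeIn PatternClusterSet-class subset clusters
#' @param i index
#' @param j,drop,... unused
#' @export
setMethod("[", "PatternClusterSet", function(x, i, j, ..., drop = FALSE) {
  new("PatternClusterSet", segments = x@segments[i], counts = x@counts[i],
      sampleId = x@sampleId)
})

setMethod("show", "PatternClusterSet", function(object) {
  d <- clusterDepths(object)
  cat(sprintf("PatternClusterSet '%s': %d 4-CpG segment cluster(s)\n",
              object@sampleId, length(object)))
  if (length(object))
    cat(sprintf("  depth: min %d, median %d, max %d\n",
                as.integer(min(d)), as.integer(stats::median(d)),
                as.integer(max(d))))
})

#' Segment identifier strings ("chrom:cpg1-cpg4")
#'
#' Used to match segments across samples (shared segment universe).
#' @param x a PatternClusterSet
#' @return character vector of keys.
#' @export
segmentKeys <- function(x) {
  mc <- S4Vectors::mcols(x@segments)
  paste0(as.character(GenomicRanges::seqnames(x@segments)), ":",
         mc$cpg1, "-", mc$cpg4)
}
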