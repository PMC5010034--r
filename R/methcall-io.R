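#' Build a CpG coordinate map from a reference
#'
#' Scans the forward strand of each reference sequence for CG
#' dinucleotides and records the coordinate of the C (1-based).
#'
#' @param reference a path to a FASTA file or a
#'   [Biostrings::DNAStringSet].
#' @return a [CpGMap-class].
#' @examples
#' buildCpGMap(Biostrings::DNAStringSet(c(chr1 = "ACGTCGG")))
#' @export
buildCpGMap <- function(reference) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (is.null(names(reference)))
    stop("reference sequences must be named")
  names(reference) <- sub("\\s.*$", "", names(reference))
  pos <- lapply(seq_along(reference), function(i) {
    Biostrings::start(Biostrings::matchPattern("CG", reference[[i]]))
  })
  names(pos) <- names(reference)
  CpGMap(pos, stats::setNames(Biostrings::width(reference), names(reference)))
}

emptyReadCalls <- function() {
  data.frame(read_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             cg_pos = I(list()), cg_state = I(list()),
             ch_pos = I(list()), ch_state = I(list()))
}

makeReadCalls <- function(read_id, chrom, start, end, strand,
                          cg_pos, cg_state, ch_pos = NULL, ch_state = NULL) {
  n <- length(read_id)
  if (is.null(ch_pos)) ch_pos <- rep(list(integer(0)), n)
  if (is.null(ch_state)) ch_state <- rep(list(character(0)), n)
  data.frame(read_id = read_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             cg_pos = I(cg_pos), cg_state = I(cg_state),
             ch_pos = I(ch_pos), ch_state = I(ch_state))
}

parseCallString <- function(s) {
  if (is.na(s) || !nzchar(s) || s == ".")
    return(list(pos = integer(0), state = character(0)))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  pos <- as.integer(vapply(parts, `[`, "", 1L))
  st <- vapply(parts, `[`, "", 2L)
  keep <- st %in% c("M", "U")
  o <- order(pos[keep])
  list(pos = pos[keep][o], state = st[keep][o])
}

#' Parse per-read methylation calls
#'
#' Reads per-read CpG (and optional CH-context) methylation calls either
#' from a plain TSV or from a SAM/BAM file carrying Bismark-style `XM`
#' call strings. Ambiguous calls (anything other than M/U, or Bismark
#' codes other than `z`/`Z` in CpG context) are dropped at parse time.
#' CpG calls from reverse-strand alignments are projected onto the
#' forward-strand C of the dyad.
#'
#' The TSV format has columns `read_id, chrom, start, end, strand,
#' cg_calls[, ch_calls]` where call columns are comma-separated
#' `pos:state` with `state` in \{M, U\} and `pos` the 1-based
#' forward-strand C coordinate (`.` for none).
#'
#' @param path path to a `.tsv`, `.sam` or `.bam` file.
#' @param cpgMap a [CpGMap-class]; calls at positions absent from the map
#'   are dropped.
#' @return a read-calls data.frame (one row per read; list columns
#'   `cg_pos`, `cg_state`, `ch_pos`, `ch_state`).
#' @export
parseReadCalls <- function(path, cpgMap) {
  ext <- tolower(tools::file_ext(path))
  reads <- switch(ext,
    tsv = , txt = parseReadCallsTsv(path),
    sam = , bam = parseReadCallsSam(path, cpgMap),
    stop("unsupported read-call file type: ", ext))
  restrictToMap(reads, cpgMap)
}

parseReadCallsTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("read_id", "chrom", "start", "strand", "cg_calls")
  if (!all(need %in% names(df)))
    stop("read-call TSV must have columns ", paste(need, collapse = ", "))
  cg <- lapply(df$cg_calls, parseCallString)
  ch <- if ("ch_calls" %in% names(df)) lapply(df$ch_calls, parseCallString)
        else rep(list(list(pos = integer(0), state = character(0))), nrow(df))
  end <- if ("end" %in% names(df)) df$end else {
    vapply(seq_len(nrow(df)), function(i) {
      p <- cg[[i]]$pos
      if (length(p)) max(p) + 1L else df$start[i]
    }, integer(1))
  }
  makeReadCalls(df$read_id, df$chrom, df$start, end, df$strand,
                lapply(cg, `[[`, "pos"), lapply(cg, `[[`, "state"),
                lapply(ch, `[[`, "pos"), lapply(ch, `[[`, "state"))
}

# Decode one Bismark XM string against reference positions. `refpos` maps
# each read base to its reference coordinate (NA for insertions/clips).
decodeXm <- function(xm, refpos, reverse, cpgpos) {
  codes <- strsplit(xm, "")[[1]]
  cg <- codes %in% c("z", "Z")
  ch <- codes %in% c("x", "X", "h", "H")
  cg_pos <- refpos[cg]
  # reverse-strand informative C sits on the G of CG: project to C = pos-1
  if (reverse) cg_pos <- cg_pos - 1L
  cg_state <- ifelse(codes[cg] == "Z", "M", "U")
  ch_pos <- refpos[ch]
  ch_state <- ifelse(codes[ch] %in% c("X", "H"), "M", "U")
  ok <- !is.na(cg_pos) & cg_pos %in% cpgpos
  o <- order(cg_pos[ok])
  ok2 <- !is.na(ch_pos)
  o2 <- order(ch_pos[ok2])
  list(cg_pos = cg_pos[ok][o], cg_state = cg_state[ok][o],
       ch_pos = ch_pos[ok2][o2], ch_state = ch_state[ok2][o2])
}

# Reference coordinate of each read base, from POS and CIGAR.
cigarRefPos <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("\\d+", "", ops)
  out <- integer(0)
  ref <- pos
  for (i in seq_along(op)) {
    switch(op[i],
      M = , `=` = , X = { out <- c(out, ref:(ref + n[i] - 1L)); ref <- ref + n[i] },
      I = , S = { out <- c(out, rep(NA_integer_, n[i])) },
      D = , N = { ref <- ref + n[i] },
      H = , P = NULL)
  }
  out
}

parseReadCallsSam <- function(path, cpgMap) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to parse SAM/BAM input")
  if (tolower(tools::file_ext(path)) == "sam")
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"), tag = "XM")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  xm <- b$tag$XM
  if (is.null(xm) || all(is.na(xm)))
    stop("unsupported records: no XM methylation-call tag present")
  keep <- !is.na(b$pos) & !is.na(xm)
  if (!any(keep)) return(emptyReadCalls())
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    chrom <- as.character(b$rname[i])
    rev <- bitwAnd(b$flag[i], 16L) > 0L
    refpos <- cigarRefPos(b$pos[i], b$cigar[i])
    dec <- decodeXm(xm[i], refpos, rev, cpgPositions(cpgMap, chrom))
    rp <- refpos[!is.na(refpos)]
    makeReadCalls(b$qname[i], chrom, min(rp), max(rp) + 1L,
                  if (rev) "-" else "+",
                  list(dec$cg_pos), list(dec$cg_state),
                  list(dec$ch_pos), list(dec$ch_state))
  })
  do.call(rbind, rows)
}

restrictToMap <- function(reads, cpgMap) {
  for (i in seq_len(nrow(reads))) {
    keep <- reads$cg_pos[[i]] %in% cpgPositions(cpgMap, reads$chrom[i])
    reads$cg_pos[[i]] <- reads$cg_pos[[i]][keep]
    reads$cg_state[[i]] <- reads$cg_state[[i]][keep]
  }
  reads
}

#' Remove PCR duplicates
#'
#' Retains the first read encountered for every duplicate key. The
#' default key is (chrom, start, strand, aligned length), configurable
#' since duplicate definitions vary between protocols.
#'
#' @param reads read-calls data.frame.
#' @param key character vector of key components among
#'   `"chrom","start","strand","length"`.
#' @return the deduplicated data.frame (input order preserved).
#' @export
dedupReads <- function(reads, key = c("chrom", "start", "strand", "length")) {
  if (!nrow(reads)) return(reads)
  parts <- list(chrom = reads$chrom, start = reads$start,
                strand = reads$strand, length = reads$end - reads$start)
  k <- do.call(paste, c(parts[key], sep = "\r"))
  reads[!duplicated(k), , drop = FALSE]
}

#' Extract 4-CpG segment pattern clusters
#'
#' Progressively scans each read: every run of four consecutive CpG-map
#' CpGs fully covered by the read with unambiguous calls contributes one
#' 4-character M/U pattern to that segment's cluster. Clusters are keyed
#' by the four CpG coordinates. A read with an ambiguous or missing call
#' inside a window is excluded from that window only.
#'
#' @param reads deduplicated read-calls data.frame.
#' @param cpgMap a [CpGMap-class].
#' @param sampleId sample identifier stored on the result.
#' @return a [PatternClusterSet-class].
#' @export
extractSegments <- function(reads, cpgMap, sampleId = "sample") {
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reads))) {
    chrom <- reads$chrom[i]
    mappos <- cpgPositions(cpgMap, chrom)
    pos <- reads$cg_pos[[i]]
    st <- reads$cg_state[[i]]
    ok <- st %in% c("M", "U")
    pos <- pos[ok]; st <- st[ok]
    if (length(pos) < 4L) next
    idx <- match(pos, mappos)
    valid <- !is.na(idx)
    pos <- pos[valid]; st <- st[valid]; idx <- idx[valid]
    if (length(idx) < 4L) next
    for (j in seq_len(length(idx) - 3L)) {
      if (idx[j + 3L] - idx[j] != 3L) next  # CpGs must be consecutive in map
      key <- paste0(chrom, "\r", idx[j])
      pat <- paste(st[j:(j + 3L)], collapse = "")
      cur <- acc[[key]]
      if (is.null(cur)) cur <- integer(0)
      cur[pat] <- if (pat %in% names(cur)) cur[[pat]] + 1L else 1L
      acc[[key]] <- cur
    }
  }
  keys <- ls(acc)
  if (!length(keys)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      cpg1 = integer(0), cpg2 = integer(0), cpg3 = integer(0),
      cpg4 = integer(0))
    return(PatternClusterSet(gr, list(), sampleId))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  i1 <- as.integer(vapply(parts, `[`, "", 2L))
  cp <- t(vapply(seq_along(keys), function(k) {
    cpgPositions(cpgMap, chrom[k])[i1[k]:(i1[k] + 3L)]
  }, integer(4)))
  o <- order(chrom, cp[, 1])
  gr <- GenomicRanges::GRanges(chrom[o],
          IRanges::IRanges(start = cp[o, 1], end = cp[o, 4] + 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cpg1 = cp[o, 1], cpg2 = cp[o, 2], cpg3 = cp[o, 3], cpg4 = cp[o, 4])
  PatternClusterSet(gr, lapply(keys[o], function(k) acc[[k]]), sampleId)
}

#' Per-segment mCG and mCH levels
#'
#' mCG level is the fraction of methylated CpG calls among all CpG calls
#' inside the segment span (from the stored patterns). mCH level is
#' computed analogously from the per-read CH-context calls, which must be
#' supplied via `reads`. Segments without any call of the requested
#' context get `NA`, never 0.
#'
#' @param clusters a [PatternClusterSet-class].
#' @param reads optional read-calls data.frame providing CH-context calls.
#' @return data.frame with columns `mcg_level`, `mch_level`.
#' @export
segmentMethLevels <- function(clusters, reads = NULL) {
  segs <- clusterSegments(clusters)
  mcg <- vapply(patternCounts(clusters), function(cc) {
    tot <- 4 * sum(cc)
    if (tot == 0) return(undefinedValue())
    m <- sum(vapply(names(cc), function(p)
      lengths(regmatches(p, gregexpr("M", p))), integer(1)) * cc)
    m / tot
  }, numeric(1))
  mch <- rep(undefinedValue(), length(clusters))
  if (!is.null(reads) && nrow(reads)) {
    chp <- unlist(reads$ch_pos, use.names = FALSE)
    chs <- unlist(reads$ch_state, use.names = FALSE)
    chc <- rep(reads$chrom, lengths(reads$ch_pos))
    if (length(chp)) {
      for (i in seq_along(mch)) {
        sel <- chc == as.character(GenomicRanges::seqnames(segs))[i] &
          chp >= GenomicRanges::start(segs)[i] &
          chp <= GenomicRanges::end(segs)[i]
        if (any(sel)) mch[i] <- mean(chs[sel] == "M")
      }
    }
  }
  data.frame(mcg_level = mcg, mch_level = mch)
}

#' Write / read a pattern-cluster TSV
#'
#' Columns: chrom, start (0-based), end, cpg_positions (comma-separated
#' 1-based C coordinates), patterns (`pattern:count` comma-separated),
#' depth.
#'
#' @param clusters a [PatternClusterSet-class].
#' @param path output path.
#' @return `writeClusters` returns `path` invisibly; `readClusters`
#'   returns a [PatternClusterSet-class].
#' @export
writeClusters <- function(clusters, path) {
  segs <- clusterSegments(clusters)
  mc <- S4Vectors::mcols(segs)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(segs)),
    start = GenomicRanges::start(segs) - 1L,
    end = GenomicRanges::end(segs),
    cpg_positions = paste(mc$cpg1, mc$cpg2, mc$cpg3, mc$cpg4, sep = ","),
    patterns = vapply(patternCounts(clusters), function(cc)
      paste(names(cc), cc, sep = ":", collapse = ","), character(1)),
    depth = as.integer(clusterDepths(clusters)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusters
#' @param sampleId sample identifier for the read object.
#' @export
readClusters <- function(path, sampleId = "sample") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  cp <- t(vapply(strsplit(df$cpg_positions, ",", fixed = TRUE),
                 function(v) as.integer(v), integer(4)))
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(start = df$start + 1L, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cpg1 = cp[, 1], cpg2 = cp[, 2], cpg3 = cp[, 3], cpg4 = cp[, 4])
  counts <- lapply(df$patterns, function(s) {
    kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                    vapply(kv, `[`, "", 1L))
  })
  PatternClusterSet(gr, counts, sampleId)
}
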