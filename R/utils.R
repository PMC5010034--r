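# Internal helpers: seed derivation, BED IO thin wrappers.

# Deterministic 31-bit seed derived from a master seed and a string key.
# Per-(segment, sample) streams make results independent of processing
# order and of which other samples are present.
deriveSeed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483629
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  # extra LCG avalanche rounds so near-identical keys give unrelated seeds
  for (i in 1:3) h <- (h * 69069 + 1234567) %% 2147483629
  as.integer(h + 1)
}

# Run fn() under a derived, isolated RNG state.
withSeed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  fn()
}

#' Read a BED file as GRanges
#'
#' Minimal BED3/BED6 reader (0-based half-open converted to 1-based
#' closed). Column 4 becomes `name`, column 5 `score`, column 6 strand.
#'
#' @param path path to a BED file.
#' @return a [GenomicRanges::GRanges].
#' @export
readBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("malformed BED: fewer than 3 columns in ", path)
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]]))
    stop("malformed BED: non-numeric coordinates in ", path)
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    strand = if (ncol(df) >= 6) sub("^\\.$", "*", df[[6]]) else "*")
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- df[[4]]
  if (ncol(df) >= 5) S4Vectors::mcols(gr)$score <- df[[5]]
  gr
}

#' Write GRanges as BED
#'
#' @param gr a GRanges; a `name` metadata column is used for BED column 4.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeBed <- function(gr, path) {
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    score = 0L,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# undefined-value sentinel used across the package (documented: NA_real_,
# never silently 0)
undefinedValue <- function() NA_real_
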