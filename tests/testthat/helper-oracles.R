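# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# quadratic Needleman-Wunsch DP, linear gap penalty, bisulfite-compatible
# columns (C/T, G/A) scoring as matches; returns the optimal score
nwOracleScore <- function(s1, s2, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  compat <- function(x, y) {
    x == y || (x == "C" && y == "T") || (x == "T" && y == "C") ||
      (x == "G" && y == "A") || (x == "A" && y == "G")
  }
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (compat(a[i], b[j])) match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap, D[i + 1, j] + gap)
  }
  D[n + 1, m + 1]
}

# exact P(subsample of size t keeps >=1 of pattern A and >=1 of pattern B)
hyperPrefilterProb <- function(a, b, n, t) {
  pNoA <- if (n - a >= t) choose(n - a, t) / choose(n, t) else 0
  pNoB <- if (n - b >= t) choose(n - b, t) / choose(n, t) else 0
  pNoAB <- if (n - a - b >= t) choose(n - a - b, t) / choose(n, t) else 0
  min(max(1 - pNoA - pNoB + pNoAB, 0), 1)  # clamp away -1e-17 cancellation
}

# transitive-closure merging of integer spans (matrix cols start, end;
# closed coordinates), brute force by repeated pairwise merging
bruteMergeSpans <- function(chrom, start, end) {
  df <- data.frame(chrom = chrom, start = start, end = end)
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        if (df$chrom[i] == df$chrom[j] &&
            df$start[i] <= df$end[j] && df$start[j] <= df$end[i]) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

# brute-force >=1 bp overlap of each query span with any subject span
bruteOverlapsAny <- function(qc, qs, qe, sc, ss, se) {
  vapply(seq_along(qc), function(i)
    any(sc == qc[i] & ss <= qe[i] & se >= qs[i]), logical(1))
}

# regulatory-element truth table from the three stated rules
elementClassOracle <- function(k4me1, k4me3, k27ac, cgi) {
  if (k4me3) { if (cgi) "active_promoter_CGI" else "active_promoter_nonCGI" }
  else if (k27ac) "active_enhancer"
  else if (k4me1) "poised_enhancer"
  else NA_character_
}

# build a PatternClusterSet from a list of pattern-count vectors on a
# synthetic chromosome (segments 100 bp apart, CpGs 10 bp apart)
makeClusterSet <- function(countsList, chrom = "chrT", sampleId = "test") {
  n <- length(countsList)
  cpg1 <- 100L * seq_len(n)
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = cpg1, end = cpg1 + 31L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cpg1 = cpg1, cpg2 = cpg1 + 10L, cpg3 = cpg1 + 20L, cpg4 = cpg1 + 30L)
  PatternClusterSet(gr, countsList, sampleId)
}

# circular-permutation enrichment p by naive exhaustive enumeration
enrichExhaustiveOracle <- function(regStart, regEnd, snpPos, L,
                                   extension = 100, proximity = 100) {
  pad <- extension + proximity
  near <- function(shift) {
    s <- ((regStart - 1 + shift) %% L) + 1
    cnt <- 0L
    for (p in snpPos) {
      hit <- FALSE
      for (r in seq_along(regStart)) {
        lo <- s[r] - pad
        hi <- s[r] + (regEnd[r] - regStart[r]) + pad
        # circular distance check
        pp <- c(p, p + L, p - L)
        if (any(pp >= lo & pp <= hi)) { hit <- TRUE; break }
      }
      if (hit) cnt <- cnt + 1L
    }
    cnt
  }
  obs <- near(0)
  nulls <- vapply(0:(L - 1), near, integer(1))
  (1 + sum(nulls >= obs)) / (1 + L)
}
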