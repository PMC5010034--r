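# Synthetic-data generators emulating mixed-cell-subset bisulfite
# methylomes and hairpin bisulfite libraries. Defaults encode the study
# conditions used throughout the test suite.

# random sequence of length L with CpGs planted at per-position density
# `density` and no accidental CG elsewhere
simChromSequence <- function(L, density) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cpg <- integer(0)
  if (density > 0) {
    cand <- which(stats::runif(L - 1) < density)
    if (length(cand)) {  # enforce >= 2 bp spacing, greedy
      keep <- cand[1]
      for (p in cand[-1]) if (p - keep[length(keep)] >= 2L) keep <- c(keep, p)
      cpg <- keep
      base[cpg] <- "C"; base[cpg + 1L] <- "G"
    }
  }
  acc <- which(base[-L] == "C" & base[-1] == "G")
  acc <- setdiff(acc, cpg)
  if (length(acc)) base[acc + 1L] <- "A"  # break accidental CGs
  list(seq = paste(base, collapse = ""), cpg = cpg)
}

randomIntervals <- function(n, L, width, chrom, minGap = 1L) {
  if (n == 0)
    return(GenomicRanges::GRanges())
  starts <- sort(sample.int(max(L - width - 1L, 1L), n))
  # push apart to keep disjoint
  for (i in seq_len(n)[-1])
    if (starts[i] <= starts[i - 1] + width + minGap)
      starts[i] <- starts[i - 1] + width + minGap
  ok <- starts + width <= L
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = starts[ok], width = width))
}

#' Simulate a reference genome with annotation tracks
#'
#' Generates per-chromosome random sequence with CpG dinucleotides
#' planted at the requested density (and nowhere else), plus TSS, CpG
#' island, histone-peak and imprinted-region tracks with the geometry
#' the annotation modules expect (half of the CGIs are placed over
#' promoters so both CGI and non-CGI promoters exist; peaks partially
#' overlap so merged-peak regions exercise every occupancy combination).
#'
#' @param chromLengths named integer vector.
#' @param cpgDensity per-position CpG probability (default 0.02).
#' @param nTss,nCgi,nPeaks,nImprinted track sizes per chromosome.
#' @param seed RNG seed (mandatory).
#' @return list with `sequences` ([Biostrings::DNAStringSet]), `cpgMap`,
#'   `tss`, `cgi`, `peaks` (list H3K4me1/H3K4me3/H3K27ac), `imprinted`.
#' @export
simulateGenome <- function(chromLengths = c(chr1 = 100000L),
                           cpgDensity = 0.02, nTss = 20, nCgi = 10,
                           nPeaks = 15, nImprinted = 2, seed = 1) {
  withSeed(seed, function() {
    seqs <- character(0); cpg <- list()
    tss <- cgi <- imp <- GenomicRanges::GRanges()
    pk <- list(H3K4me1 = GenomicRanges::GRanges(),
               H3K4me3 = GenomicRanges::GRanges(),
               H3K27ac = GenomicRanges::GRanges())
    for (chr in names(chromLengths)) {
      L <- chromLengths[[chr]]
      s <- simChromSequence(L, cpgDensity)
      seqs[chr] <- s$seq
      cpg[[chr]] <- s$cpg
      if (nTss > 0) {
        pos <- sort(sample(seq(3000L, max(L - 3000L, 3001L)), nTss))
        str <- sample(c("+", "-"), nTss, replace = TRUE)
        g <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, width = 1),
                                    strand = str)
        S4Vectors::mcols(g)$name <- paste0(chr, "_gene", seq_len(nTss))
        tss <- c(tss, g)
        # half the CGIs on promoters, half elsewhere
        nProm <- min(nCgi %/% 2, nTss)
        cg1 <- GenomicRanges::GRanges(chr, IRanges::IRanges(
          pmax(pos[seq_len(nProm)] - 500L, 1L), width = 1000L))
        cg2 <- randomIntervals(nCgi - nProm, L, 800L, chr)
        cgi <- c(cgi, GenomicRanges::trim(c(cg1, cg2)))
      }
      for (mark in names(pk))
        pk[[mark]] <- c(pk[[mark]], randomIntervals(nPeaks, L, 1200L, chr))
      imp <- c(imp, randomIntervals(nImprinted, L, 2000L, chr))
    }
    list(sequences = Biostrings::DNAStringSet(seqs),
         cpgMap = CpGMap(cpg, chromLengths),
         tss = tss, cgi = cgi, peaks = pk, imprinted = imp)
  })
}

#' Simulate bulk bisulfite reads from a mixture of cell subsets
#'
#' Each read is one molecule drawn from a cell subset according to the
#' mixing proportions; its CpG states are Bernoulli draws from that
#' subset's per-CpG methylation probability. CSM segments (runs of four
#' consecutive CpGs) get probability `pHi` in one subset and `pLo` in the
#' others; the remaining CpGs share a bimodal baseline across subsets.
#' Conversion failures flip U to M at the configured rate; duplicates
#' (identical chrom/start/strand/length and calls) are injected at the
#' duplicate rate. CH-context calls are emitted at non-CpG cytosines
#' with methylation probability `mchRate`.
#'
#' @param genome result of [simulateGenome()].
#' @param mixing subset mixing proportions (simplex).
#' @param csmFraction fraction of candidate disjoint 4-CpG segments that
#'   are CSM.
#' @param pHi,pLo per-CpG methylation probabilities of the discordant
#'   subsets at CSM segments (defaults 0.95 / 0.05).
#' @param baselineHigh,baselineLow,fracHigh bimodal baseline: a CpG is
#'   "high" (prob `baselineHigh`) with probability `fracHigh`, else
#'   "low".
#' @param readLength,depth read geometry.
#' @param conversionFailure U->M flip rate (default 0.003).
#' @param duplicateRate fraction of duplicate reads injected.
#' @param mchRate CH methylation probability (default 0.02).
#' @param seed RNG seed.
#' @return list with `reads` (read-calls data.frame), `truth`
#'   (data.frame chrom, cpg1..cpg4, csm, one row per candidate disjoint
#'   segment), `readSubset` (subset index per original read),
#'   `nDuplicates`.
#' @export
simulateBulkReads <- function(genome, mixing = c(0.5, 0.5),
                              csmFraction = 0.05, pHi = 0.95, pLo = 0.05,
                              baselineHigh = 0.9, baselineLow = 0.1,
                              fracHigh = 0.8, readLength = 100, depth = 20,
                              conversionFailure = 0.003, duplicateRate = 0,
                              mchRate = 0.02, seed = 1) {
  stopifnot(abs(sum(mixing) - 1) < 1e-9)
  nSub <- length(mixing)
  withSeed(seed, function() {
    map <- genome$cpgMap
    truth <- list(); reads <- list(); subsets <- list()
    for (chr in chromNames(map)) {
      pos <- cpgPositions(map, chr)
      L <- chromLengths(map)[[chr]]
      nCpg <- length(pos)
      # per-CpG, per-subset probabilities
      base <- ifelse(stats::runif(nCpg) < fracHigh, baselineHigh, baselineLow)
      p <- matrix(base, nCpg, nSub)
      segStarts <- seq(1L, nCpg - 3L, by = 4L)  # disjoint candidates
      csm <- stats::runif(length(segStarts)) < csmFraction
      hiSub <- sample.int(nSub, length(segStarts), replace = TRUE)
      for (si in which(csm)) {
        idx <- segStarts[si]:(segStarts[si] + 3L)
        p[idx, ] <- pLo
        p[idx, hiSub[si]] <- pHi
      }
      truth[[chr]] <- data.frame(
        chrom = chr, cpg1 = pos[segStarts], cpg2 = pos[segStarts + 1L],
        cpg3 = pos[segStarts + 2L], cpg4 = pos[segStarts + 3L], csm = csm)
      # non-CpG cytosines for CH calls
      bases <- strsplit(as.character(genome$sequences[[chr]]), "")[[1]]
      chPos <- setdiff(which(bases == "C"), pos)
      nReads <- round(depth * L / readLength)
      starts <- sample.int(L - readLength + 1L, nReads, replace = TRUE)
      strands <- sample(c("+", "-"), nReads, replace = TRUE)
      sub <- sample.int(nSub, nReads, replace = TRUE, prob = mixing)
      rows <- vector("list", nReads)
      for (i in seq_len(nReads)) {
        lo <- starts[i]; hi <- starts[i] + readLength - 1L
        cov <- pos[pos >= lo & pos + 1L <= hi]
        st <- character(0)
        if (length(cov)) {
          pr <- p[match(cov, pos), sub[i]]
          meth <- stats::runif(length(cov)) < pr
          flip <- !meth & stats::runif(length(cov)) < conversionFailure
          st <- ifelse(meth | flip, "M", "U")
        }
        covCh <- chPos[chPos >= lo & chPos <= hi]
        chSt <- character(0)
        if (length(covCh)) {
          mCh <- stats::runif(length(covCh)) < mchRate
          flipCh <- !mCh & stats::runif(length(covCh)) < conversionFailure
          chSt <- ifelse(mCh | flipCh, "M", "U")
        }
        rows[[i]] <- makeReadCalls(
          sprintf("%s_read%06d", chr, i), chr, lo, hi + 1L, strands[i],
          list(cov), list(st), list(covCh), list(chSt))
      }
      reads[[chr]] <- do.call(rbind, rows)
      subsets[[chr]] <- sub
    }
    reads <- do.call(rbind, reads)
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    nDup <- round(duplicateRate * nrow(reads))
    if (nDup > 0) {
      src <- sample.int(nrow(reads), nDup, replace = FALSE)
      dup <- reads[src, , drop = FALSE]
      dup$read_id <- paste0(dup$read_id, "_dup")
      reads <- rbind(reads, dup)
    }
    list(reads = reads, truth = truth,
         readSubset = unlist(subsets, use.names = FALSE), nDuplicates = nDup)
  })
}

#' Simulate 4-CpG pattern clusters directly
#'
#' Cluster-level generator for the bipolar classifier: CSM clusters draw
#' each read from one of two subsets (per-cluster mixing proportion
#' uniform in `mixingRange`) with per-CpG probabilities `pHi` / `pLo`;
#' null clusters draw every read from a single subset with independent
#' per-CpG probability `pNull`.
#'
#' @param nCsm,nNull numbers of CSM and null clusters (defaults 500/500).
#' @param depth reads per cluster (default 20).
#' @param pHi,pLo CSM subset probabilities (defaults 0.95/0.05).
#' @param mixingRange per-cluster CSM mixing range (default 0.3..0.7).
#' @param pNull null per-CpG probability (default 0.5).
#' @param seed RNG seed.
#' @return list with `clusters` ([PatternClusterSet-class] on a
#'   synthetic chromosome) and `truth` (logical CSM status).
#' @export
simulateClusters <- function(nCsm = 500, nNull = 500, depth = 20,
                             pHi = 0.95, pLo = 0.05,
                             mixingRange = c(0.3, 0.7), pNull = 0.5,
                             seed = 1) {
  withSeed(seed, function() {
    n <- nCsm + nNull
    truth <- rep(c(TRUE, FALSE), c(nCsm, nNull))
    counts <- vector("list", n)
    for (i in seq_len(n)) {
      if (truth[i]) {
        m <- stats::runif(1, mixingRange[1], mixingRange[2])
        subA <- stats::runif(depth) < m
        pr <- ifelse(subA, pHi, pLo)
      } else pr <- rep(pNull, depth)
      pats <- vapply(pr, function(pp)
        paste(ifelse(stats::runif(4) < pp, "M", "U"), collapse = ""), "")
      tab <- table(pats)
      counts[[i]] <- stats::setNames(as.integer(tab), names(tab))
    }
    cpg1 <- 100L * seq_len(n)
    gr <- GenomicRanges::GRanges("chrS",
            IRanges::IRanges(start = cpg1, end = cpg1 + 31L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      cpg1 = cpg1, cpg2 = cpg1 + 10L, cpg3 = cpg1 + 20L, cpg4 = cpg1 + 30L)
    list(clusters = PatternClusterSet(gr, counts, "sim"), truth = truth)
  })
}

#' Simulate CpG dyad calls
#'
#' Fast dyad-level generator: each molecule carries a molecule-level base
#' state (fully methylated with probability `methLevel`, else fully
#' unmethylated), optionally perturbed per dyad on the top strand at rate
#' `dyadNoise`; the bottom strand flips each dyad independently at the
#' asymmetry rate.
#'
#' @param nMolecules,dyadsPerMolecule geometry.
#' @param methLevel fraction of methylated molecules (default 0.75).
#' @param asymmetryRate per-dyad strand discordance (default 0.05).
#' @param dyadNoise per-dyad top-state flip rate (default 0).
#' @param seed RNG seed.
#' @return dyad data.frame (molecule, pos, top, bottom).
#' @export
simulateDyads <- function(nMolecules = 1000, dyadsPerMolecule = 20,
                          methLevel = 0.75, asymmetryRate = 0.05,
                          dyadNoise = 0, seed = 1) {
  withSeed(seed, function() {
    n <- nMolecules * dyadsPerMolecule
    molState <- stats::runif(nMolecules) < methLevel
    top <- rep(molState, each = dyadsPerMolecule)
    if (dyadNoise > 0) {
      fl <- stats::runif(n) < dyadNoise
      top <- xor(top, fl)
    }
    asym <- stats::runif(n) < asymmetryRate
    bottom <- xor(top, asym)
    data.frame(molecule = rep(seq_len(nMolecules), each = dyadsPerMolecule),
               pos = rep(seq_len(dyadsPerMolecule), nMolecules),
               top = ifelse(top, "M", "U"),
               bottom = ifelse(bottom, "M", "U"))
  })
}

# bisulfite-convert one molecule into its two hairpin arms (top arm and
# the bottom arm reverse-complemented into the read-2 orientation)
convertArms <- function(bases, cpgPos, topM, botM, conversionFailure) {
  a1 <- bases
  # top strand: every C converts to T unless it is a methylated CpG C or a
  # conversion failure retains it
  cIdx <- which(bases == "C")
  conv <- !(cIdx %in% cpgPos[topM]) &
    stats::runif(length(cIdx)) >= conversionFailure
  a1[cIdx[conv]] <- "T"
  # bottom strand in top frame: its Cs sit under the Gs; conversion shows
  # as G -> A unless the dyad's bottom C is methylated
  a2p <- bases
  gIdx <- which(bases == "G")
  convG <- !(gIdx %in% (cpgPos[botM] + 1L)) &
    stats::runif(length(gIdx)) >= conversionFailure
  a2p[gIdx[convG]] <- "A"
  list(r1 = paste(a1, collapse = ""),
       r2 = as.character(Biostrings::reverseComplement(
         Biostrings::DNAString(paste(a2p, collapse = "")))))
}

#' Simulate hairpin bisulfite read pairs
#'
#' Molecules with planted CpG dyad states (molecule-level base state as
#' in [simulateDyads()]); the top arm is emitted as read 1 and the
#' reverse-complemented bottom arm as read 2, with hairpin-adapter
#' read-through when the read length exceeds the insert. Bisulfite
#' conversion failures retain unmethylated cytosines at the configured
#' rate.
#'
#' @param nMolecules number of molecules.
#' @param moleculeLength insert length (default 80).
#' @param dyadsPerMolecule CpGs per molecule (default 4).
#' @param methLevel,asymmetryRate as in [simulateDyads()].
#' @param conversionFailure retained-C rate (default 0.003).
#' @param readLength emitted read length (default 100; read-through into
#'   the hairpin when longer than the insert).
#' @param hairpinSeq hairpin adapter (default [HAIRPIN_ADAPTER]).
#' @param seed RNG seed.
#' @return list with `r1`, `r2` (character vectors), `truth` (dyad
#'   data.frame with molecule-local 1-based `pos`), `moleculeSeqs`.
#' @export
simulateHairpinPairs <- function(nMolecules = 200, moleculeLength = 80,
                                 dyadsPerMolecule = 4, methLevel = 0.75,
                                 asymmetryRate = 0.05,
                                 conversionFailure = 0.003,
                                 readLength = 100,
                                 hairpinSeq = HAIRPIN_ADAPTER, seed = 1) {
  withSeed(seed, function() {
    r1 <- r2 <- mseq <- character(nMolecules)
    truth <- vector("list", nMolecules)
    for (i in seq_len(nMolecules)) {
      # molecule with planted CpGs, no accidental CG
      gap <- max((moleculeLength - 2L) %/% (dyadsPerMolecule + 1L), 3L)
      cpgPos <- gap * seq_len(dyadsPerMolecule)
      bases <- sample(c("A", "C", "G", "T"), moleculeLength, replace = TRUE)
      bases[cpgPos] <- "C"; bases[cpgPos + 1L] <- "G"
      acc <- setdiff(which(bases[-moleculeLength] == "C" & bases[-1] == "G"),
                     cpgPos)
      if (length(acc)) bases[acc + 1L] <- "A"
      molM <- stats::runif(1) < methLevel
      topM <- rep(molM, dyadsPerMolecule)
      botM <- xor(topM, stats::runif(dyadsPerMolecule) < asymmetryRate)
      arms <- convertArms(bases, cpgPos, topM, botM, conversionFailure)
      ext <- max(readLength - moleculeLength, 0L)
      if (ext > 0) {
        tail <- substr(paste(rep(hairpinSeq, 10), collapse = ""), 1L, ext)
        arms$r1 <- paste0(arms$r1, tail)
        arms$r2 <- paste0(arms$r2, tail)
      }
      r1[i] <- arms$r1; r2[i] <- arms$r2
      mseq[i] <- paste(bases, collapse = "")
      truth[[i]] <- data.frame(molecule = i, pos = cpgPos,
                               top = ifelse(topM, "M", "U"),
                               bottom = ifelse(botM, "M", "U"))
    }
    list(r1 = r1, r2 = r2, truth = do.call(rbind, truth),
         moleculeSeqs = mseq)
  })
}

#' Simulate GWAS SNP tables with planted enrichment
#'
#' Null traits place SNPs uniformly along the genome; enriched traits
#' place a fraction `effect` of their SNPs uniformly inside the given
#' regions.
#'
#' @param regions GRanges of pCSM regions.
#' @param chromLengths named integer vector.
#' @param nEnriched,nNull trait counts.
#' @param snpsPerTrait SNPs per trait (default 200).
#' @param effect in-region fraction for enriched traits (default 0.5).
#' @param seed RNG seed.
#' @return list with `snps` (data.frame chrom, pos, trait) and `truth`
#'   (data.frame trait, enriched).
#' @export
simulateSnps <- function(regions, chromLengths, nEnriched = 5, nNull = 20,
                         snpsPerTrait = 200, effect = 0.5, seed = 1) {
  withSeed(seed, function() {
    chroms <- names(chromLengths)
    tot <- sum(as.numeric(chromLengths))
    drawUniform <- function(n) {
      chr <- sample(chroms, n, replace = TRUE,
                    prob = as.numeric(chromLengths) / tot)
      pos <- vapply(chr, function(cc)
        sample.int(chromLengths[[cc]], 1L), integer(1))
      data.frame(chrom = chr, pos = pos)
    }
    drawInRegions <- function(n) {
      idx <- sample.int(length(regions), n, replace = TRUE)
      data.frame(
        chrom = as.character(GenomicRanges::seqnames(regions))[idx],
        pos = GenomicRanges::start(regions)[idx] +
          floor(stats::runif(n) * GenomicRanges::width(regions)[idx]))
    }
    traits <- c(sprintf("enriched_%02d", seq_len(nEnriched)),
                sprintf("null_%03d", seq_len(nNull)))
    enriched <- rep(c(TRUE, FALSE), c(nEnriched, nNull))
    snps <- do.call(rbind, lapply(seq_along(traits), function(i) {
      if (enriched[i]) {
        nIn <- round(effect * snpsPerTrait)
        d <- rbind(drawInRegions(nIn), drawUniform(snpsPerTrait - nIn))
      } else d <- drawUniform(snpsPerTrait)
      d$trait <- traits[i]
      d
    }))
    rownames(snps) <- NULL
    list(snps = snps, truth = data.frame(trait = traits, enriched = enriched))
  })
}

#' Write read calls as TSV / reads as FASTQ / SAM helpers
#'
#' `writeReadCallsTsv` writes the TSV format consumed by
#' [parseReadCalls()]. `writeSimulatedSam` writes a minimal SAM with
#' Bismark-style XM tags for the simulated reads. `writeFastq` writes
#' plain 4-line FASTQ with constant qualities.
#'
#' @param reads read-calls data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReadCallsTsv <- function(reads, path) {
  fmt <- function(pos, st) {
    vapply(seq_along(pos), function(i) {
      if (!length(pos[[i]])) "." else
        paste(pos[[i]], st[[i]], sep = ":", collapse = ",")
    }, "")
  }
  df <- data.frame(read_id = reads$read_id, chrom = reads$chrom,
                   start = reads$start, end = reads$end,
                   strand = reads$strand,
                   cg_calls = fmt(reads$cg_pos, reads$cg_state),
                   ch_calls = fmt(reads$ch_pos, reads$ch_state))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReadCallsTsv
#' @param genome result of [simulateGenome()] (for sequences/lengths).
#' @export
writeSimulatedSam <- function(reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in chromNames(genome$cpgMap))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chr,
                       chromLengths(genome$cpgMap)[[chr]]), con)
  for (i in seq_len(nrow(reads))) {
    lo <- reads$start[i]; len <- reads$end[i] - reads$start[i]
    refseq <- substr(as.character(genome$sequences[[reads$chrom[i]]]),
                     lo, lo + len - 1L)
    xm <- rep(".", len); sq <- strsplit(refseq, "")[[1]]
    pos <- reads$cg_pos[[i]]; st <- reads$cg_state[[i]]
    rev <- reads$strand[i] == "-"
    off <- (if (rev) pos + 1L else pos) - lo + 1L
    ok <- off >= 1 & off <= len
    xm[off[ok]] <- ifelse(st[ok] == "M", "Z", "z")
    if (!rev) sq[off[ok & st == "U"]] <- "T"
    writeLines(paste(reads$read_id[i], if (rev) 16L else 0L,
                     reads$chrom[i], lo, 42L, paste0(len, "M"), "*", 0L, 0L,
                     paste(sq, collapse = ""),
                     paste(rep("I", len), collapse = ""),
                     paste0("XM:Z:", paste(xm, collapse = "")),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeReadCallsTsv
#' @param seqs character vector of read sequences.
#' @param ids read ids (defaults to read_1..n).
#' @export
writeFastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(n)
                      paste(rep("I", n), collapse = ""), "")), con)
  invisible(path)
}
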