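# Hairpin bisulfite sequencing: molecule reconstruction, methylation
# level, fidelity, sliding-window strand symmetry.

#' Default hairpin adapter sequence
#'
#' The biotinylated hairpin adapter ligated between the two strands of a
#' fragment (biotin-dT written as T).
#' @export
HAIRPIN_ADAPTER <- "GGCCAGCTGCAAGTGAAGCAGCTGGCCT"

# Earliest read position from which the remainder of the read matches a
# prefix of `adapter` with <= maxMismatchFrac mismatches and overlap >=
# minOverlap; NA if none. Semi-global suffix matcher replacing an
# external adapter-search tool.
adapterHit <- function(read, adapter, maxMismatchFrac = 0.1, minOverlap = 8) {
  rb <- strsplit(read, "")[[1]]
  ab <- strsplit(adapter, "")[[1]]
  n <- length(rb)
  for (i in seq_len(n)) {
    ov <- min(n - i + 1L, length(ab))
    if (ov < minOverlap) break
    mm <- sum(rb[i:(i + ov - 1L)] != ab[seq_len(ov)])
    if (mm <= floor(maxMismatchFrac * ov)) return(i)
  }
  NA_integer_
}

#' Trim hairpin and sequencing adapters from a read pair
#'
#' Removes from each mate any suffix matching a prefix of the hairpin
#' sequence or the sequencing adapter (at most 10% mismatches, minimum
#' overlap 8 by default). Untrimmable reads pass through unchanged.
#'
#' @param r1,r2 read sequences (character).
#' @param hairpinSeq hairpin adapter (default [HAIRPIN_ADAPTER]).
#' @param adapterSeq optional sequencing adapter searched after the
#'   hairpin.
#' @param maxMismatchFrac,minOverlap matcher tolerances.
#' @return list with trimmed `r1`, `r2` character vectors.
#' @export
trimHairpin <- function(r1, r2, hairpinSeq = HAIRPIN_ADAPTER,
                        adapterSeq = NULL, maxMismatchFrac = 0.1,
                        minOverlap = 8) {
  trimOne <- function(read) {
    for (ad in c(hairpinSeq, adapterSeq)) {
      hit <- adapterHit(read, ad, maxMismatchFrac, minOverlap)
      if (!is.na(hit)) read <- substr(read, 1L, hit - 1L)
    }
    read
  }
  list(r1 = vapply(r1, trimOne, "", USE.NAMES = FALSE),
       r2 = vapply(r2, trimOne, "", USE.NAMES = FALSE))
}

# bisulfite-aware substitution matrix: +1 match, -1 mismatch, C/T and G/A
# score as matches (post-conversion compatible), N neutral-ish (0)
bisulfiteSubMat <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["C", "T"] <- m["T", "C"] <- match
  m["G", "A"] <- m["A", "G"] <- match
  m["N", ] <- m[, "N"] <- 0
  m
}

#' Globally align the two arms of a hairpin read pair
#'
#' `r2` is reverse-complemented into `r1`'s frame and the two arms are
#' aligned with the Needleman-Wunsch algorithm (match +1, mismatch -1,
#' gap -2 by default); C/T and G/A column pairs are bisulfite-compatible
#' and score as matches. Identity is the fraction of compatible columns
#' among aligned columns after trimming end-gap overhangs.
#'
#' @param r1,r2 single read sequences.
#' @param match,mismatch,gap scoring parameters.
#' @return list with `score`, `identity`, `aligned1`, `aligned2` (aligned
#'   strings after overhang trimming, `aligned2` in `r1`'s frame).
#' @export
alignArms <- function(r1, r2, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(r1) || !nzchar(r2)) {
    return(list(score = NA_real_, identity = 0, aligned1 = "",
                aligned2 = "", discard = TRUE))
  }
  arm2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2)))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(r1),
    subject = Biostrings::DNAString(arm2),
    substitutionMatrix = bisulfiteSubMat(match, mismatch),
    gapOpening = 0, gapExtension = -gap, type = "global")
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # trim end-gap overhangs
  inner <- which(a1 != "-" & a2 != "-")
  if (!length(inner)) {
    return(list(score = Biostrings::score(aln), identity = 0,
                aligned1 = "", aligned2 = "", discard = TRUE))
  }
  span <- inner[1]:inner[length(inner)]
  a1 <- a1[span]; a2 <- a2[span]
  comp <- compatibleColumns(a1, a2)
  list(score = Biostrings::score(aln),
       identity = sum(comp) / length(a1),
       aligned1 = paste(a1, collapse = ""),
       aligned2 = paste(a2, collapse = ""),
       discard = FALSE)
}

compatibleColumns <- function(a1, a2) {
  (a1 == a2 & a1 != "-") |
    (a1 == "C" & a2 == "T") | (a1 == "T" & a2 == "C") |
    (a1 == "G" & a2 == "A") | (a1 == "A" & a2 == "G")
}

#' Recover the original molecule and its CpG dyad states
#'
#' Resolves, at each aligned column, the pre-conversion base: a T on the
#' top arm opposite a C on the bottom-frame arm was originally C (top
#' strand unmethylated); a retained C is methylated. Symmetrically, G/A
#' columns carry the bottom strand's state. CpG dyads are positions where
#' the recovered sequence reads CG: the top state comes from the C column
#' of the top arm, the bottom state from the G column of the bottom-frame
#' arm. Pairs with arm identity below `minIdentity` are rejected.
#'
#' @param aln result of [alignArms()].
#' @param minIdentity identity gate (default 0.9).
#' @return list with `sequence` (recovered original), `identity`, and
#'   `dyads` (data.frame pos, top, bottom with states "M"/"U"/NA;
#'   `pos` is the 1-based C position within the recovered sequence), or
#'   `NULL` when the pair is rejected.
#' @export
recoverMolecule <- function(aln, minIdentity = 0.9) {
  if (isTRUE(aln$discard) || aln$identity < minIdentity) return(NULL)
  a1 <- strsplit(aln$aligned1, "")[[1]]
  a2 <- strsplit(aln$aligned2, "")[[1]]
  n <- length(a1)
  orig <- character(n)
  for (i in seq_len(n)) {
    orig[i] <- if (a1[i] == a2[i] && a1[i] != "-") a1[i]
      else if ((a1[i] %in% c("C", "T")) && a2[i] == "C") "C"
      else if (a1[i] == "G" && (a2[i] %in% c("G", "A"))) "G"
      else if (a1[i] == "-") a2[i]
      else if (a2[i] == "-") a1[i]
      else "N"
  }
  keep <- orig != "-"
  orig <- orig[keep]; a1 <- a1[keep]; a2 <- a2[keep]
  seqc <- paste(orig, collapse = "")
  cg <- which(orig[-length(orig)] == "C" & orig[-1] == "G")
  top <- bottom <- rep(NA_character_, length(cg))
  if (length(cg)) {
    top <- ifelse(a1[cg] == "C", "M", ifelse(a1[cg] == "T", "U", NA))
    g <- cg + 1L
    bottom <- ifelse(a2[g] == "G", "M", ifelse(a2[g] == "A", "U", NA))
  }
  list(sequence = seqc, identity = aln$identity,
       dyads = data.frame(pos = cg, top = top, bottom = bottom))
}

#' Process hairpin read pairs end to end
#'
#' Trim, align, gate on arm identity, recover molecules and collect dyad
#' calls.
#'
#' @param r1,r2 character vectors of read pairs.
#' @param hairpinSeq,adapterSeq passed to [trimHairpin()].
#' @param minIdentity arm-identity gate (default 0.9).
#' @return list with `molecules` (list of [recoverMolecule()] results),
#'   `dyads` (data.frame molecule, pos, top, bottom; complete dyads
#'   only), `nPairs`, `nRejected`.
#' @export
processHairpinPairs <- function(r1, r2, hairpinSeq = HAIRPIN_ADAPTER,
                                adapterSeq = NULL, minIdentity = 0.9) {
  tr <- trimHairpin(r1, r2, hairpinSeq, adapterSeq)
  mols <- vector("list", length(r1))
  nRej <- 0L
  for (i in seq_along(r1)) {
    if (!nzchar(tr$r1[i]) || !nzchar(tr$r2[i])) { nRej <- nRej + 1L; next }
    m <- recoverMolecule(alignArms(tr$r1[i], tr$r2[i]), minIdentity)
    if (is.null(m)) { nRej <- nRej + 1L; next }
    mols[[i]] <- m
  }
  idx <- which(!vapply(mols, is.null, logical(1)))
  dy <- do.call(rbind, lapply(idx, function(i) {
    d <- mols[[i]]$dyads
    if (!nrow(d)) return(NULL)
    cbind(molecule = i, d)
  }))
  if (is.null(dy))
    dy <- data.frame(molecule = integer(0), pos = integer(0),
                     top = character(0), bottom = character(0))
  dy <- dy[!is.na(dy$top) & !is.na(dy$bottom), , drop = FALSE]
  list(molecules = mols[idx], dyads = dy,
       nPairs = length(r1), nRejected = nRej)
}

#' Methylation fidelity
#'
#' Percentage (as a fraction) of CpG dyads whose two strands carry the
#' same methylation state (both M or both U).
#'
#' @param dyads data.frame with `top` and `bottom` columns ("M"/"U").
#' @return fraction in \[0, 1\], or `NA` when no complete dyad exists.
#' @export
methylationFidelity <- function(dyads) {
  ok <- !is.na(dyads$top) & !is.na(dyads$bottom)
  if (!any(ok)) return(undefinedValue())
  mean(dyads$top[ok] == dyads$bottom[ok])
}

#' Hairpin methylation level
#'
#' Methylated strand-calls over total strand-calls at CpG dyads (both
#' strands counted), the convention inherited from hairpin bisulfite
#' analyses.
#'
#' @param dyads dyad data.frame.
#' @return fraction in \[0, 1\], or `NA` with no calls.
#' @export
methylationLevel <- function(dyads) {
  calls <- c(dyads$top, dyads$bottom)
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(undefinedValue())
  mean(calls == "M")
}

#' Sliding-window strand symmetry
#'
#' Over all runs of `w` adjacent called dyads within one molecule, a
#' window is symmetric when both strands are uniform (all M or all U) and
#' identical, asymmetric when both strands are uniform and opposite; all
#' other windows count only toward `nWindows`.
#'
#' @param dyads dyad data.frame with a `molecule` column.
#' @param w window size (1..4).
#' @return list with `w`, `nWindows`, `nSymmetric`, `nAsymmetric`,
#'   `symmetricFraction`, `asymmetricFraction`.
#' @export
windowSymmetry <- function(dyads, w) {
  stopifnot(w >= 1, w <= 4)
  ok <- !is.na(dyads$top) & !is.na(dyads$bottom)
  dyads <- dyads[ok, , drop = FALSE]
  o <- order(dyads$molecule, dyads$pos)
  topM <- dyads$top[o] == "M"
  botM <- dyads$bottom[o] == "M"
  mol <- dyads$molecule[o]
  n <- length(topM)
  nw <- ns <- na_ <- 0L
  if (n >= w) {
    # rolling sums over windows fully inside one molecule
    cs <- function(x) { c0 <- cumsum(x); c0[(w):n] - c(0, c0)[1:(n - w + 1)] }
    tS <- cs(topM); bS <- cs(botM)
    sameMol <- mol[1:(n - w + 1)] == mol[(w):n]
    tS <- tS[sameMol]; bS <- bS[sameMol]
    nw <- length(tS)
    tUni <- tS == 0L | tS == w
    bUni <- bS == 0L | bS == w
    ns <- sum(tUni & bUni & tS == bS)
    na_ <- sum(tUni & bUni & tS != bS & (tS + bS) == w)
  }
  list(w = w, nWindows = nw, nSymmetric = ns, nAsymmetric = na_,
       symmetricFraction = if (nw) ns / nw else undefinedValue(),
       asymmetricFraction = if (nw) na_ / nw else undefinedValue())
}

#' Per-bin methylation level and fidelity along features
#'
#' Each feature is divided into `nBins` equal-sized bins (strand-aware:
#' bin 1 is the 5' end); dyads are assigned by fractional position and
#' pooled across features.
#'
#' @param dyads data.frame with `chrom`, `pos`, `top`, `bottom`.
#' @param features a stranded [GenomicRanges::GRanges] (or BED path).
#' @param nBins number of bins (default 20).
#' @return data.frame bin, nDyads, level, fidelity (NA for empty bins).
#' @export
aggregateByFeature <- function(dyads, features, nBins = 20) {
  if (is.character(features)) features <- readBed(features)
  short <- GenomicRanges::width(features) < nBins
  if (any(short)) {
    warning(sum(short), " feature(s) shorter than nBins skipped")
    features <- features[!short]
  }
  binIdx <- integer(0); topv <- botv <- character(0)
  dg <- GenomicRanges::GRanges(dyads$chrom,
                               IRanges::IRanges(dyads$pos, width = 1))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(dg, features, ignore.strand = TRUE))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    fs <- GenomicRanges::start(features)[si]
    fw <- GenomicRanges::width(features)[si]
    frac <- (dyads$pos[qi] - fs + 0.5) / fw
    neg <- as.character(GenomicRanges::strand(features))[si] == "-"
    frac[neg] <- 1 - frac[neg]
    binIdx <- pmin(pmax(ceiling(frac * nBins), 1L), nBins)
    topv <- dyads$top[qi]; botv <- dyads$bottom[qi]
  }
  out <- data.frame(bin = seq_len(nBins), nDyads = 0L,
                    level = undefinedValue(), fidelity = undefinedValue())
  for (b in seq_len(nBins)) {
    sel <- binIdx == b
    if (!any(sel)) next
    out$nDyads[b] <- sum(sel)
    st <- c(topv[sel], botv[sel]); st <- st[!is.na(st)]
    if (length(st)) out$level[b] <- mean(st == "M")
    cc <- !is.na(topv[sel]) & !is.na(botv[sel])
    if (any(cc)) out$fidelity[b] <- mean(topv[sel][cc] == botv[sel][cc])
  }
  out
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' @param states character vector of calls at cytosine positions of reads
#'   mapped to the unmethylated spike-in ("M" retained, "U" converted).
#' @return converted fraction, or `NA` with no calls.
#' @export
conversionRate <- function(states) {
  states <- states[states %in% c("M", "U")]
  if (!length(states)) return(undefinedValue())
  mean(states == "U")
}
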