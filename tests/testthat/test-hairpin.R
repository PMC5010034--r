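test_that("hairpin adapter read-through is trimmed, clean reads pass through", {
  insert <- "ACGTACGTACGTACGT"
  read <- paste0(insert, HAIRPIN_ADAPTER)
  tr <- trimHairpin(read, read)
  expect_identical(tr$r1, insert)
  expect_identical(tr$r2, insert)

  # partial adapter (>= minOverlap) still trims
  read2 <- paste0(insert, substr(HAIRPIN_ADAPTER, 1, 10))
  expect_identical(trimHairpin(read2, read2)$r1, insert)

  # short overhang below minOverlap is left alone
  read3 <- paste0(insert, substr(HAIRPIN_ADAPTER, 1, 5))
  expect_identical(trimHairpin(read3, read3)$r1, read3)

  # no adapter: unchanged
  expect_identical(trimHairpin(insert, insert)$r1, insert)

  # one mismatch in a 10-base overlap is within the 10% tolerance
  ad10 <- substr(HAIRPIN_ADAPTER, 1, 10)
  substr(ad10, 5, 5) <- if (substr(ad10, 5, 5) == "A") "C" else "A"
  read4 <- paste0(insert, ad10)
  expect_identical(trimHairpin(read4, read4)$r1, insert)
})

test_that("arm alignment scores identity 1 for perfectly complementary arms", {
  r1 <- "ACGTTGCAACGT"
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r1)))
  aln <- alignArms(r1, r2)
  expect_equal(aln$identity, 1)
  expect_equal(aln$score, nchar(r1))
  expect_identical(aln$aligned1, r1)
  expect_identical(aln$aligned2, r1)
})

test_that("bisulfite-compatible columns (C/T, G/A) count as matches", {
  # arm2 (in r1 frame) keeps C where r1 shows the converted T, and vice versa
  a1 <- "ATGTACGA"  # originally ACGTACGA with C2 converted on the top arm
  arm2inframe <- "ACGTACAA"  # G7 converted on the bottom arm
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arm2inframe)))
  aln <- alignArms(a1, r2)
  expect_equal(aln$identity, 1)
  expect_equal(aln$score, 8)
})

test_that("identity is the compatible fraction and gates recovery at 90%", {
  # 20 columns with exactly 2 incompatible mismatches -> identity 0.9
  base <- strsplit("ACGTACGTACGTACGTACGT", "")[[1]]
  mut <- base
  mut[c(3, 10)] <- c("T", "G")  # G->T and C->G are incompatible swaps
  r1 <- paste(base, collapse = "")
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste(mut, collapse = ""))))
  aln <- alignArms(r1, r2)
  expect_equal(aln$identity, 0.9)
  expect_false(is.null(recoverMolecule(aln, minIdentity = 0.9)))
  expect_null(recoverMolecule(aln, minIdentity = 0.95))
})

test_that("alignment score equals an independent Needleman-Wunsch oracle", {
  set.seed(61)
  for (i in 1:100) {
    n1 <- sample(15:40, 1); n2 <- sample(15:40, 1)
    s1 <- paste(sample(c("A", "C", "G", "T"), n1, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), n2, TRUE), collapse = "")
    aln <- alignArms(s1, s2)
    arm2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s2)))
    expect_equal(aln$score, nwOracleScore(s1, arm2))
  }
})

test_that("dyad recovery resolves strand states from retained/converted bases", {
  # molecule TACGA, one CpG at pos 2; both strands methylated
  aln1 <- alignArms("TACGA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("TACGA"))))
  m1 <- recoverMolecule(aln1)
  expect_identical(m1$sequence, "TACGA")
  expect_identical(m1$dyads$pos, 3L)
  expect_identical(m1$dyads$top, "M")
  expect_identical(m1$dyads$bottom, "M")

  # top unmethylated (C->T on arm1), bottom methylated (G retained)
  aln2 <- alignArms("TATGA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("TACGA"))))
  m2 <- recoverMolecule(aln2)
  expect_identical(m2$sequence, "TACGA")
  expect_identical(m2$dyads$top, "U")
  expect_identical(m2$dyads$bottom, "M")

  # both unmethylated: C->T on top, G->A on bottom-frame arm
  aln3 <- alignArms("TATGA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("TACAA"))))
  m3 <- recoverMolecule(aln3)
  expect_identical(m3$sequence, "TACGA")
  expect_identical(m3$dyads$top, "U")
  expect_identical(m3$dyads$bottom, "U")
})

test_that("fidelity is the symmetric-dyad fraction and matches w=1 window symmetry", {
  dy <- data.frame(molecule = 1L, pos = 1:4,
                   top = c("M", "M", "U", "U"),
                   bottom = c("M", "U", "U", "U"))
  expect_equal(methylationFidelity(dy), 0.75)
  expect_equal(methylationLevel(dy), 3 / 8)
  w1 <- windowSymmetry(dy, 1)
  expect_equal(w1$nWindows, 4)
  expect_equal(w1$symmetricFraction, methylationFidelity(dy))
  expect_equal(w1$nSymmetric + w1$nAsymmetric, w1$nWindows)

  none <- data.frame(molecule = integer(0), pos = integer(0),
                     top = character(0), bottom = character(0))
  expect_true(is.na(methylationFidelity(none)))
  expect_true(is.na(methylationLevel(none)))

  # this property holds on simulated data too
  sim <- simulateDyads(nMolecules = 300, seed = 63)
  expect_equal(windowSymmetry(sim, 1)$asymmetricFraction,
               1 - methylationFidelity(sim))
})

test_that("multi-dyad windows require uniform strands and never span molecules", {
  # two dyads, both strands fully methylated: one symmetric w=2 window
  dy <- data.frame(molecule = 1L, pos = 1:2,
                   top = c("M", "M"), bottom = c("M", "M"))
  w <- windowSymmetry(dy, 2)
  expect_equal(w$nWindows, 1)
  expect_equal(w$nSymmetric, 1)
  expect_equal(w$nAsymmetric, 0)

  # fully asymmetric: top all M, bottom all U
  dy2 <- dy; dy2$bottom <- c("U", "U")
  w2 <- windowSymmetry(dy2, 2)
  expect_equal(w2$nAsymmetric, 1)
  expect_equal(w2$nSymmetric, 0)

  # mixed bottom strand: window counts toward the denominator only
  dy3 <- dy; dy3$bottom <- c("M", "U")
  w3 <- windowSymmetry(dy3, 2)
  expect_equal(w3$nWindows, 1)
  expect_equal(w3$nSymmetric, 0)
  expect_equal(w3$nAsymmetric, 0)

  # windows never cross molecule boundaries
  dy4 <- data.frame(molecule = c(1L, 2L), pos = c(1L, 1L),
                    top = c("M", "M"), bottom = c("M", "M"))
  expect_equal(windowSymmetry(dy4, 2)$nWindows, 0)
})

test_that("feature aggregation bins dyads 5' to 3' with strand awareness", {
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 20),
                                 strand = "+")
  dy <- data.frame(chrom = "chr1", pos = c(3L, 17L),
                   top = c("M", "U"), bottom = c("M", "U"))
  agg <- aggregateByFeature(dy, feat, nBins = 2)
  expect_equal(agg$nDyads, c(1L, 1L))
  expect_equal(agg$level, c(1, 0))
  expect_equal(agg$fidelity, c(1, 1))

  featMinus <- feat; GenomicRanges::strand(featMinus) <- "-"
  aggM <- aggregateByFeature(dy, featMinus, nBins = 2)
  expect_equal(aggM$level, c(0, 1))

  # dyads outside any feature leave bins empty (NA, not 0)
  aggEmpty <- aggregateByFeature(
    data.frame(chrom = "chr2", pos = 5L, top = "M", bottom = "M"),
    feat, nBins = 2)
  expect_equal(aggEmpty$nDyads, c(0L, 0L))
  expect_true(all(is.na(aggEmpty$level)))
})

test_that("conversion rate comes from spike-in calls with an NA sentinel", {
  states <- c(rep("U", 997), rep("M", 3))
  expect_equal(conversionRate(states), 0.997)
  expect_true(is.na(conversionRate(character(0))))
  expect_equal(conversionRate(c("U", "M", NA, "X")), 0.5)
})

test_that("the full hairpin pipeline recovers simulated molecules and dyad states", {
  sim <- simulateHairpinPairs(nMolecules = 60, moleculeLength = 80,
                              dyadsPerMolecule = 4, methLevel = 0.75,
                              asymmetryRate = 0.3, conversionFailure = 0,
                              readLength = 100, seed = 65)
  out <- processHairpinPairs(sim$r1, sim$r2)
  expect_equal(out$nRejected, 0)
  expect_equal(nrow(out$dyads), nrow(sim$truth))
  # with zero conversion failure every molecule and dyad is exact
  expect_identical(vapply(out$molecules, `[[`, "", "sequence"),
                   sim$moleculeSeqs)
  got <- out$dyads[order(out$dyads$molecule, out$dyads$pos), ]
  want <- sim$truth[order(sim$truth$molecule, sim$truth$pos), ]
  expect_identical(got$top, want$top)
  expect_identical(got$bottom, want$bottom)
  expect_equal(methylationFidelity(out$dyads),
               methylationFidelity(sim$truth))
})

test_that("fidelity is stable under subsampling ten thousand molecules", {
  full <- simulateDyads(nMolecules = 50000, dyadsPerMolecule = 20,
                        asymmetryRate = 0.05, seed = 67)
  fidFull <- methylationFidelity(full)
  set.seed(68)
  for (rep in 1:3) {
    mols <- sample(50000, 10000)
    sub <- full[full$molecule %in% mols, ]
    expect_lt(abs(methylationFidelity(sub) - fidFull), 0.01)
  }
})
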