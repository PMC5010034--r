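test_that("promoters span 2 kb upstream of the TSS, strand-aware, with CGI status", {
  tss <- GenomicRanges::GRanges(c("chr1", "chr1"),
                                IRanges::IRanges(c(5000, 5000), width = 1),
                                strand = c("+", "-"))
  S4Vectors::mcols(tss)$name <- c("gPlus", "gMinus")
  cgi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3500, 3600))
  prom <- promoterSet(tss, cgi)
  expect_equal(GenomicRanges::start(prom), c(3000, 5001))
  expect_equal(GenomicRanges::end(prom), c(4999, 7000))
  expect_equal(S4Vectors::mcols(prom)$cgiStatus, c("CGI", "nonCGI"))
})

test_that("element classification reproduces the full occupancy truth table", {
  combos <- expand.grid(k4me1 = c(FALSE, TRUE), k4me3 = c(FALSE, TRUE),
                        k27ac = c(FALSE, TRUE), cgi = c(FALSE, TRUE))
  loci <- 1000L * seq_len(nrow(combos))
  mk <- function(sel) {
    if (!any(sel)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges("chr1",
      IRanges::IRanges(loci[sel], width = 100))
  }
  got <- classifyElements(mk(combos$k4me1), mk(combos$k4me3),
                          mk(combos$k27ac), mk(combos$cgi))
  anyMark <- combos$k4me1 | combos$k4me3 | combos$k27ac
  expect_equal(length(got), sum(anyMark))
  for (i in which(anyMark)) {
    j <- which(GenomicRanges::start(got) == loci[i])
    expect_length(j, 1)
    expect_identical(S4Vectors::mcols(got)$elementClass[j],
                     elementClassOracle(combos$k4me1[i], combos$k4me3[i],
                                        combos$k27ac[i], combos$cgi[i]))
  }

  # overlapping peaks of different marks merge into one labelled region
  one <- classifyElements(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 300)),
    GenomicRanges::GRanges(),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(250, 400)),
    GenomicRanges::GRanges())
  expect_equal(length(one), 1)
  expect_identical(S4Vectors::mcols(one)$elementClass, "active_enhancer")
})

test_that("gene association uses a 10 kb TSS window against a background set", {
  tss <- GenomicRanges::GRanges(rep("chr1", 3),
                                IRanges::IRanges(c(20000, 60000, 100000),
                                                 width = 1),
                                strand = "+")
  S4Vectors::mcols(tss)$name <- c("g1", "g2", "g3")
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(25000, 71000), width = 32))  # 5 kb from g1; 11 kb from g2
  eligible <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(25000, 65000, 71000), width = 32))
  assoc <- associateGenes(regions, tss, eligible)
  expect_identical(assoc$foreground, "g1")
  expect_setequal(assoc$background, c("g1", "g2"))

  # randomized oracle: midpoint distance to the TSS window
  set.seed(81)
  tpos <- sort(sample.int(500000, 30))
  tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(tpos, width = 1),
                               strand = "+")
  S4Vectors::mcols(tr)$name <- paste0("g", seq_along(tpos))
  rs <- sample.int(500000, 60)
  rg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rs, width = 32))
  a2 <- associateGenes(rg, tr, rg)
  hit <- vapply(seq_along(tpos), function(i)
    any(rs <= tpos[i] + 10000 & rs + 31 >= tpos[i] - 10000), logical(1))
  expect_setequal(a2$foreground, paste0("g", which(hit)))
  expect_identical(a2$foreground, a2$background)
})

test_that("TSS profile bins eligible segments by strand-aware midpoint offset", {
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, width = 1),
                                strand = "+")
  mkCalls <- function(mids, elig, bip) {
    gr <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(mids - 15L, mids + 16L))
    S4Vectors::mcols(gr)$eligible <- elig
    S4Vectors::mcols(gr)$isBipolar <- bip
    gr
  }
  # midpoints at -4500 (bin 1) and +4500 (bin 10) with nBins = 10
  calls <- mkCalls(c(5500L, 14500L), c(TRUE, TRUE), c(TRUE, FALSE))
  pr <- tssProfile(calls, tss, flank = 5000, nBins = 10)
  expect_equal(pr$nEligible, c(1L, rep(0L, 8), 1L))
  expect_equal(pr$frequency[1], 1)
  expect_equal(pr$frequency[10], 0)
  expect_true(all(is.na(pr$frequency[2:9])))
  expect_equal(pr$offsetMid[1], -4500)

  # ineligible segments are excluded entirely
  pr2 <- tssProfile(mkCalls(5500L, FALSE, TRUE), tss, 5000, 10)
  expect_equal(sum(pr2$nEligible), 0)

  # minus-strand TSS flips upstream/downstream
  tssM <- tss; GenomicRanges::strand(tssM) <- "-"
  prM <- tssProfile(calls, tssM, flank = 5000, nBins = 10)
  expect_equal(prM$frequency[10], 1)
  expect_equal(prM$frequency[1], 0)
})

test_that("observed SNP counts respect the inclusive extension+proximity distance", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600))
  mkSnps <- function(pos) data.frame(chrom = "chr1", pos = pos, trait = "t")
  cl <- c(chr1 = 100000L)
  # pad = 200: positions 300..800 count
  obsAt <- function(pos)
    gwasEnrichment(regions, mkSnps(pos), cl, nIter = 5, seed = 82)$observed
  expect_equal(obsAt(c(300, 800)), 2)
  expect_equal(obsAt(c(299, 801)), 0)
  # duplicate SNPs count once
  expect_equal(obsAt(c(550, 550, 550)), 1)

  # wrap-around arc near the chromosome start
  regWrap <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 60))
  clS <- c(chr1 = 1000L)
  obsW <- function(pos)
    gwasEnrichment(regWrap, mkSnps(pos), clS, nIter = 5, seed = 82)$observed
  expect_equal(obsW(c(900, 200)), 2)   # 850..1000 and 1..260
  expect_equal(obsW(c(849, 261)), 0)
})

test_that("exhaustive circular permutation equals the naive enumeration oracle", {
  L <- 1000L
  regStart <- c(100L, 400L); regEnd <- c(140L, 430L)
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(regStart, regEnd))
  set.seed(83)
  pos <- sort(sample.int(L, 12))
  snps <- data.frame(chrom = "chr1", pos = pos, trait = "t1")
  got <- gwasEnrichment(regions, snps, c(chr1 = L), extension = 5,
                        proximity = 5, exhaustive = TRUE)
  want <- enrichExhaustiveOracle(regStart, regEnd, pos, L,
                                 extension = 5, proximity = 5)
  expect_equal(got$p, want)
  expect_equal(got$nIter, L)

  expect_error(
    gwasEnrichment(regions, snps, c(chr1 = L, chr2 = L), exhaustive = TRUE),
    "single-chromosome")
})

test_that("sampled permutation p-values are bounded, seeded, and flag planted enrichment", {
  set.seed(84)
  L <- 200000L
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sort(sample.int(L - 2000L, 10)), width = 500))
  sim <- simulateSnps(regions, c(chr1 = L), nEnriched = 1, nNull = 1,
                      snpsPerTrait = 100, effect = 0.8, seed = 85)
  res <- gwasEnrichment(regions, sim$snps, c(chr1 = L), nIter = 199,
                        seed = 86)
  expect_true(all(res$p >= 1 / 200 & res$p <= 1))
  enrTrait <- sim$truth$trait[sim$truth$enriched]
  nullTrait <- sim$truth$trait[!sim$truth$enriched]
  expect_lt(res$p[res$trait == enrTrait], 0.05)
  expect_gt(res$p[res$trait == nullTrait], 0.05)
  # identical seed, identical result
  res2 <- gwasEnrichment(regions, sim$snps, c(chr1 = L), nIter = 199,
                         seed = 86)
  expect_identical(res, res2)

  # zero-SNP traits are skipped with a warning
  s2 <- sim$snps; s2$chrom[s2$trait == nullTrait] <- "chrZ"
  expect_warning(r3 <- gwasEnrichment(regions, s2, c(chr1 = L),
                                      nIter = 19, seed = 87),
                 "zero SNPs")
  expect_false(nullTrait %in% r3$trait)
})

test_that("trait ranking orders by recurrence then mean p, with optional BH", {
  results <- data.frame(
    trait = rep(c("tA", "tB", "tC"), each = 2),
    p = c(0.01, 0.02, 0.01, 0.50, 0.80, 0.90),
    sample_id = rep(c("s1", "s2"), 3))
  rk <- rankTraits(results)
  expect_equal(rk$trait, c("tA", "tB", "tC"))
  expect_equal(rk$nSignificant, c(2L, 1L, 0L))
  expect_equal(rk$meanP, c(0.015, 0.255, 0.85))

  # BH within each sample: s1 has p = .01, .01, .80 over 3 traits
  rkBH <- rankTraits(results, adjust = "BH")
  padj1 <- stats::p.adjust(c(0.01, 0.01, 0.80), "BH")
  padj2 <- stats::p.adjust(c(0.02, 0.50, 0.90), "BH")
  expect_equal(rkBH$nSignificant[rkBH$trait == "tA"],
               sum(c(padj1[1], padj2[1]) <= 0.05))
})
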