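# bipolarMeth

Detection of cell-subset specific (bipolar) DNA methylation from bulk
bisulfite sequencing, with hairpin bisulfite fidelity analysis.

## Why per-read patterns

Bulk bisulfite sequencing averages methylation across all cells of a
tissue, so a locus fully methylated in one cell subset and fully
unmethylated in another looks identical to uniform 50% methylation.
Each sequencing read, however, is one molecule from one cell. At such a
locus the *reads* are bipolar: some fully methylated, some fully
unmethylated, few in between. `bipolarMeth` scans segments of four
consecutive CpGs, collects each read's methylation pattern
(`MMMM` … `UUUU`), and classifies segments whose pattern mixture
decomposes into a hypomethylated and a hypermethylated component as
putative cell-subset specific methylation (pCSM) loci.

The package covers the full workflow:

* **Pattern extraction** (`buildCpGMap`, `parseReadCalls`,
  `dedupReads`, `extractSegments`) from SAM/BAM with Bismark-style `XM`
  tags or a plain per-CpG-call TSV.
* **Bipolar classification** (`classifyBipolar`): prefilter (depth
  ≥ 10 plus concurrent `MMMM` and `UUUU` reads), then a
  Dirichlet-process mixture of Beta-Binomial components fit by a
  collapsed Gibbs sampler (Rcpp); a segment is bipolar when the
  posterior favours both a component with mean ≤ 0.25 and one with
  mean ≥ 0.75, each with weight ≥ 0.10. Deterministic `em_bic` and
  `lrt_oracle` routes provide independent cross-checks.
* **Filtering and merging** (`filterCalls`, `mergeRegions`,
  `pcsmFrequency`, `profileCorrelation`): sex chromosomes and imprinted
  regions excluded, overlapping bipolar segments merged into pCSM
  regions.
* **Hairpin bisulfite analysis** (`trimHairpin`, `alignArms`,
  `recoverMolecule`, `processHairpinPairs`, `methylationFidelity`,
  `windowSymmetry`): reconstruct both strands of each molecule,
  compute the fraction of symmetric CpG dyads, and separate stochastic
  per-dyad noise (asymmetric window fraction decaying as rate^w) from
  stable subset structure.
* **Down-sampling normalization** (`commonSegments`,
  `detectionProbability`, `normalizedFrequency`) for depth-fair
  cross-sample comparison.
* **Annotation and enrichment** (`classifyElements`, `promoterSet`,
  `associateGenes`, `tssProfile`, `gwasEnrichment`, `rankTraits`):
  histone-mark element classes and GWAS SNP enrichment under a
  circular-permutation null.
* **Simulators** (`simulateClusters`, `simulateBulkReads`,
  `simulateDyads`, `simulateHairpinPairs`, `simulateGenome`,
  `simulateSnps`): first-class, tested generators for every module.

A thin command-line front end over these functions ships in
`inst/cli/bipolarmeth.R`.

## Worked example

Simulate 50 CSM segments (two subsets at per-CpG methylation 0.95 and
0.05, mixing 0.3–0.7) plus 50 null segments at 20×, classify, and
summarise:

```r
library(bipolarMeth)

sc <- simulateClusters(nCsm = 50, nNull = 50, depth = 20, seed = 1)
calls <- classifyBipolar(sc$clusters, seed = 1)
table(truth = sc$truth, called = S4Vectors::mcols(calls)$isBipolar)
#>        called
#> truth   FALSE TRUE
#>   FALSE    50    0
#>   TRUE      0   50

pcsmFrequency(calls)
#> [1] 0.5

calls[1]
#> GRanges object with 1 range and 15 metadata columns:
#>       seqnames    ranges strand |  cpg1  cpg2  cpg3  cpg4 depth eligible
#>   [1]     chrS   100-131      * |   100   110   120   130    20     TRUE
#>       prefilterPass isBipolar nComponents hypoWeight hyperWeight ...
#>   [1]          TRUE      TRUE           6       0.55        0.35 ...
```

Hairpin read pairs: trim the hairpin adapter, align the arms, recover
dyads, and measure fidelity:

```r
hp <- simulateHairpinPairs(nMolecules = 100, asymmetryRate = 0.05,
                           conversionFailure = 0, seed = 2)
out <- processHairpinPairs(hp$r1, hp$r2)
methylationFidelity(out$dyads)
#> [1] 0.945

dy <- simulateDyads(nMolecules = 20000, asymmetryRate = 0.05, seed = 3)
sapply(1:3, function(w) windowSymmetry(dy, w)$asymmetricFraction)
#> [1] 0.0495550000 0.0024447368 0.0001527778   # ~0.05^w
```

Down-sampling detection probability for one cluster (3 `MMMM`, 4
`UUUU`, 13 `MMUU`) subsampled to 10 reads:

```r
detectionProbability(c(MMMM = 3L, UUUU = 4L, MMUU = 13L), 10,
                     nRepeats = 100, seed = 4, classifier = "prefilter")
#> [1] 0.88   # exact hypergeometric value: 0.853
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "bipolarMeth", load_package = "installed")'
```

The suite validates each module against independent oracles: a
quadratic-DP reimplementation of the arm aligner, exact hypergeometric
detection probabilities, brute-force interval merging/filtering,
exhaustive circular-permutation enumeration, and the classifier's
`lrt_oracle` route. `tests/testthat/test-acceptance.R` holds the
end-to-end performance checks (classifier sensitivity/FPR, fidelity
identities, 0.05^w window scaling, permutation-test calibration).

## Further reading

The methods vignette
(`vignettes/bipolar-methylation-methods.Rmd`) documents the model,
the classifier and its thresholds, the hairpin definitions, the
simulator design, and known limitations.
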