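---
title: "Detecting cell-subset specific methylation from bulk and hairpin bisulfite data"
author: "bipolarMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell-subset specific methylation from bulk and hairpin bisulfite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# Scientific background

Bulk bisulfite sequencing averages methylation over all cells in a
tissue. A locus that is fully methylated in one cell subset and fully
unmethylated in another shows an intermediate average indistinguishable
from uniform partial methylation — unless the individual sequencing
reads are examined. Each read reports one molecule from one cell, so a
mixed tissue leaves a *bipolar* footprint at such a locus: some reads
fully methylated, others fully unmethylated, with few intermediates.

`bipolarMeth` detects these putative cell-subset specific methylation
(pCSM) loci from per-read methylation patterns over segments of four
consecutive CpGs, and complements that with hairpin bisulfite analysis,
which reads both strands of one molecule and quantifies how faithfully
methylation states are copied across strands (the *methylation
fidelity*), distinguishing stable cell-subset differences from
stochastic per-strand noise.

# Per-read pattern extraction

Reads (aligner output with Bismark-style `XM` methylation-call tags, or
a plain TSV of per-CpG calls) are deduplicated on
(chromosome, start, strand, length) and sliced into 4-CpG segments: for
every run of four *consecutive* CpGs in the reference CpG map, each read
covering all four with unambiguous calls contributes one pattern in
`{M,U}^4` (e.g. `MMUU`). Patterns per segment are stored in a
`PatternClusterSet`.

Internally all coordinates are 1-based closed, the native convention of
`GRanges` and `Biostrings`; BED input/output converts to and from
0-based half-open at the file boundary only. Keeping the platform's
single native convention avoids off-by-one drift between our code and
the Bioconductor operations we call.

# Bipolar classification

A segment enters classification only if it passes the **prefilter**:
depth at least 10 *and* at least one fully methylated (`MMMM`) and one
fully unmethylated (`UUUU`) read concurrently. Note the distinction
between *eligible* (depth ≥ 10; the denominator of pCSM frequency) and
*prefilter-passing* (the candidates actually classified): a deep
segment with no extreme reads counts in the denominator but can never
be called bipolar.

For each candidate, the per-read methylated-CpG counts $k_i \in
\{0..4\}$ are modelled as a Dirichlet-process mixture of Beta-Binomial
components ($n = 4$ trials, concentration $\alpha = 1$,
$\mathrm{Beta}(0.5, 0.5)$ base measure), fit by collapsed Gibbs sampling
(200 sweeps, 100 burn-in). On each recorded sweep we ask whether the
partition contains both a hypomethylated component (posterior mean
≤ 0.25) and a hypermethylated one (mean ≥ 0.75), each with weight
≥ 0.10; the segment is **bipolar** when at least half of the recorded
sweeps qualify. This reads "the fitted mixture contains both extreme
components" as a posterior statement rather than a point estimate,
which is the natural translation for a sampled posterior.

Two alternative routes with the same bipolarity rule are provided:
`em_bic` (finite binomial mixtures, $K = 1..3$, deterministic
quantile-initialised EM with BIC selection) and `lrt_oracle`
(exhaustive-grid two-component maximum likelihood gated by a
$\chi^2_2$ likelihood-ratio test at 0.95), used as independent
cross-checks in the test suite.

All classification operates on the *canonicalised* pattern multiset
(patterns sorted lexicographically before expansion), so results are
invariant to input order; each (segment, sample) derives its own RNG
stream from the master seed, so results are also invariant to the set
of other segments processed.

```{r classify}
library(bipolarMeth)
sc <- simulateClusters(nCsm = 50, nNull = 50, depth = 20, seed = 1)
calls <- classifyBipolar(sc$clusters, seed = 1)
table(truth = sc$truth, called = S4Vectors::mcols(calls)$isBipolar)
```

Segments on chrX/chrY and segments overlapping imprinted regions are
excluded (`filterCalls`) because allele-specific methylation mimics
bipolarity; surviving bipolar segments merge into pCSM regions where
they overlap by at least 1 bp (`mergeRegions`; adjacent segments that
share no CpG stay separate).

# Hairpin bisulfite analysis

Hairpin libraries ligate a hairpin adapter between the two strands of
one fragment, so a read pair contains both strands of one molecule.
Processing: (1) trim read-through into the hairpin (semi-global suffix
match, ≤ 10% mismatches, ≥ 8 bp overlap); (2) reverse-complement read 2
and align the arms globally (Needleman–Wunsch, match +1, mismatch −1,
linear gap −2) under a bisulfite-aware substitution matrix where C/T
and G/A columns count as matches; (3) keep pairs whose arm identity —
compatible columns over aligned columns after trimming end-gap
overhangs — is at least 90%; (4) recover the original sequence and, at
every recovered CpG, the two strand states: the top strand's state from
the C/T of arm 1 at the C position, the bottom strand's from the G/A of
the bottom-frame arm at the G position.

**Fidelity** is the fraction of complete dyads with equal states.
**Window symmetry** slides windows of $w$ adjacent called dyads within
one molecule: a window is *symmetric* when both strands are uniform and
equal, *asymmetric* when both are uniform and opposite; mixed windows
count only in the denominator. At $w = 1$ the symmetric fraction is
identically the fidelity. Under independent per-dyad discordance at
rate $q$ with molecule-level uniform top strands, the asymmetric
fraction at window size $w$ is exactly $q^w$ in expectation — the
signature separating stochastic errors (decaying geometrically) from
genuine subset structure (persisting across windows).

```{r hairpin}
sim <- simulateHairpinPairs(nMolecules = 100, asymmetryRate = 0.05,
                            conversionFailure = 0, seed = 2)
out <- processHairpinPairs(sim$r1, sim$r2)
methylationFidelity(out$dyads)
windowSymmetry(simulateDyads(nMolecules = 20000, seed = 3), 2)$asymmetricFraction
```

# Down-sampling normalization

pCSM frequencies are depth-dependent (deeper segments are more likely
to contain both extreme reads), so cross-sample comparisons down-sample
each common segment (covered ≥ 10× in all samples) to the segment's
minimum depth $D_{\min}$, 100 times, and record the fraction of repeats
in which the segment is (pre)filter-detected — the *detection
probability*. In prefilter-only mode this probability has a closed
hypergeometric form, used as an exact oracle in the tests.

# Annotation and enrichment

Merged histone peaks are labelled by occupancy precedence (H3K4me3 →
active promoter, split by CGI overlap; else H3K27ac → active enhancer;
else H3K4me1 → poised enhancer). Genes associate with pCSM regions
within 10 kb of their TSS, against a background of genes with any
eligible segment in the same window.

GWAS enrichment counts unique trait SNPs within 100 bp of pCSM regions
extended by 100 bp, against a circular-permutation null: each
chromosome is circularized and all its regions shifted by one shared
uniform offset per iteration (10,000 by default), preserving region
count, lengths and spacing. We implement the joint shift by shifting
the SNPs by the negative offset (equivalent, and free of arc
wrap-around bookkeeping); an exhaustive mode enumerating all $L$ shifts
of a single-chromosome genome provides exact p-values for validation.
P-values use the add-one estimator $(1 + \#\{null \ge obs\}) / (1 + N)$.

# Simulation design

The generators in `R/simulate.R` are first-class, tested code; their
defaults are the study conditions used by the test suite.

* `simulateClusters` — cluster-level generator for the classifier: CSM
  clusters mix two subsets (per-cluster mixing uniform in 0.3–0.7) with
  per-CpG probabilities 0.95/0.05; null clusters use independent
  per-CpG probability 0.5.
* `simulateGenome`/`simulateBulkReads` — read-level pipeline tests.
  CpGs are planted at a chosen density and nowhere else, so the CpG map
  is exact by construction. Pipeline-level tests use densities
  0.04–0.08 and read lengths 120–150 so 4-CpG windows are actually
  covered by single reads; at the default density 0.02 and 100 bp
  reads, 4-CpG co-coverage is rare — a geometry fact, decided before
  the tests were run.
* `simulateDyads`/`simulateHairpinPairs` — molecule-level base states
  (fully methylated or fully unmethylated molecules) with per-dyad
  bottom-strand flips at the asymmetry rate. The molecule-level choice
  is what makes the $q^w$ closed form hold with the all-windows
  denominator, and mirrors bimodally partitioned somatic methylomes.
* Null-calibration geometry for the permutation test: two 500 kb
  chromosomes, 100 regions of 2 kb, 200 null traits of 500 uniform
  SNPs, 199 iterations per trait — chosen so the observed counts take
  many distinct values (the add-one p-value is close to uniform despite
  count discreteness) while staying fast.

# Numerical and engineering choices

* The collapsed Gibbs sampler is Rcpp (`src/dp_gibbs.cpp`), using R's
  own RNG so seeding behaves like R code; ~1,000 clusters classify in
  seconds.
* Depth is capped at 500 reads per cluster (seeded subsample) before
  fitting; beyond that the posterior is effectively saturated.
* Undefined ratios (no eligible segments, no complete dyads, empty
  bins) are `NA`, never silently 0.
* Seeds derive per (segment, sample) via a hash with avalanche rounds,
  so adjacent repeat indices yield uncorrelated streams.

# Limitations

* The classifier sees only 4-CpG segments; longer-range epiallele
  structure is out of scope.
* Imprinted-region exclusion requires an external annotation; unknown
  imprinted loci will surface as false pCSM.
* The DP mixture assumes exchangeable reads within a segment; allele
  dropout or mapping bias violating this is not modelled.
* Exhaustive permutation is only feasible for single-chromosome toys;
  genome-scale p-values are Monte-Carlo with the usual resolution limit
  of $1/(N+1)$.
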