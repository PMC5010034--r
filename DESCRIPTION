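Package: bipolarMeth
Title: Detection of Cell-Subset Specific (Bipolar) DNA Methylation from
    Bulk Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers putative cell-subset specific methylated (pCSM) loci
    from bulk bisulfite sequencing by extracting per-read methylation
    patterns over segments of four neighbouring CpGs, prefiltering for
    concurrent fully methylated and fully unmethylated reads, and
    classifying bipolar clusters with a Dirichlet-process mixture of
    Beta-Binomial components. Also provides hairpin bisulfite read-pair
    reconstruction and methylation fidelity analysis, down-sampling
    normalization of sequencing depth with per-segment detection
    probabilities, regulatory-element annotation from histone marks and
    CpG islands, GWAS-variant enrichment by circular permutation, and a
    synthetic-data generator emulating mixed-cell-subset methylomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    Rsamtools,
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Epigenetics, MethylSeq, Sequencing, Software
VignetteBuilder: knitr
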