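Package: pltraj
Title: De Novo Discovery of Tumour Evolutionary Trajectories with
    Plackett-Luce Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers subsets of tumours that share an evolutionary
    trajectory from allele-specific copy-number profiles and driver-gene
    SNV calls. Segments are classified into SCNA classes conditioned on
    whole-genome duplication (WGD), recurrently altered loci are found by
    an exact binomial scan under genomic filter masks, and each tumour's
    present events are ordered within randomized iterations honouring
    clonal/subclonal, pre/post-WGD and CCF-phylogeny constraints. Mixtures
    of Plackett-Luce ranking models fitted by EM (with an MM inner loop)
    cluster the per-sample orderings, the number of trajectories is chosen
    by lowest median BIC, and aggregate orderings with 95 percent intervals
    summarise each trajectory. Downstream statistics cover event enrichment,
    demographic comparisons, co-occurrence and mutual exclusivity, clonality
    preference, pre-WGD event proportions, copy-number deviation, burden
    metrics and a genomic-instability regression with VIF diagnostics. A
    synthetic-cohort generator with planted trajectory archetypes makes the
    whole pipeline testable without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
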