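Package: sweepscan
Title: Selective Sweep Scans from Phased Haplotypes
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects signatures of recent positive selection in phased
    biallelic SNP data. Implements site-frequency-spectrum statistics
    (nucleotide diversity, Watterson's theta, Tajima's D, Fay and Wu's H)
    in sliding windows, haplotype-homozygosity statistics (EHH, iHS, nSL)
    with frequency-bin standardization, population differentiation
    statistics (Hudson's FST and the population branch statistic), pairwise
    LD r-squared, per-population allele frequency reports, and genome-wide
    empirical p-values with top-quantile cutoffs. Ships a synthetic-data
    generator (Kingman coalescent under the infinite-sites model,
    Balding-Nichols structured populations, injected sweeps) and a VCF +
    panel fixture writer so every stage is verifiable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
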