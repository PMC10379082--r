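Package: radsweep
Title: Population-Genomic Diversity, Differentiation and Selective-Sweep
    Scans from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-variant-calling population genomics for reduced-representation
    (RAD-seq style) SNP data. Reads multi-sample VCFs into a dosage-matrix data
    model; applies the standard hard-filter cascade (site annotations, SNP
    clusters, per-genotype depth masking, missingness and minor-allele
    frequency, exact Hardy-Weinberg tests); computes per-population observed
    and expected heterozygosity, inbreeding coefficients and windowed
    nucleotide diversity; scans population pairs for selective sweeps with
    sliding-window Weir-Cockerham FST, Z(FST) and log2 pi-ratio joint top-5
    percent outlier calling with region merging and gene annotation; estimates
    linkage disequilibrium decay and LD-based effective population size; and
    infers population structure by genotype PCA and maximum-likelihood
    admixture with cross-validation over K. Ships Balding-Nichols and forward
    Wright-Fisher simulators with serialized truth tables so the whole
    pipeline is testable end-to-end against known parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
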