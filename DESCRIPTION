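Package: balsel
Title: Balancing-Selection Scans with Coalescent-Calibrated Neutrality Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting long-term balancing selection from resequencing
    data of a candidate locus and a panel of neutral control regions. Implements
    phased-haplotype alignment handling with amplicon-edge quality filters,
    outgroup polarization and polymorphism/divergence counting; folded and
    unfolded site-frequency spectra with hypergeometric projection to a common
    sample size; Tajima's D, the one-sided Mann-Whitney folded-spectrum test
    against controls (MWUhigh), and the Hudson-Kreitman-Aguade (HKA)
    polymorphism/divergence test; a structured-coalescent simulation engine with
    a three-population out-of-Africa demographic null, recombination, fixed-S
    mutation placement and an outgroup branch calibrated to a target
    SNP-to-fixed-difference ratio, used to obtain empirical p-values; deep
    haplogroup partitioning, diagnostic-SNP detection and rho-statistic TMRCA
    dating calibrated by outgroup divergence time; donor splice-site strength
    scoring with transcript assembly and nonsense-mediated-decay classification;
    and standard-curve allele-specific expression ratios plus standardized
    flow-cytometry statistics. Seeded generators produce synthetic versions of
    every input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
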