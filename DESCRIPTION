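Package: poolfinemap
Title: Fine-Mapping Case-Control Associations from Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-mapping a candidate locus for a binary phenotype
    using pooled high-throughput sequencing of case and control cohorts.
    Implements quality-cutoff calibration from spike-in controls, allele
    frequency rounding to the pool sampling grid, a two-proportion Z-test
    extended with an additive allele-frequency estimation-error variance,
    rare-variant collapsing with one-tail Fisher burden tests, haplotype-level
    association via tag SNPs selected by linkage disequilibrium from a phased
    reference panel, conditional haplotype independence tests, recombinant
    detection, joint logistic validation on individual genotypes, and
    regulatory annotation of candidate variants (conserved-element selection
    and position-weight-matrix binding disruption scores). A synthetic-data
    module generates phased panels, case-control cohorts, pooled frequency
    estimates and spike-in scores with the statistical structure the analysis
    assumes, so the full pipeline can be exercised and validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
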