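Package: gnotoreg
Title: Integrative Regulatory Genomics for Gnotobiotic 2x2 Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the integrative statistical analysis of host
    transcriptional responses to microbiota colonization in a two-genotype by
    two-colonization-state (germ-free vs conventionalized) design: a
    negative-binomial two-group differential test applied to gene and
    regulatory-region counts, four-way differential-set logic and fold-change
    quadrant classification, single-nearest-TSS peak-to-gene association,
    enhancer-state/expression concordance by two-sample Kolmogorov-Smirnov
    tests, condition-specific binding-site comparison and flanking-signal
    profiles, one-to-one ortholog filtering and chaining with hypergeometric
    gene-set enrichment, and errors-in-variables (Deming) regression of paired
    orthologous fold changes with jackknife standard errors and
    slope-comparison tests. A synthetic-data module generates every input the
    pipeline consumes with planted effect structure, so the whole analysis is
    testable without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
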