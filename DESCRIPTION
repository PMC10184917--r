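Package: igem
Title: Geneset-Embedded Joint Non-Negative Matrix Factorization for
    Multi-Omic Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates gene expression and DNA methylation profiles that
    share a subject axis by a joint non-negative matrix factorization in
    which the gene basis is embedded in a fixed geneset design (topics by
    genesets times genesets by genes) and the two omic bases are coupled
    through a sparse gene-CpG interaction graph penalty. Provides the
    multiplicative-update solver with restarts and rank diagnostics, the
    surrounding feature-selection and normalization pipeline (differential
    filters, recursive geneset merging, interaction-graph construction),
    topic-phenotype association statistics with false-discovery control,
    genotype quality control with an exact Hardy-Weinberg test, cis-QTL
    scans under additive and major-allele-presence codings, and a synthetic
    multi-omic cohort generator with planted ground truth for recovery and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    ape,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
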