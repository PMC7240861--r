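Package: avnrtwes
Title: Case-Control Whole-Exome Rare-Variant Prioritization for AVNRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for case-control whole-exome rare-variant
    prioritization as applied to atrioventricular nodal reentrant
    tachycardia (AVNRT): qualification of deleterious rare variants at two
    minor-allele-frequency strata, gene-based carrier-collapsing Fisher
    exact burden tests, single-variant allelic association with QC and
    genomic-inflation diagnostics, hypergeometric pathway
    over-representation with rich factors, dual-network protein-protein
    interaction gene ranking, and external cross-cohort variant-overlap
    validation.  A bundled synthetic-cohort generator with planted
    carrier effects makes every stage testable without access to
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
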