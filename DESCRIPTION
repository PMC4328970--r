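Package: coexmod
Title: Weighted Gene Coexpression Modules, Cross-Condition Preservation,
    and Coding-Sequence Selection Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds weighted gene coexpression networks from developmental
    tag-count (digital gene expression) profiles, detects coexpression
    modules by topological-overlap clustering, compares module membership
    between two independently built networks (e.g. two breeds) to call
    preserved and condition-specific modules and their hub genes, and
    screens module genes for selection pressure via Nei-Gojobori Ka/Ks
    estimation on group consensus coding sequences derived from SNP
    tables. Includes a synthetic-data generator that plants known module
    structure in overdispersed count matrices and known substitution
    patterns in coding alignments, so the whole pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    ape,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
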