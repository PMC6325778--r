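Package: mrith
Title: Multi-Region Intratumor Heterogeneity and ctDNA Concordance Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying intratumor heterogeneity (ITH) from
    multi-region somatic variant calls in non-small-cell lung cancer
    cohorts: trunk/branch classification of mutations by sharing across
    tumor regions, an ITH index, per-patient maximum-parsimony phylogenies
    with mutation-count branch lengths, driver/passenger and
    oncogene/tumor-suppressor composition of the trunk and branch
    compartments, a per-gene driver-dominance score, and trunk-versus-branch
    detection concordance in matched circulating tumor DNA (ctDNA).
    Includes a clonal-evolution and ctDNA-detection simulator with full
    ground truth so every pipeline stage can be validated without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
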