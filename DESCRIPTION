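Package: strucpower
Title: Power and Stratification Correction for Case-Control Studies with
    Shared Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis of case-control genetic association studies
    that reuse external or shared controls in structured populations. Implements
    the generalized Bourgain retrospective association test (generalized least
    squares with a marker-estimated, eigen-smoothed kinship matrix and a Wald
    chi-square statistic), method-of-moments kinship estimation with
    Tracy-Widom eigenvalue significance, closed-form and matrix-based
    non-centrality-parameter and power calculators under Balding-Nichols
    population models (isolated, completely admixed, and beta-heterogeneous
    admixed populations), and a genotype simulator that makes every component
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    vcfR,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
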