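Package: sutox
Title: Quantification of Loss-of-Function Mutation Rates from Sucrose
    Counterselection Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying loss-of-function (LOF) mutation rates in
    synthesized DNA from sucrose counterselection (sacB) colony-count data.
    Normalizes colony-forming-unit counts for dilution and plating fraction,
    subtracts negative-control background, applies a half-count convention
    for replicates below the detection limit, derives DNA doublings from
    input and output masses, and estimates LOF mutation rates per doubling,
    per base pair, and as percent per kilobase. Includes fold-change and
    many-to-one group comparisons (one-way ANOVA with Dunnett contrasts), a
    construct-level LOF-risk calculator for gene-therapy payloads, and a
    seeded forward simulator of the whole assay (branching replication with
    absorbing LOF mutation, Poisson plating, background colonies) so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
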