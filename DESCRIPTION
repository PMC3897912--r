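Package: kwscan
Title: Matrix-Based Kruskal-Wallis Association Scans for eQTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous computation of the Kruskal-Wallis rank test for
    every marker-trait pair of an expression quantitative trait locus (eQTL)
    dataset by sparse indicator-matrix multiplications.  Handles missing
    genotype and expression values, tied observations (with the standard
    tie correction), memory-bounded marker slicing, chi-squared p-values
    above a significance cutoff, permutation-based empirical false discovery
    rates, cis-window annotation and classification of associations into
    skewed / non-linear / other types.  Includes a synthetic panel generator
    with Hardy-Weinberg genotypes and planted additive, dominant and
    heterozygote-outside effects for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
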