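Package: rvburden
Title: Gene-Based Rare-Variant Burden Tests via Baseline Mutation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects genes with an excess burden of rare variants in
    sequenced patients by comparing each gene's observed weighted
    rare-allele count against a baseline predicted from genomic features.
    The baseline is a left-truncated negative-binomial regression on eight
    gene-level predictors (coding length, reference-population frequency
    score, their interaction, gnomAD-style constraint ratios and mutation
    rates, and exon GC content), refit recursively after excluding
    significant genes so that putative susceptibility genes do not inflate
    the background. Deviance residuals from the converged model are
    standardized and converted to one-sided P-values. Includes variant-level
    preparation (QC, rarity and case-enrichment filters, functional-score
    weighting), a grid search over the weighting bin and truncation point,
    a synthetic-data generator with matching statistical structure, and a
    chi-squared case-control burden comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
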