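Package: mucimin
Title: Model-Driven Minimal-Medium Design and Growth Phenotype Analysis
    for Akkermansia muciniphila
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based analysis of Akkermansia muciniphila amino-sugar
    metabolism supporting the design of a defined minimal medium. Provides a
    compact flux balance analysis (FBA) and flux variability analysis (FVA)
    engine over genome-scale metabolic models read from SBML or tab-separated
    tables, model curation with replayable logs (the v1 to v2 adjustment that
    removes the spurious GlmS reaction and adds a UDP-GlcNAc 4-epimerase),
    medium-to-exchange-bound translation with nutrient essentiality and
    uptake scans, and the accompanying experiment analyses: specific growth
    rates from OD600 curves, acetate to propionate short-chain fatty acid
    ratios from fermentation time series, and NagB Michaelis-Menten kinetics
    by double-reciprocal and nonlinear fitting. Seeded synthetic-data
    generators (toy metabolic networks including an amino-sugar core, growth
    curves, fermentation series, enzyme assays) make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
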