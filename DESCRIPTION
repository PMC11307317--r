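Package: calorimix
Title: Growth Kinetics, Stability and Metabolic Exchange of Defined Gut
    Bacterial Consortia from Isothermal Microcalorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serially passaged anaerobic gut
    bacterial consortia monitored by isothermal microcalorimetry (IMC).
    Transforms heat-flow measurements into cumulative heat, segments
    polyphasic growth with exact dynamic-programming changepoint
    regression and estimates phase-specific growth rates; normalizes 16S
    read counts by rRNA gene copy number and deconvolves consortium heat
    into per-strain growth curves; quantifies passage-to-passage
    stability and resilience of the community with principal component
    analysis of heat-flow curves; compares endpoint metabolite production
    between consortia and stacked monocultures; and screens
    substrate essentiality with constraint-based metabolic modeling
    (flux balance and variability analysis on genome-scale models read
    from JSON or SBML-fbc). A multi-strain Monod batch simulator with
    growth-associated heat release, serial 1 percent passaging,
    adaptation drift, multinomial read sampling and endpoint metabolite
    noise generates all input data types for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
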