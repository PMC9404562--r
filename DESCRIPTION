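Package: succscreen
Title: Flux-Balance Screening of Succinate-Consuming Gut Bacteria and
    Cohort Association Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An in silico discovery pipeline for succinate-consuming gut
    bacteria. Reads genome-scale metabolic models in a compact COBRA-style
    JSON dialect and growth media as TSV, solves flux balance analysis
    (FBA), flux variability analysis (FVA) and parsimonious FBA linear
    programs with a built-in deterministic simplex solver, and runs an
    iterated nutrient-limitation phenotypic screen (plus a western-diet
    gut-condition simulation) that classifies each organism as a succinate
    consumer, producer or neither. Also provides the upstream marker-gene
    candidate filter (homology thresholds and pathogenicity/habitat
    blocklists) and the downstream clinical-association arm: Kendall
    tau-b correlation with tie-corrected and exact p-values, Dirichlet
    Monte Carlo centered log-ratio transformation for taxa counts, and
    insulin-sensitivity (M-value) multiple regression reports, together
    with seeded generators for toy metabolic models and synthetic patient
    cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
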