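Package: mixoniche
Title: Trophic-Niche Analysis of Small Marine Eukaryotes from 18S Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the prevalence and environmental niche of
    phago-mixotrophic, autotrophic and heterotrophic small eukaryotes from
    18S rRNA gene metabarcoding surveys. Corrects gene abundances to cell
    abundances with group-specific rRNA copy-number models, annotates
    lineages with trophic modes using rank-fallback lookup, computes
    per-sample trophic indices, relates them to environmental gradients
    (principal components, additive-model smoothers, single-variable and
    stepwise regressions, Hellinger-transformed redundancy analysis with
    Escoufier species selection), and estimates growth, ingestion and
    clearance rates from grazer-prey batch-culture time series. A seeded
    synthetic-data generator provides communities, environmental tables,
    copy-number calibrations and culture dynamics with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
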