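Package: foramshift
Title: Compositional Change, No-Analogue Detection and Diversity
    Gradients in Planktonic Foraminifera Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for millennial-scale planktonic foraminifera
    assemblage time series. Computes Morisita-Horn compositional
    dissimilarities and their principal-component reduction with RGB
    visualisation on time-by-latitude (Hovmoller) grids, per-site
    compositional trends (PC1) with polarity alignment and a stacked LOESS
    summary, identity-aware species gains and losses with linear rates of
    change, no-analogue assemblage detection against a Last Glacial Maximum
    reference using self-referential null thresholds, and the evolution of
    the latitudinal diversity gradient from richness and Shannon entropy.
    Includes a synthetic assemblage generator with temperature-controlled
    Gaussian niches and multinomial count noise for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
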