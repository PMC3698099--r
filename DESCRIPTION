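Package: tcmepi
Title: Chromatin-Modifying Potential of Traditional Chinese Medicinals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A materia-medica-wide analysis pipeline linking the traditional
    annotations of Chinese medicinals (seven-grade cold-hot nature, yin-yang
    flavors) to their predicted modulation of 18 histone/DNA modification
    attributes and the resulting chromatin state. Provides quantitative
    nature/flavor/yin-yang scoring, Moran's I phylogenetic autocorrelation of
    the scores with inverse cophenetic-distance weights, chemical-protein
    interaction mapping to per-attribute modification potencies, chromatin
    condensing/unpacking/poising classification, hierarchical clustering of
    potency profiles, a resampling null for herbal-formula synergy, and a
    seeded synthetic-data generator that emulates all required inputs so the
    full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
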