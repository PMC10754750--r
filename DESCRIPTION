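Package: mpsurvey
Title: Microplastic Survey Analysis for Wastewater Sediment and Chironomid Bioindicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-site, four-season microplastic (MP)
    surveys of wastewater sediment and chironomid bioindicators. Provides
    particle- and replicate-level table schemas with strict validation, a
    seeded synthetic-survey generator calibrated to published seasonal
    abundances, shape/colour/polymer compositions and size distributions,
    descriptive summaries (abundance, composition, size-class binning,
    detection rates), the five-equation sediment risk-index stack
    (contamination factor, pollution load index, polymer hazard index,
    toxicity coefficient, potential ecological risk index) with hazard
    category classification, and the field statistics used to compare
    sites, seasons, size classes and larval instars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
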