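Package: mesodose
Title: Meso-Activity Exposure Factors and Incidental Soil Ingestion Doses
    for Agricultural Workers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives time-activity exposure factors from seasonal
    soil-contact activity questionnaires administered to fruit and
    vegetable growers, and estimates average daily doses (ADD) of a
    hypothetical soil contaminant ingested incidentally, using daily,
    hourly, and hourly task-specific soil ingestion rates.  Provides
    empirical (per-grower) and Monte Carlo (simulated population) dose
    estimation, task-specific ingestion-rate scaling driven by reported
    soil-contact fractions, descriptive summaries matching common
    exposure-factor reporting conventions, a questionnaire CSV schema
    with readers and writers, and a synthetic questionnaire-cohort
    generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
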