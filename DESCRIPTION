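Package: genefounder
Title: Gene Age Inference and Gene-Family Founder Events from Homology
    Hit Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers relative gene ages (phylostrata) by taxonomic
    trace-back over tabular homology hit files, scores the taxonomic
    representativeness of each age assignment, collapses taxonomic levels
    lacking genomic representation, groups paralogs into gene families by
    Markov clustering and dates each family by its oldest reliable member,
    and separates true gene-family founder events from homology detection
    failure with a bitscore-decay probability model. Ships a synthetic-data
    generator that emulates the generative assumptions of the method so
    every stage can be tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
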