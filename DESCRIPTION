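Package: ddiscreen
Title: Combinatoric Screening of Drug Combinations for Pairwise
    Interaction-Free Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates all k-drug combinations from a drug universe,
    filters those containing no pairwise drug-drug interaction, condenses
    the surviving hereditary family to its maximal sets, and reports
    inclusion statistics, size distributions, class tallies, and
    allow-list-restricted results. Ships a curated reference dataset of 44
    non-opioid, non-barbiturate headache abortive medications with their
    DrugBank-derived non-interacting sets, a mockable remote interaction
    source contract with a local cache, synthetic interaction-graph
    generators for property testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
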