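Package: threatminer
Title: Keyword-Based Threat Screening of Red List Narratives for an
    Invasive Focal Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the documented threat an invasive focal taxon (by
    default the wild pig, Sus scrofa) poses to biodiversity from a
    Red-List-style corpus of per-taxon threat narratives. A wildcard
    keyword screen builds a manual-review queue; curated verdicts remove
    false positives and out-of-scope mentions; rule tables grade each
    confirmed threat as major, minor or potential and tag its mechanisms
    (predation, disturbance, disease risk, competition, hybridization);
    taxa are stratified by biogeographic region, island endemism and the
    focal species' native versus non-native range; and descriptive
    summaries (counts, proportions, means and standard deviations) are
    assembled into a validated report. A seeded synthetic-corpus
    generator with ground truth makes the full pipeline testable without
    redistributing Red List assessments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
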