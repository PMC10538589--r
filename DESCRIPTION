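Package: oradex
Title: Rule-Based Extraction of Opioid-Related Adverse Drug Events from
    Discharge Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for opioid pharmacovigilance from
    free-text hospital discharge summaries. Locates the narrative sections
    where adverse events are documented, segments clinical prose into
    sentences robust to abbreviations and de-identification placeholders,
    matches opioid drugs, trigger phrases, reversal agents and adverse-event
    terms against packaged lexicons, links drugs to events with a
    trigger-phrase rule and an antidote (naloxone) rule over a +/-3-sentence
    context window, flags known false-positive patterns (pain-indication
    pairs, medication switches, negated mentions), normalizes events to a
    MedDRA-style vocabulary, and scores output against gold labels. Includes
    a synthetic discharge-summary generator with exact gold annotations so
    every stage is testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
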