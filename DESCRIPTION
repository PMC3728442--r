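Package: dxbias
Title: Detection of Cognitive Heuristics and Biases in Diagnostic Reasoning Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based detection of cognitive heuristics and biases
    (anchoring, availability, confirmation, gambler's fallacy,
    representativeness, search satisficing, and over/underconfidence) in
    event logs of clinicians diagnosing cases. Provides a domain
    knowledge-base container with support/refute relations and taught
    finding-diagnosis pairs, a session-log parser and replay evaluator, a
    case-sequence designer that embeds availability and gambler's-fallacy
    opportunity sub-sequences, eight deterministic pattern classifiers over
    evaluated sessions, a feeling-of-knowing confidence bias score, a
    synthetic clinician simulator with injectable ground-truth bias
    behaviour, and frequency/association reporting with opportunity-aware
    denominators and nonparametric group comparisons.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
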