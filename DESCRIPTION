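Package: rxnforge
Title: Template-Based Generation and Evaluation of Fictive Chemical Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for augmenting chemical reaction corpora with fictive
    (template-generated) reactions. Parses atom-mapped reaction SMILES,
    detects reaction centers from atom mapping, extracts radius-0 and
    radius-1 retrosynthesis templates with hierarchical correction, applies
    templates in the retro and forward directions, tags changed atoms in
    starting materials with a "!" token, validates candidate reactions
    through a pluggable forward predictor behind a confidence-score gate,
    equilibrates datasets per template, and evaluates round-trip accuracy
    (RTA) and template-averaged round-trip accuracy (TA-RTA). Includes a
    self-contained toy-chemistry fixture generator so the whole pipeline is
    testable without external reaction data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
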