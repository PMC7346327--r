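Package: experia
Title: Patient Experience Evidence for Clinical Decision Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines feature-level opinions from part-of-speech tagged patient
    reviews by seed-lexicon polarity propagation over a synonym/antonym
    graph, stores the mined opinions as Clinical Sentiment Ontology
    individuals in an RDF (Turtle) Patient Experience Knowledge Base, and
    runs a k-nearest-neighbour experience inference engine that matches a
    query patient's clinical conditions and visual-analogue-scale preference
    vector against stored cases to re-rank an ordered list of objective
    candidate clinical decisions. Ships a synthetic-data generator (tagged
    review corpora with planted opinions, case bases with planted preference
    archetypes) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
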