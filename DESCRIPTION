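Package: eventmodels
Title: Event Segmentation, Episodic Markers, and Mental-Model Temporal Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A computational engine for event cognition: online segmentation
    of a symbolic observation stream (goals, locations, persons, objects)
    into discrete episodic markers, an activation-based episodic store with
    decay and spreading, retrospective construction of event models
    (veridical and goal-prioritized bounded partonomies of durational and
    punctate events on an ordinal timeline), and mental-model temporal
    inference over those models, including multi-model indeterminacy
    (necessary / possible / impossible verdicts) and counterfactual
    revision. Includes a scenario generator with ground truth, JSONL/JSON
    interchange formats, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
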