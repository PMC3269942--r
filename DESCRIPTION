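Package: genorm
Title: Multi-Stage Gene Normalization for Full-Text Articles with TAP-k Evaluation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping gene and protein mentions in structured
    full-text articles to unique database identifiers. Implements a
    three-stage, memory-based normalization procedure that exploits the
    information gradient across article sections, dictionary matching with
    orthographic variant generation and inverted-index partial matching,
    rule-based weighted-vote disambiguation, context-based species filtering
    with static and dynamic dictionary-entry selection strategies, a linear
    ranking model over section-aware features, the threshold average
    precision (TAP-k) evaluation metric, and a deterministic synthetic-corpus
    generator for end-to-end testing without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
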