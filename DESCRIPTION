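Package: thyscore
Title: Subtype Scoring and Literature Profiling of Thyroid Cancer Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies biomedical abstracts into thyroid cancer
    histopathological subtypes (papillary, anaplastic, follicular,
    medullary) with a keyword-decomposition scoring scheme: subtype names
    are dissociated into subtype, anatomy and malignancy keywords,
    sentence-level relevance scores are accumulated with positional
    weights, and per-subtype thresholds assign document labels. Ranks
    genes and pathways per subtype by summing document score vectors over
    entity mentions, evaluates predictions against a gold standard with
    per-subtype and micro-averaged precision/recall/F1, and generates
    synthetic corpora with planted subtype mentions for end-to-end
    testing. Reads MEDLINE-format and JSON-lines corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
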