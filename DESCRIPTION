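Package: citesnow
Title: Automatic Citation Snowballing for Literature Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic citation snowballing: locating the reference
    section of a plain-text scholarly article, segmenting it into individual
    citation strings, normalizing each string into a search query, resolving
    queries against a bibliographic index with rarity-weighted token matching,
    following links to full text or abstracts with a failure taxonomy, and
    recursing breadth-first over newly retrieved documents to build a citation
    graph. Includes an evaluation harness that computes precision, recall and
    F1 per pipeline stage across three gold-standard denominators, and a
    seeded synthetic-corpus generator (bibliographic index, rendered articles,
    retrieval fixtures, gold standard) so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
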