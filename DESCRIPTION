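Package: accmine
Title: Mining Database Accession-Number Citations from Full-Text Articles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects citations of biological database records (European
    Nucleotide Archive, UniProt, Protein Data Bank, and extension databases
    such as Pfam, InterPro, Ensembl and ArrayExpress) in full-text JATS/NLM
    XML articles. Implements a three-step, high-precision annotation
    pipeline -- article-level contextual gating, sentence-level candidate
    identification with per-database shape grammars and cue words, and
    validation against a database whitelist -- together with extraction of
    publisher-supplied structured ('ext-link') accession citations,
    precision/recall/F-score evaluation against gold standards, corpus-level
    citation analytics (publisher versus text-mined overlap, per-year trends,
    citations per database record, article-database link comparison), and a
    deterministic synthetic JATS corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    tibble,
    xml2,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
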