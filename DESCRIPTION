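Package: patret
Title: Field-Selective Patent Retrieval with BM25/PL2, Co-Citation
    Re-Ranking and IPC Query Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained patent search engine for prior-art and
    technical-survey retrieval over biomedical patent collections.
    Provides readers and writers for a simple patent XML dialect and
    terminology dictionaries, a seeded generator of synthetic patent
    corpora with topical vocabulary clusters and a citation network,
    dictionary-based concept normalization scoped to selected fields,
    an inverted index with Porter stemming and field selection, Okapi
    BM25 and PL2 divergence-from-randomness ranking, co-citation
    re-ranking and IPC code query augmentation, benchmark construction
    (prior-art, known-item), TREC-style run and qrels I/O, retrieval
    metrics (MRR/P0, MAP, P@1) and a paired sign-flip randomization
    test for comparing runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
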