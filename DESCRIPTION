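Package: soxpath
Title: Ontology-Based Query Engineering and XPath Generation for
    Section-Structured XML Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for ontology-based query engineering on
    section-structured XML electronic health records, in the style of the
    Search Ontology XML extension (SOX).  A declarative query model binds
    regex-bearing search terms to nodes of an XML document structure;
    boolean combinations of such bound concepts are compiled to XPath 2.0
    expressions with regular-expression predicates.  Includes an execution
    engine for directory corpora, an independent brute-force matcher used
    as a test oracle, reviewer-support diagnostics for enumeration
    coreference (ECRI) and physical-quantity coreference (PQCRI) false
    positives, quantity extraction and summarisation, and a seeded
    generator of synthetic pathology-report corpora with ground-truth
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
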