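Package: meshcooc
Title: MeSH Descriptor Co-Occurrence Mining of PubMed Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative literature mining of bibliographic records indexed
    with Medical Subject Headings (MeSH). Reads PubMed XML and MEDLINE nbib
    records, filters them by date window, abstract availability and
    affiliation, matches descriptors exactly against curated controlled
    vocabularies (digital-health terminology, diseases, age groups), computes
    occurrence totals, per-year publication trends and record-level binary
    term co-occurrence counts, and builds a typed co-occurrence network with
    first-degree-neighbour subnetwork extraction and Cytoscape-compatible
    GraphML/SIF export. A seeded synthetic corpus generator with closed-form
    expected counts makes every pipeline stage testable without network
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
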