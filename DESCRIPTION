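Package: armpersist
Title: Archetype Relational Mapping for openEHR-Style Clinical Data Persistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates relational database schemas from openEHR-style
    archetypes and templates carrying archetype relational mapping (ARM)
    constraints (identification and query data items, generalized/specialized
    mappings), persists and queries archetype instances through the generated
    schema, and benchmarks the result against a Node+Path (entity-attribute-
    value) reference backend on synthetic clinical workloads covering
    demographics, imaging examinations, and laboratory tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
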