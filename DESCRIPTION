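Package: wdds
Title: Validate, Share, and Simulate Wildlife Disease Surveillance Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with a minimum data standard for wildlife
    disease research and surveillance, in which each row of a flat table is
    one diagnostic-test result on one sample from one (or a pool of) wild
    animal(s). Provides a machine-readable registry of the 40 core fields
    and 24 project-metadata properties; standard-conformant CSV and JSON
    input/output that treats blank cells as first-class missing values;
    a rule-based validator with record-addressed error and warning reports;
    persistent-identifier (DOI, ORCID, ROR) syntax checks; a Darwin Core
    occurrence crosswalk; coordinate obfuscation (truncation and seeded
    jitter) with uncertainty propagation and provenance logging; a linkage
    graph for multi-sample, pooled, and nested host-parasite records; and a
    seeded generator of standard-conformant synthetic surveillance datasets
    with targeted corruptions for validator testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
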