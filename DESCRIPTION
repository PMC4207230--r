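Package: modaudit
Title: Curation Accuracy Auditing for Model Organism Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the accuracy of manually curated biological
    databases. Ingests per-fact validation records (gene, fact, validator
    verdict, citations), applies curator rescoring that separates true factual
    errors from validator mistakes and citation-metadata errors, computes
    initial and final error rates per database and pooled, and quantifies
    uncertainty with a gene-cluster bootstrap that resamples genes with
    replacement and truncates each replicate to the original number of facts.
    A seeded synthetic-data generator emulates the two-stage fact-sampling
    protocol (random genes, up to five facts per gene) so the whole pipeline
    can be exercised without access to the original databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
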