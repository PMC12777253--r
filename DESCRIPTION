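Package: reanalyzr
Title: Phenotype-Driven Bayesian Reanalysis of Trio Variant Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale engine for phenotype-driven genomic reanalysis in
    rare-disease diagnostics. Computes a Bayesian differential diagnosis over
    a curated disease-finding-gene knowledge base from pertinent positive and
    negative clinical findings, ascertains gene zygosities (monoallelic,
    biallelic, X-linked hemizygous, with de novo status and a 0-5 severity
    scale) from annotated trio variant tables, filters variants whose
    population allele frequency exceeds the carrier frequency expected from
    disease incidence, ranks ascertained evidence by a leave-one-out
    pertinence metric, and recommends further tests (including genes absent
    from the variant table) by an expected-change usefulness metric. Includes
    a synthetic trio-cohort simulator with ground truth for benchmarking
    recovery under false de novo noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
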