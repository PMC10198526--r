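Package: molgenfhir
Title: Structured Molecular Genomics Reports as FHIR R4 Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the German Medical Informatics Initiative (MII) molecular
    genomics (MolGen) report standard: a machine-readable registry of the 76-element
    core dataset and its 16 FHIR profiles, a profile-agnostic report model with
    JSON/YAML readers and writers, an HGVS-aware terminology layer, kinship
    decomposition with shared-DNA arithmetic, a FHIR R4 bundle builder and
    declarative profile-conformance validator, an ISO/TS 20428:2017 conformance
    reporter, and a seeded generator of synthetic example reports covering the
    standard's five archetypes (somatic oncology panel, CNV/MSI/TMB, hereditary
    breast and ovarian cancer with family history, rare disease, polygenic risk
    score).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
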