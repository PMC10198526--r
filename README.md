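# molgenfhir

Molecular genomics (MolGen) reports in Germany are still largely exchanged as
unstructured PDFs, which blocks the integration of genomic findings with
phenotype data in electronic health records. The German Medical Informatics
Initiative (MII) addressed this with a core dataset for MolGen reports — **76
data elements clustered into 6 categories** (specimen incl. patient, request,
methods, results, interpretation, miscellaneous) — and a FHIR R4
specification of **16 profiles** (14 aliased core profiles adapted from HL7's
Genomics Reporting Implementation Guide plus Specimen/Patient module
references) with **7 additional SearchParameter definitions**.

`molgenfhir` implements that standard as a reusable R package and CLI for
informaticians at testing laboratories and data integration centres:

* **registry** — the machine-readable 76-element dataset and 16-profile
  registry, with CSV/JSON export (`load_registry()`, `elements_by_category()`,
  `profile_by_alias()`).
* **terminology** — code-system metadata (SNOMED CT, LOINC, ICD-10-GM,
  Alpha-ID, Orphanet, EBM, ISCN under OID `urn:oid:2.16.840.1.113883.6.335`,
  v3.RoleCode), the bound value sets, and a syntactic HGVS validator for
  `c.`/`g.`/`n.`/`p.` expressions (`validate_hgvs()`).
* **report model** — a profile-agnostic report representation with JSON/YAML
  readers, a canonical writer and required-element completeness scoring
  (`read_report()`, `write_report()`, `completeness()`).
* **kinship** — family relationships on three axes (lineage, degree, type)
  with expected shared-DNA fractions following the geometric law
  `shared = 0.5^degree` (first degree 50 %, second degree 25 %, ...):
  `degree_of()`, `decompose_relationship()`, `compose_relationship()`.
* **FHIR builder & validator** — `build_bundle()` emits a collection bundle
  conforming to the registered profiles (detection-limit component on the
  Variant observation, relationship extension on FamilyMemberHistory, EBM
  billing via ChargeItem + workflow-supportingInfo, influence-factor extension
  on the polygenic risk score prediction); `parse_bundle()` inverts it and
  `validate_bundle()` reports structured conformance issues.
* **ISO/TS 20428** — a conformance report mapping dataset elements onto the
  ISO required fields: 30 elements map, 4 required ISO fields (order received
  date, addendum creation date, subject of care ethnicity, medical specialty
  of ordering physician) have no dataset counterpart (`conformance_report()`).
* **synth** — a seeded generator of synthetic, non-clinical example reports
  covering the five archetypes (somatic oncology panel, CNV/MSI/TMB,
  hereditary breast/ovarian cancer with family history, rare disease,
  polygenic risk score): `generate_report()`, `generate_corpus()`.

## Worked example

```r
library(molgenfhir)

r <- generate_report("hboc_germline_family", seed = 7)
r
#> MolGen report MGR-2024-41094 [final]: 1 variant(s), 2 family member(s), 0 risk score(s)

b <- build_bundle(r, seed = 7)
length(b$entry)
#> [1] 13

issues <- validate_bundle(b)
sum(issues$severity == "error")
#> [1] 0

identical(unclass(parse_bundle(b)), unclass(r))   # lossless round trip
#> [1] TRUE

degree_of("grandparent")
#> $degree
#> [1] 2
#> $shared_dna
#> [1] 0.25

conformance_report()$mapped_elements
#> [1] 30
```

The bundle holds 13 resources (Patient, Specimen, Organization, 2
FamilyMemberHistory, ServiceRequest, ChargeItem, Variant/Region-Studied/
Result-Summary/Diagnostic-Implication observations, a follow-up Task and the
single DiagnosticReport tying them together); zero error-severity issues
means every cardinality, binding, slice and HGVS rule of the registered
profiles is met.

A thin CLI wraps the same functions:

```sh
exec/molgen registry dump --format csv
exec/molgen generate --archetype prs_report --seed 5 --out report.json
exec/molgen build report.json --seed 5 --out bundle.json
exec/molgen validate bundle.json          # exit 0 iff conformant
exec/molgen iso-report --format json
```

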