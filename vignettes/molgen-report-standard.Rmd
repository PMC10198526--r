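---
title: "The MolGen report standard: model, profiles and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MolGen report standard: model, profiles and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molgenfhir)
```

## The problem

Molecular genetic test results — variants detected by panel or exome
sequencing following oncological or rare-disease indications — are typically
communicated as free-text reports. To make them computable, the German MII
defined a core dataset for MolGen reports and a FHIR R4 exchange format
adapting HL7's Genomics Reporting Implementation Guide (v2.0.0 element
names). This package implements that standard end to end: registry, report
model, bundle builder, conformance validator, ISO/TS 20428 mapping and a
synthetic-example generator.

## The dataset registry

The registry (`load_registry()`) fixes 76 distinct data elements in six
categories. The printed per-block counts are 11 (specimen characteristics),
5 (patient), 14 (request), 10 (methods), 20 (results), 9 (interpretation) and
8 (miscellaneous), which sum to 77; the headline total is 76. We reconcile
the two by storing exactly one record — the patient/subject reference — once
(specimen category, patient sub-block) while listing it in both the specimen
and request blocks; this is the smallest change satisfying both figures.

The authoritative element enumeration lives in a supplementary table that is
not machine-readable here, so the packaged list is this package's own fixed
enumeration, consistent with every element the standard's running text names
(specimen type/collection/site/additives; name, age, administrative gender;
requester, reason, supporting information, family history, EBM billing;
device, read depth, coverage, detection limit; DNA/genomic/protein changes,
variant origin, variant ID, cytogenetic location; clinical significance,
evidence level, medication assessed/recommended, general recommendations;
report ID, status, issue date, attachments, performer contact). The counts,
not the labels, are the testable surface.

The profile registry holds the 14 aliased core profiles (German name /
English alias pairs) plus two module references — Specimen per the MII
Biobank module and Patient per the MII Person module — for a total of 16.
The "two additional profiles" (FamilyMemberHistory, RiskAssessment) are
carried inside the aliased set with origin `additional`; whether they are
counted inside or outside the 14 cannot be read consistently from the
published material, so this reconciliation is a recorded design choice.
Haplotype is mentioned once in the standard's text but absent from the
profile table; we carry it as an alternate alias of the Genotype profile
rather than a fifteenth aliased profile. EBM billing uses the *unprofiled*
core ChargeItem resource, referenced from the finding report's
workflow-supportingInfo extension; the registry link check therefore accepts
a documented core-resource path (`ChargeItem.code`) alongside
profile-declared paths. The three Task search parameters serve both the
Recommended Follow-Up and Medication Recommendation profiles; to keep the
stated total of seven definitions with one owner each, they are attached to
Recommended Follow-Up.

## Terminology and HGVS

All terminology checks run from packaged data; there is no terminology
server and no network access. Full SNOMED CT/LOINC content cannot be
bundled, so value-set membership validates the code *system* plus, where the
standard names the answers, a small explicit member list (variant origin,
clinical significance, allelic state, MSI status, qualitative risk). EBM
codes are validated by shape only (five-digit fee schedule positions).
Binding strengths are not printed in the source material; we treat bindings
as `extensible` (warning on miss) except where the terminology is described
as required or where the value list is closed, which are `required` (error
on miss).

`validate_hgvs()` implements an explicit grammar subset: substitutions,
del/dup/ins/delins at the `c.`/`g.`/`n.` levels with optional RefSeq/LRG
prefixes and intronic/UTR offsets, and three-letter substitutions,
frameshifts (`fs`, `fsTer#`), stop gains (`Ter`) and in-frame del/dup at the
`p.` level. RNA (`r.`) descriptions, mosaicism, complex rearrangements and
one-letter amino-acid codes are deliberately outside the subset and return
`valid = FALSE` with a reason — mirroring the standard's own deferral of
complex variants. The function never raises on arbitrary non-empty text and
is invariant under surrounding whitespace.

## Kinship

Family relationships are coded on three axes — lineage (maternal/paternal),
degree, relationship type — because reporting sites differ in whether they
record one combined concept or three components. Shared-DNA expectations
follow the geometric law `0.5^degree` (50 % first degree, 25 % second
degree); identical twins and X-linked sharing, which break the law, are out
of scope. Degree assignments beyond the stated first/second degree follow
standard consanguinity tables (half-sibling 2, first cousin 3,
great-great-grandparent 4). SNOMED CT offers degree concepts only for first
and second degree, so `compose_relationship()` emits a textual degree
annotation for degrees three and four instead of a degree concept. The
concrete SNOMED axis codes are not reproduced in the published material;
packaged codes carry the correct code systems but are marked synthetic in
the data file and are replaceable via configuration.

## The report model and units

The internal model mirrors the six categories and is deliberately
profile-agnostic. JSON and YAML are accepted on input; output is canonical
key-sorted JSON with unset optional fields omitted, so deep-equal reports
serialize byte-identically and `read_report(write_report(r))` is the
identity. Unknown keys are collected and reported (warning +
`unknown_keys` attribute), never silently dropped.

Numeric conventions: detection limits are stored as dimensionless fractions,
with percentage inputs (values in (1, 100]) normalized on read; allele
fractions must already lie in [0, 1] — a value like 1.7 is rejected rather
than guessed at. Both birth date and age are accepted for the patient;
birth date is preferred and age rides in a dedicated extension. The
interpretation element is named `medication_assessed`; the source material
once prints "medication accessed", which we read as a typographical variant.

`completeness()` scores populated required elements against the registry's
requirement flags. Requirement levels are not printed per element; the
packaged flags mark 24 elements required (identifiers, status/intent/code of
the request, patient demographics, specimen type and collection date, test
method and device, gene and variant origin, clinical significance, report
identifier/status/issue date, performing laboratory, and the EBM billing
code, which the German use case mandates).

## Bundle building and validation

`build_bundle()` emits a `collection` bundle with `urn:uuid` entry URLs
drawn from a seeded generator: identical report + identical seed gives a
byte-identical bundle. A `document` bundle was not chosen because the
profile set contains no Composition resource. Extension canonicals default
to a configurable placeholder base URI (`molgen_config()`), since published
canonical URLs exist for profiles but not extensions. Attachments route by
MIME type: members of a configurable "file-like" set (VCF and similar) go to
the `genomics-file` extension, everything else to `DiagnosticReport.media`.
The detection limit is an added `Observation.component` on the Variant
profile with a percent-unit quantity. Assay-level method characteristics
(method, device, read depth, coverage, primers, reference assembly) ride on
the first Variant observation, which is also where the standard maps them.

`validate_bundle()` checks the packaged declarative rules per profile-tagged
resource: min/max cardinality, fixed codings, bindings (required → error,
extensible → warning), the condition-code slice (SNOMED CT / ICD-10-GM /
Alpha-ID / Orphanet), syntactic HGVS on variant components, fraction and
percent ranges, the ISCN system on cytogenetic locations, EBM shape on
ChargeItem, referential closure, and must-support presence — reported at
information level, never as errors, because the standard could not make
those elements mandatory. Unknown extensions and unprofiled resources are
tolerated (FHIR's open-world reading). Validation is self-contained by
design; an external FHIR validator can serve as a secondary oracle but is
not shelled out to. Issue order is deterministic (entry index, then path,
then rule), and rule ids are stable
(`<profile>/<path>/<kind>`), which the mutation-detection suite relies on.

## ISO/TS 20428 mapping

The ISO field list is licensed and the standard's own mapping table is not
machine-readable, so the packaged table is constructed to the stated
surface: 30 dataset elements map onto required ISO fields (many-to-one
mappings allowed) and exactly four required fields — order received date,
addendum creation date, subject of care ethnicity, medical specialty of the
ordering physician — have no dataset counterpart. The table is a replaceable
CSV. `check_report_against_iso()` additionally evaluates a concrete report
instance: a required field is satisfied when at least one mapped element is
populated; the four gaps are flagged as structural, not instance, gaps.

## The synthetic generator

`generate_report()` emulates the five example archetypes the standard's
example bundles cover. Defaults are chosen to match a typical report of each
kind: 2 somatic variants for the oncology SNV panel, a CNV plus MSI-high
status and a tumor mutational burden drawn uniformly from 4–40 mutations/Mb
for the CNV/MSI/TMB report, 1 germline BRCA-pathway variant plus 2 family
members for the hereditary breast/ovarian report, 1 variant plus phenotype
references for the rare-disease report, and a probability-type risk score in
0.05–0.6 with an ethnicity influence factor for the PRS report. Variant
content comes from a small curated catalogue of internally consistent
c./p./g. HGVS triples on well-known genes; names and dates come from neutral
pools. Everything is labelled synthetic and non-clinical.

The generator emulates the structure and coding of real MolGen reports, not
their statistics: variant frequencies, organ distributions and laboratory
heterogeneity are not modelled. Passing tests therefore demonstrate
structural and terminological conformance of the pipeline, not robustness to
the messiness of real-world report content. Five golden bundles (one per
archetype, fixed seeds) are packaged and must regenerate byte-identically;
the test corpus uses one report per archetype per run, which keeps the whole
suite under ten seconds while still exercising every profile.

## Known limitations

Gene-expression/FISH results, RNA fusion detail and bioinformatics-pipeline
provenance are out of scope, as they are in the current standard. The HGVS
subset excludes complex rearrangements. SNOMED kinship axis codes are
placeholders pending the requested third/fourth-degree concepts. The
validator implements the packaged declarative rules, not full FHIRPath
invariant evaluation, and code membership beyond the packaged lists is
checked at the system level only.
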