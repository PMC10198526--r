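# Fixtures built in code: a minimal report document, a fully populated
# report, and small bundle-manipulation helpers shared across test files.

minimal_report_doc <- function() {
  jsonlite::toJSON(list(
    patient = list(name = list(family = "Muster", given = list("Alex")),
                   birth_date = "1970-01-01", gender = "female",
                   identifier = "PID-000001"),
    request = list(id = "REQ-1", status = "completed", intent = "order",
                   reasons = list(list(system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
                                       code = "C50.9"))),
    results = list(variants = list(list(
      gene = list(system = "http://www.genenames.org", code = "BRAF", display = "BRAF"),
      dna_change_c = "NM_004333.4:c.1799T>A", origin = "somatic"))),
    misc = list(status = "final")
  ), auto_unbox = TRUE)
}

# Populates every registry element (required and optional).
full_report <- function(seed = 3) {
  r <- generate_report("hboc_germline_family", seed = seed, include_prs = TRUE)
  r <- unclass(r)
  r$specimen$method <- list(system = "http://snomed.info/sct", code = "129314006",
                            display = "Biopsy")
  r$specimen$conditions <- list(list(system = "http://snomed.info/sct",
                                     code = "119376003", display = "Tissue specimen"))
  r$specimen$parent_id <- "SP-PARENT-1"
  r$specimen$body_site <- list(system = "http://snomed.info/sct", code = "76752008",
                               display = "Breast structure")
  r$request$reason_phenotypes <- "Phenotypic feature: familial breast cancer"
  r$request$supporting_info <- "Prior pathology report PATH-2023-551"
  r$specimen$notes <- "Specimen of adequate quality"
  r$methods$primer <- "Custom panel primer set v3"
  r$methods$notes <- "Library prep per standard protocol"
  r$results$variants[[1]]$variant_type <- "snv"
  r$results$variants[[1]]$copy_number <- 2
  r$results$variants[[1]]$exact_start <- 43124027
  r$results$variants[[1]]$exact_end <- 43124028
  r$results$msi_status <- "stable"
  r$results$mutational_burden <- 3.2
  r$results$genotype <- "BRCA1 c.68_69del heterozygous carrier"
  r$interpretation$medication_assessed <- "Olaparib"
  r$interpretation$medication_recommendation <- "PARP inhibitor eligibility review"
  r$interpretation$therapeutic_implication <- "Predicted PARP inhibitor sensitivity"
  r$patient$age <- 52
  do.call(molgen_report, r)
}

bundle_entries <- function(bundle) bundle$entry

entry_index_of <- function(bundle, profile_id) {
  profs <- vapply(bundle$entry, molgenfhir:::mg_entry_profile, character(1))
  which(profs == profile_id)[1]
}

entry_index_of_type <- function(bundle, rtype) {
  types <- vapply(bundle$entry, function(e) e$resource$resourceType, character(1))
  which(types == rtype)[1]
}

modify_resource <- function(bundle, profile_id, fn) {
  i <- entry_index_of(bundle, profile_id)
  stopifnot(!is.na(i))
  bundle$entry[[i]]$resource <- fn(bundle$entry[[i]]$resource)
  bundle
}

drop_component <- function(obs, slice) {
  reg <- load_registry()
  want <- reg$component_slice_codes[[slice]]
  obs$component <- Filter(function(cm) {
    cd <- cm$code$coding[[1]]
    !(identical(cd$code, want$code) && identical(cd$system, want$system))
  }, obs$component)
  obs
}

set_component_value <- function(obs, slice, value) {
  reg <- load_registry()
  want <- reg$component_slice_codes[[slice]]
  obs$component <- lapply(obs$component, function(cm) {
    cd <- cm$code$coding[[1]]
    if (identical(cd$code, want$code) && identical(cd$system, want$system)) {
      cm <- cm[c("code")]
      cm <- c(cm, value)
    }
    cm
  })
  obs
}

# Catalogue of seeded single-rule bundle corruptions. Each entry names the
# base archetype, a mutation of a conformant bundle and the rule expected to
# fire with error severity.
mutation_catalog <- function() {
  list(
    list(name = "drop report status", archetype = "hboc_germline_family",
         rule = "molgen-finding-report/DiagnosticReport.status/card-min",
         fn = function(b) modify_resource(b, "molgen-finding-report", function(r) { r$status <- NULL; r })),
    list(name = "drop report identifier", archetype = "hboc_germline_family",
         rule = "molgen-finding-report/DiagnosticReport.identifier/card-min",
         fn = function(b) modify_resource(b, "molgen-finding-report", function(r) { r$identifier <- NULL; r })),
    list(name = "drop issue date", archetype = "hboc_germline_family",
         rule = "molgen-finding-report/DiagnosticReport.issued/card-min",
         fn = function(b) modify_resource(b, "molgen-finding-report", function(r) { r$issued <- NULL; r })),
    list(name = "drop report performer", archetype = "hboc_germline_family",
         rule = "molgen-finding-report/DiagnosticReport.performer/card-min",
         fn = function(b) modify_resource(b, "molgen-finding-report", function(r) { r$performer <- NULL; r })),
    list(name = "drop testing reason", archetype = "hboc_germline_family",
         rule = "request/ServiceRequest.reasonCode/card-min",
         fn = function(b) modify_resource(b, "request", function(r) { r$reasonCode <- NULL; r })),
    list(name = "drop requester", archetype = "hboc_germline_family",
         rule = "request/ServiceRequest.requester/card-min",
         fn = function(b) modify_resource(b, "request", function(r) { r$requester <- NULL; r })),
    list(name = "drop request intent", archetype = "hboc_germline_family",
         rule = "request/ServiceRequest.intent/card-min",
         fn = function(b) modify_resource(b, "request", function(r) { r$intent <- NULL; r })),
    list(name = "drop patient gender", archetype = "hboc_germline_family",
         rule = "patient/Patient.gender/card-min",
         fn = function(b) modify_resource(b, "patient", function(r) { r$gender <- NULL; r })),
    list(name = "drop patient birth date", archetype = "hboc_germline_family",
         rule = "patient/Patient.birthDate/card-min",
         fn = function(b) modify_resource(b, "patient", function(r) { r$birthDate <- NULL; r })),
    list(name = "drop specimen type", archetype = "hboc_germline_family",
         rule = "specimen/Specimen.type/card-min",
         fn = function(b) modify_resource(b, "specimen", function(r) { r$type <- NULL; r })),
    list(name = "drop gene component", archetype = "hboc_germline_family",
         rule = "variant/Observation.component:gene-studied/card-min",
         fn = function(b) modify_resource(b, "variant", function(r) drop_component(r, "gene-studied"))),
    list(name = "drop variant origin", archetype = "hboc_germline_family",
         rule = "variant/Observation.component:variant-origin/card-min",
         fn = function(b) modify_resource(b, "variant", function(r) drop_component(r, "variant-origin"))),
    list(name = "truncated coding HGVS", archetype = "hboc_germline_family",
         rule = "variant/Observation.component:dna-chg/hgvs",
         fn = function(b) modify_resource(b, "variant", function(r)
           set_component_value(r, "dna-chg", list(valueCodeableConcept = list(coding = list(
             list(system = "http://varnomen.hgvs.org", code = "c.76A>"))))))),
    list(name = "malformed protein HGVS", archetype = "hboc_germline_family",
         rule = "variant/Observation.component:amino-acid-chg/hgvs",
         fn = function(b) modify_resource(b, "variant", function(r)
           set_component_value(r, "amino-acid-chg", list(valueCodeableConcept = list(coding = list(
             list(system = "http://varnomen.hgvs.org", code = "p.Val600"))))))),
    list(name = "family condition coded in LOINC", archetype = "hboc_germline_family",
         rule = "family-medical-history/FamilyMemberHistory.condition.code/slice-systems",
         fn = function(b) modify_resource(b, "family-medical-history", function(r) {
           r$condition[[1]]$code$coding[[1]]$system <- "http://loinc.org"
           r
         })),
    list(name = "relationship outside permitted schemes", archetype = "hboc_germline_family",
         rule = "family-medical-history/FamilyMemberHistory.relationship/binding",
         fn = function(b) modify_resource(b, "family-medical-history", function(r) {
           r$relationship$coding[[1]]$system <- "http://loinc.org"
           r
         })),
    list(name = "dangling result reference", archetype = "hboc_germline_family",
         rule = "bundle/reference-closure",
         fn = function(b) modify_resource(b, "molgen-finding-report", function(r) {
           r$result[[1]]$reference <- "urn:uuid:00000000-dead-beef-0000-000000000000"
           r
         })),
    list(name = "allele fraction above one", archetype = "hboc_germline_family",
         rule = "variant/Observation.component:sample-allelic-frequency/fraction-range",
         fn = function(b) modify_resource(b, "variant", function(r)
           set_component_value(r, "sample-allelic-frequency",
                               list(valueQuantity = list(value = 1.7, unit = "1"))))),
    list(name = "detection limit above 100 percent", archetype = "hboc_germline_family",
         rule = "variant/Observation.component:detection-limit/percent-range",
         fn = function(b) modify_resource(b, "variant", function(r)
           set_component_value(r, "detection-limit",
                               list(valueQuantity = list(value = 150, unit = "%"))))),
    list(name = "cytogenetic location off ISCN", archetype = "hboc_germline_family",
         rule = "variant/Observation.component:cytogenetic-location/system-fixed",
         fn = function(b) modify_resource(b, "variant", function(r)
           set_component_value(r, "cytogenetic-location", list(valueCodeableConcept = list(coding = list(
             list(system = "http://loinc.org", code = "17q21.31"))))))),
    list(name = "variant observation code changed", archetype = "hboc_germline_family",
         rule = "variant/Observation.code/fixed-value",
         fn = function(b) modify_resource(b, "variant", function(r) {
           r$code$coding[[1]]$code <- "12345-6"
           r
         })),
    list(name = "EBM code malformed", archetype = "hboc_germline_family",
         rule = "chargeitem/ebm-shape",
         fn = function(b) {
           i <- entry_index_of_type(b, "ChargeItem")
           b$entry[[i]]$resource$code$coding[[1]]$code <- "ABC"
           b
         }),
    list(name = "clinical significance off answer list", archetype = "hboc_germline_family",
         rule = "diagnostic-implication/Observation.component:clinical-significance/binding",
         fn = function(b) modify_resource(b, "diagnostic-implication", function(r)
           set_component_value(r, "clinical-significance", list(valueCodeableConcept = list(coding = list(
             list(system = "http://loinc.org", code = "LA0000-0"))))))),
    list(name = "implication lost variant linkage", archetype = "hboc_germline_family",
         rule = "diagnostic-implication/Observation.derivedFrom/card-min",
         fn = function(b) modify_resource(b, "diagnostic-implication", function(r) { r$derivedFrom <- NULL; r })),
    list(name = "follow-up task code dropped", archetype = "hboc_germline_family",
         rule = "recommended-follow-up/Task.code/card-min",
         fn = function(b) modify_resource(b, "recommended-follow-up", function(r) { r$code <- NULL; r })),
    list(name = "medication task subject dropped", archetype = "onc_somatic_snv",
         rule = "medication-recommendation/Task.for/card-min",
         fn = function(b) modify_resource(b, "medication-recommendation", function(r) { r[["for"]] <- NULL; r })),
    list(name = "MSI value off answer list", archetype = "onc_cnv_msi_tmb",
         rule = "microsatellite-instability/Observation.value[x]/binding",
         fn = function(b) modify_resource(b, "microsatellite-instability", function(r) {
           r$valueCodeableConcept$coding[[1]]$code <- "LA9999-9"
           r
         })),
    list(name = "PRS probability above one", archetype = "prs_report",
         rule = "polygenic-risk-score/RiskAssessment.prediction.probability[x]/fraction-range",
         fn = function(b) modify_resource(b, "polygenic-risk-score", function(r) {
           r$prediction[[1]]$probabilityDecimal <- 1.4
           r
         })),
    list(name = "PRS qualitative risk off value set", archetype = "prs_report",
         rule = "polygenic-risk-score/RiskAssessment.prediction.qualitativeRisk/binding",
         fn = function(b) modify_resource(b, "polygenic-risk-score", function(r) {
           r$prediction[[1]]$probabilityDecimal <- NULL
           r$prediction[[1]]$qualitativeRisk <- list(coding = list(
             list(system = "http://terminology.hl7.org/CodeSystem/risk-probability",
                  code = "astronomical")))
           r
         }))
  )
}

base_bundle_for <- local({
  cache <- list()
  function(archetype) {
    if (is.null(cache[[archetype]])) {
      cache[[archetype]] <<- build_bundle(generate_report(archetype, seed = 42), seed = 42)
    }
    cache[[archetype]]
  }
})
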