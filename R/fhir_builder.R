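#' @title FHIR R4 bundle builder
#' @description Transforms a `molgen_report` into a FHIR R4 collection bundle
#'   whose resources conform to the registered MolGen profiles, including the
#'   detection-limit component on the Variant observation, the three-axis
#'   relationship extension on FamilyMemberHistory, the influence-factor
#'   extension on the polygenic-risk-score prediction, EBM billing through
#'   ChargeItem referenced from the finding report's workflow-supportingInfo
#'   extension, and genomics-file/media routing of attachments. Entry URLs are
#'   `urn:uuid`s drawn from a seeded generator so that an identical report and
#'   seed produce a byte-identical bundle.
#' @name fhir_builder
NULL

MG_ORIGIN_CODES <- list(
  somatic = list(system = "http://loinc.org", code = "LA6684-0", display = "Somatic"),
  germline = list(system = "http://loinc.org", code = "LA6683-2", display = "Germline"),
  unknown = list(system = "http://loinc.org", code = "LA18194-3", display = "Unknown genomic source class")
)
MG_SIG_CODES <- list(
  pathogenic = list(system = "http://loinc.org", code = "LA6668-3", display = "Pathogenic"),
  `likely-pathogenic` = list(system = "http://loinc.org", code = "LA26332-9", display = "Likely pathogenic"),
  uncertain = list(system = "http://loinc.org", code = "LA26333-7", display = "Uncertain significance"),
  `likely-benign` = list(system = "http://loinc.org", code = "LA26334-5", display = "Likely benign"),
  benign = list(system = "http://loinc.org", code = "LA6675-8", display = "Benign")
)
MG_MSI_CODES <- list(
  stable = list(system = "http://loinc.org", code = "LA14122-8", display = "Stable"),
  `unstable-low` = list(system = "http://loinc.org", code = "LA14123-6", display = "Unstable low"),
  `unstable-high` = list(system = "http://loinc.org", code = "LA14124-4", display = "Unstable high")
)
MG_ALLELIC_CODES <- list(
  homozygous = list(system = "http://loinc.org", code = "LA6705-3", display = "Homozygous"),
  heterozygous = list(system = "http://loinc.org", code = "LA6706-1", display = "Heterozygous"),
  hemizygous = list(system = "http://loinc.org", code = "LA6707-9", display = "Hemizygous")
)
MG_ISCN <- "urn:oid:2.16.840.1.113883.6.335"
MG_HGVS_SYS <- "http://varnomen.hgvs.org"
MG_HGNC <- "http://www.genenames.org"
MG_EBM_SYS <- "http://fhir.de/CodeSystem/kbv/ebm"
MG_UCUM <- "http://unitsofmeasure.org"
MG_REFSEQ <- "http://www.ncbi.nlm.nih.gov/refseq"
MG_RISK_PROB <- "http://terminology.hl7.org/CodeSystem/risk-probability"

#' Builder configuration
#'
#' @param canonical_base Base URI for profile canonicals and extension URLs;
#'   defaults to the registry's packaged placeholder base.
#' @param file_mime MIME types routed to the `genomics-file` extension of the
#'   finding report; other attachments go to `DiagnosticReport.media`.
#' @return A `molgen_config` list.
#' @export
molgen_config <- function(canonical_base = NULL,
                          file_mime = c("text/x-vcf", "application/gzip",
                                        "application/octet-stream",
                                        "text/tab-separated-values")) {
  base <- canonical_base %||% load_registry()$canonical_base
  structure(list(canonical_base = base, file_mime = file_mime),
            class = c("molgen_config", "list"))
}

mg_ext_url <- function(config, name) {
  paste0(sub("/StructureDefinition$", "", config$canonical_base),
         "/StructureDefinition/", name)
}

mg_profile_url <- function(config, profile_id) {
  paste0(config$canonical_base, "/", profile_id)
}

# Seeded urn:uuid generator: hex digits from a dedicated Mersenne-Twister
# stream so bundles are bit-stable for a given (report, seed) pair.
mg_uuid_gen <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  function() {
    assign(".Random.seed", state, envir = globalenv())
    hx <- paste(sample(c(0:9, letters[1:6]), 32, replace = TRUE), collapse = "")
    state <<- get(".Random.seed", globalenv())
    sprintf("urn:uuid:%s-%s-%s-%s-%s", substr(hx, 1, 8), substr(hx, 9, 12),
            substr(hx, 13, 16), substr(hx, 17, 20), substr(hx, 21, 32))
  }
}

mg_cc <- function(coding = NULL, text = NULL) {
  out <- list()
  if (!is.null(coding)) {
    if (!is.null(coding$system) || !is.null(coding$code)) coding <- list(coding)
    out$coding <- lapply(coding, function(cd) cd[!vapply(cd, is.null, logical(1))])
  }
  if (!is.null(text)) out$text <- text
  out
}

mg_ref <- function(url, display = NULL) {
  out <- list(reference = url)
  if (!is.null(display)) out$display <- display
  out
}

mg_component <- function(slice, value, registry = load_registry()) {
  code <- registry$component_slice_codes[[slice]]
  c(list(code = mg_cc(list(system = code$system, code = code$code))), value)
}

mg_quantity <- function(value, unit = "1", code = unit, system = MG_UCUM) {
  list(value = value, unit = unit, system = system, code = code)
}

#' Build a FHIR bundle from a MolGen report
#'
#' Refuses to build when the report violates the model invariants or when any
#' HGVS expression fails syntactic validation; otherwise emits a collection
#' bundle covering, as applicable: Patient and Specimen (module references),
#' ServiceRequest with reason and supportingInfo wiring, FamilyMemberHistory
#' with the relationship-components extension and the condition-code slice,
#' Variant observations with HGVS-coded components, variant origin, ISCN
#' cytogenetic location and the detection-limit component, Region Studied,
#' Microsatellite Instability, Mutational Burden, Result Summary and Genotype
#' observations, Diagnostic and Therapeutic Implication observations,
#' Medication Recommendation and Recommended Follow-Up tasks, RiskAssessment
#' entries with the influence-factor prediction extension, ChargeItem (EBM)
#' and the single MolGen Finding Report that references them.
#'
#' @param report A `molgen_report`.
#' @param seed Integer seed for the urn:uuid generator.
#' @param config A [molgen_config()].
#' @return A `molgen_bundle` (nested list mirroring the FHIR JSON).
#' @export
build_bundle <- function(report, seed = 0L, config = molgen_config()) {
  bad <- mg_report_violations(report)
  if (length(bad)) {
    mg_validation_error(paste0("build refused; report violates model invariants:\n  ",
                               paste(bad, collapse = "\n  ")))
  }
  checks <- list(dna_change_c = "c", dna_change_g = "g", protein_change = "p")
  for (i in seq_along(report$results$variants %||% list())) {
    v <- report$results$variants[[i]]
    for (field in names(checks)) {
      if (mg_has(v[[field]])) {
        res <- validate_hgvs(v[[field]], checks[[field]])
        if (!res$valid) {
          mg_validation_error(sprintf("build refused; variant %d %s: %s", i, field, res$reason))
        }
      }
    }
  }

  registry <- load_registry()
  uuid <- mg_uuid_gen(seed)
  entries <- list()
  add <- function(resource) {
    url <- uuid()
    entries[[length(entries) + 1L]] <<- list(fullUrl = url, resource = resource)
    url
  }
  withmeta <- function(resource, profile_id) {
    resource$meta <- list(profile = list(mg_profile_url(config, profile_id)))
    # keep resourceType first, meta second
    resource[c("resourceType", "meta", setdiff(names(resource), c("resourceType", "meta")))]
  }

  pat <- report$patient
  patient_res <- list(resourceType = "Patient")
  if (mg_has(pat$identifier)) patient_res$identifier <- list(list(value = pat$identifier))
  if (mg_has(pat$name)) {
    patient_res$name <- list(list(family = pat$name$family,
                                  given = as.list(pat$name$given %||% NULL)))
  }
  if (mg_has(pat$gender)) patient_res$gender <- pat$gender
  if (mg_has(pat$birth_date)) patient_res$birthDate <- pat$birth_date
  if (mg_has(pat$age)) {
    patient_res$extension <- list(list(url = mg_ext_url(config, "patient-age"),
                                       valueDecimal = pat$age))
  }
  patient_url <- add(withmeta(patient_res, "patient"))
  subject <- mg_ref(patient_url)

  sp <- report$specimen
  specimen_url <- NULL
  if (mg_has(sp)) {
    s <- list(resourceType = "Specimen")
    if (mg_has(sp$id)) s$identifier <- list(list(value = sp$id))
    if (mg_has(sp$status)) s$status <- sp$status
    if (mg_has(sp$type)) s$type <- mg_cc(sp$type)
    s$subject <- subject
    if (mg_has(sp$received)) s$receivedTime <- sp$received
    if (mg_has(sp$parent_id)) s$parent <- list(list(display = sp$parent_id))
    coll <- list()
    if (mg_has(sp$collected)) coll$collectedDateTime <- sp$collected
    if (mg_has(sp$method)) coll$method <- mg_cc(sp$method)
    if (mg_has(sp$body_site)) coll$bodySite <- mg_cc(sp$body_site)
    if (length(coll)) s$collection <- coll
    if (mg_has(sp$additives)) {
      s$container <- lapply(sp$additives, function(a) list(additiveCodeableConcept = mg_cc(a)))
    }
    if (mg_has(sp$conditions)) s$condition <- lapply(sp$conditions, mg_cc)
    if (mg_has(sp$notes)) s$note <- lapply(as.list(sp$notes), function(t) list(text = t))
    specimen_url <- add(withmeta(s, "specimen"))
  }

  perf <- report$misc$performer
  org_url <- NULL
  if (mg_has(perf)) {
    org <- list(resourceType = "Organization")
    if (mg_has(perf$name)) org$name <- perf$name
    if (mg_has(perf$contact)) {
      sys <- if (grepl("@", perf$contact)) "email" else "phone"
      org$telecom <- list(list(system = sys, value = perf$contact))
    }
    org_url <- add(org)
  }

  # Family member histories (emitted before the ServiceRequest that wires
  # them into supportingInfo).
  fmh_urls <- character(0)
  for (fh in report$request$family_history %||% list()) {
    triple <- relationship_triple(fh$relation$relation_type,
                                  fh$relation$lineage %||% "unspecified")
    axis <- compose_relationship(triple, "snomed_familymember")
    sub_ext <- list()
    if (triple$lineage != "unspecified") {
      sub_ext <- c(sub_ext, list(list(url = "lineage", valueCoding = unclass(axis[[1]]))))
    }
    type_concept <- axis[[length(axis)]]
    if (triple$degree <= 2) {
      deg_concept <- axis[[length(axis) - 1L]]
      sub_ext <- c(sub_ext, list(list(url = "degree", valueCoding = unclass(deg_concept))))
    } else {
      sub_ext <- c(sub_ext, list(list(url = "degree-annotation",
                                      valueString = attr(axis, "degree_annotation"))))
    }
    sub_ext <- c(sub_ext, list(list(url = "type", valueCoding = unclass(type_concept))))
    rel <- mg_cc(unclass(type_concept), text = relationship_display(triple))
    rel$extension <- list(list(url = mg_ext_url(config, "relationship-components"),
                               extension = sub_ext))
    fmh <- list(resourceType = "FamilyMemberHistory",
                status = "completed", patient = subject, relationship = rel)
    conds <- fh$conditions %||% list()
    if (length(conds)) {
      fmh$condition <- lapply(seq_along(conds), function(j) {
        cond <- list(code = mg_cc(conds[[j]]))
        if (j == 1L && mg_has(fh$age_at_onset)) {
          cond$onsetAge <- mg_quantity(fh$age_at_onset, unit = "a", code = "a")
        }
        cond
      })
    }
    if (!is.null(fh$deceased)) fmh$deceasedBoolean <- isTRUE(fh$deceased)
    fmh_urls <- c(fmh_urls, add(withmeta(fmh, "family-medical-history")))
  }

  rq <- report$request
  sr <- list(resourceType = "ServiceRequest")
  if (mg_has(rq$id)) sr$identifier <- list(list(value = rq$id))
  if (mg_has(rq$status)) sr$status <- rq$status
  if (mg_has(rq$intent)) sr$intent <- rq$intent
  if (mg_has(rq$code)) sr$code <- mg_cc(rq$code)
  sr$subject <- subject
  if (mg_has(rq$requester)) sr$requester <- list(display = rq$requester)
  if (mg_has(rq$authored_on)) sr$authoredOn <- rq$authored_on
  if (mg_has(rq$reasons)) sr$reasonCode <- lapply(rq$reasons, mg_cc)
  if (mg_has(rq$reason_phenotypes)) {
    sr$reasonReference <- lapply(as.list(rq$reason_phenotypes), function(p) list(display = p))
  }
  supp <- lapply(fmh_urls, mg_ref)
  if (mg_has(rq$supporting_info)) {
    supp <- c(supp, lapply(as.list(rq$supporting_info), function(s) list(display = s)))
  }
  if (length(supp)) sr$supportingInfo <- supp
  if (mg_has(rq$performer_requested)) sr$performer <- list(list(display = rq$performer_requested))
  sr_url <- add(withmeta(sr, "request"))

  charge_url <- NULL
  if (mg_has(rq$ebm_code)) {
    charge <- list(resourceType = "ChargeItem", status = "billable",
                   code = mg_cc(list(system = MG_EBM_SYS, code = rq$ebm_code)),
                   subject = subject)
    charge_url <- add(charge)
  }

  result_urls <- character(0)
  mt <- report$methods
  variant_urls <- character(0)
  for (i in seq_along(report$results$variants %||% list())) {
    v <- report$results$variants[[i]]
    obs <- list(resourceType = "Observation", status = "final",
                code = mg_cc(list(system = "http://loinc.org", code = "69548-6",
                                  display = "Genetic variant assessment")),
                subject = subject)
    if (mg_has(v$variant_id)) {
      obs$identifier <- list(list(system = v$variant_id$system, value = v$variant_id$code))
    }
    if (!is.null(specimen_url)) obs$specimen <- mg_ref(specimen_url)
    comps <- list()
    pushc <- function(slice, value) comps[[length(comps) + 1L]] <<-
      mg_component(slice, value, registry)
    if (mg_has(v$gene)) pushc("gene-studied", list(valueCodeableConcept = mg_cc(v$gene)))
    if (mg_has(v$dna_change_c)) {
      pushc("dna-chg", list(valueCodeableConcept =
        mg_cc(list(system = MG_HGVS_SYS, code = v$dna_change_c))))
    }
    if (mg_has(v$dna_change_g)) {
      pushc("genomic-dna-chg", list(valueCodeableConcept =
        mg_cc(list(system = MG_HGVS_SYS, code = v$dna_change_g))))
    }
    if (mg_has(v$protein_change)) {
      pushc("amino-acid-chg", list(valueCodeableConcept =
        mg_cc(list(system = MG_HGVS_SYS, code = v$protein_change))))
    }
    pushc("variant-origin", list(valueCodeableConcept = mg_cc(MG_ORIGIN_CODES[[v$origin]])))
    if (mg_has(v$cytogenetic_location)) {
      pushc("cytogenetic-location", list(valueCodeableConcept =
        mg_cc(list(system = MG_ISCN, code = v$cytogenetic_location))))
    }
    if (mg_has(v$allelic_state)) {
      pushc("allelic-state", list(valueCodeableConcept = mg_cc(MG_ALLELIC_CODES[[v$allelic_state]])))
    }
    if (mg_has(v$allele_fraction)) {
      pushc("sample-allelic-frequency", list(valueQuantity = mg_quantity(v$allele_fraction)))
    }
    if (mg_has(v$detection_limit)) {
      pushc("detection-limit", list(valueQuantity =
        mg_quantity(v$detection_limit * 100, unit = "%", code = "%")))
    }
    if (mg_has(v$copy_number)) pushc("copy-number", list(valueQuantity = mg_quantity(v$copy_number)))
    if (mg_has(v$variant_type)) {
      pushc("variation-code", list(valueCodeableConcept =
        mg_cc(list(system = "https://example.org/fhir/molgen/CodeSystem/local",
                   code = v$variant_type))))
    }
    if (mg_has(v$transcript_ref)) {
      pushc("transcript-ref-seq", list(valueCodeableConcept =
        mg_cc(list(system = MG_REFSEQ, code = v$transcript_ref))))
    }
    if (mg_has(v$genomic_ref)) {
      pushc("genomic-ref-seq", list(valueCodeableConcept =
        mg_cc(list(system = MG_REFSEQ, code = v$genomic_ref))))
    }
    if (mg_has(v$exact_start)) {
      pushc("exact-start-end", list(valueRange = list(low = list(value = v$exact_start),
                                                      high = list(value = v$exact_end %||% v$exact_start))))
    }
    if (i == 1L) {
      # assay-level method characteristics ride on the first variant
      if (mg_has(mt$test_method)) obs$method <- list(text = mt$test_method)
      if (mg_has(mt$device)) obs$device <- list(display = mt$device)
      if (mg_has(mt$notes)) obs$note <- lapply(as.list(mt$notes), function(t) list(text = t))
      if (mg_has(mt$read_depth)) pushc("read-depth", list(valueQuantity = mg_quantity(mt$read_depth)))
      if (mg_has(mt$coverage)) pushc("coverage", list(valueQuantity = mg_quantity(mt$coverage, unit = "%", code = "%")))
      if (mg_has(mt$primer)) pushc("primer", list(valueString = mt$primer))
      if (mg_has(mt$reference_assembly)) pushc("ref-sequence-assembly", list(valueString = mt$reference_assembly))
    }
    obs$component <- comps
    url <- add(withmeta(obs, "variant"))
    variant_urls <- c(variant_urls, url)
    result_urls <- c(result_urls, url)
  }

  if (mg_has(mt$region_description) || mg_has(mt$gene_panel)) {
    reg_obs <- list(resourceType = "Observation", status = "final",
                    code = mg_cc(list(system = "http://loinc.org", code = "53041-0",
                                      display = "DNA region of interest panel")),
                    subject = subject)
    comps <- list()
    if (mg_has(mt$region_description)) {
      comps[[length(comps) + 1L]] <- mg_component("description-of-ranges",
        list(valueString = mt$region_description), registry)
    }
    for (g in as.list(mt$gene_panel %||% NULL)) {
      comps[[length(comps) + 1L]] <- mg_component("gene-studied",
        list(valueCodeableConcept = mg_cc(list(system = MG_HGNC, code = g, display = g))), registry)
    }
    reg_obs$component <- comps
    result_urls <- c(result_urls, add(withmeta(reg_obs, "region-studied")))
  }

  rs <- report$results
  if (mg_has(rs$msi_status)) {
    msi <- list(resourceType = "Observation", status = "final",
                code = mg_cc(list(system = "http://loinc.org", code = "81695-9",
                                  display = "Microsatellite instability")),
                subject = subject,
                valueCodeableConcept = mg_cc(MG_MSI_CODES[[rs$msi_status]]))
    result_urls <- c(result_urls, add(withmeta(msi, "microsatellite-instability")))
  }
  if (mg_has(rs$mutational_burden)) {
    tmb <- list(resourceType = "Observation", status = "final",
                code = mg_cc(list(system = "http://loinc.org", code = "94076-7",
                                  display = "Mutations/Megabase")),
                subject = subject,
                valueQuantity = list(value = rs$mutational_burden, unit = "mutations/Mb"))
    result_urls <- c(result_urls, add(withmeta(tmb, "mutational-burden")))
  }
  if (mg_has(rs$summary)) {
    summ <- list(resourceType = "Observation", status = "final",
                 code = mg_cc(list(system = "http://loinc.org", code = "51968-6",
                                   display = "Genetic analysis overall interpretation")),
                 subject = subject, valueString = rs$summary)
    result_urls <- c(result_urls, add(withmeta(summ, "result-summary")))
  }
  if (mg_has(rs$genotype)) {
    gt <- list(resourceType = "Observation", status = "final",
               code = mg_cc(list(system = "http://loinc.org", code = "84413-4",
                                 display = "Genotype display name")),
               subject = subject, valueString = rs$genotype)
    result_urls <- c(result_urls, add(withmeta(gt, "genotype")))
  }

  ip <- report$interpretation
  if (mg_has(ip$clinical_significance) || mg_has(ip$evidence_level) || mg_has(ip$associated_phenotypes)) {
    di <- list(resourceType = "Observation", status = "final",
               code = mg_cc(list(system = "https://example.org/fhir/molgen/CodeSystem/local",
                                 code = "diagnostic-implication")),
               subject = subject,
               derivedFrom = lapply(variant_urls, mg_ref))
    comps <- list()
    if (mg_has(ip$clinical_significance)) {
      comps[[length(comps) + 1L]] <- mg_component("clinical-significance",
        list(valueCodeableConcept = mg_cc(MG_SIG_CODES[[ip$clinical_significance]])), registry)
    }
    if (mg_has(ip$evidence_level)) {
      comps[[length(comps) + 1L]] <- mg_component("evidence-level",
        list(valueCodeableConcept = mg_cc(text = ip$evidence_level)), registry)
    }
    for (ph in ip$associated_phenotypes %||% list()) {
      comps[[length(comps) + 1L]] <- mg_component("associated-phenotype",
        list(valueCodeableConcept = mg_cc(ph)), registry)
    }
    di$component <- comps
    result_urls <- c(result_urls, add(withmeta(di, "diagnostic-implication")))
  }
  if (mg_has(ip$medication_assessed) || mg_has(ip$therapeutic_implication)) {
    ti <- list(resourceType = "Observation", status = "final",
               code = mg_cc(list(system = "https://example.org/fhir/molgen/CodeSystem/local",
                                 code = "therapeutic-implication")),
               subject = subject,
               derivedFrom = lapply(variant_urls, mg_ref))
    comps <- list()
    if (mg_has(ip$medication_assessed)) {
      comps[[length(comps) + 1L]] <- mg_component("medication-assessed",
        list(valueCodeableConcept = mg_cc(text = ip$medication_assessed)), registry)
    }
    if (mg_has(ip$therapeutic_implication)) {
      comps[[length(comps) + 1L]] <- mg_component("predicted-therapeutic-implication",
        list(valueCodeableConcept = mg_cc(text = ip$therapeutic_implication)), registry)
    }
    ti$component <- comps
    result_urls <- c(result_urls, add(withmeta(ti, "therapeutic-implication")))
  }
  if (mg_has(ip$medication_recommendation)) {
    task <- list(resourceType = "Task", status = "requested", intent = "proposal",
                 code = mg_cc(text = ip$medication_recommendation), `for` = subject)
    add(withmeta(task, "medication-recommendation"))
  }
  if (mg_has(ip$general_recommendation) || mg_has(ip$recommended_action_target)) {
    task <- list(resourceType = "Task", status = "requested", intent = "proposal",
                 code = mg_cc(text = ip$general_recommendation %||% "follow-up"),
                 `for` = subject)
    if (mg_has(ip$recommended_action_target)) {
      task$focus <- list(display = ip$recommended_action_target)
    }
    add(withmeta(task, "recommended-follow-up"))
  }

  for (p in rs$prs %||% list()) {
    pred <- list(outcome = mg_cc(p$trait))
    if (identical(p$score_type, "probability")) {
      pred$probabilityDecimal <- p$value
    } else {
      pred$qualitativeRisk <- mg_cc(list(system = MG_RISK_PROB, code = p$value))
    }
    if (mg_has(p$influence_factors)) {
      pred$extension <- lapply(p$influence_factors, function(f) {
        list(url = mg_ext_url(config, "influence-factor"), valueCodeableConcept = mg_cc(f))
      })
    }
    ra <- list(resourceType = "RiskAssessment", status = "final",
               subject = subject, prediction = list(pred))
    add(withmeta(ra, "polygenic-risk-score"))
  }

  ms <- report$misc
  dr <- list(resourceType = "DiagnosticReport")
  if (mg_has(ms$report_id)) dr$identifier <- list(list(value = ms$report_id))
  dr$basedOn <- list(mg_ref(sr_url))
  if (mg_has(ms$status)) dr$status <- ms$status
  dr$code <- mg_cc(list(system = "http://loinc.org", code = "51969-4",
                        display = "Genetic analysis report"))
  dr$subject <- subject
  if (mg_has(ms$issued)) dr$issued <- ms$issued
  if (!is.null(org_url)) dr$performer <- list(mg_ref(org_url, display = perf$name))
  if (length(result_urls)) dr$result <- lapply(result_urls, mg_ref)
  if (mg_has(ip$summary)) dr$conclusion <- ip$summary
  exts <- list()
  media <- list()
  for (a in ms$attachments %||% list()) {
    if ((a$mime %||% "") %in% config$file_mime) {
      exts <- c(exts, list(list(url = mg_ext_url(config, "genomics-file"),
                                valueAttachment = list(contentType = a$mime, title = a$title))))
    } else {
      media <- c(media, list(list(comment = a$mime %||% "", link = list(display = a$title))))
    }
  }
  if (!is.null(charge_url)) {
    exts <- c(exts, list(list(url = mg_ext_url(config, "workflow-supportingInfo"),
                              valueReference = mg_ref(charge_url))))
  }
  if (length(media)) dr$media <- media
  if (length(exts)) dr$extension <- exts
  add(withmeta(dr, "molgen-finding-report"))

  version <- tryCatch(as.character(utils::packageVersion("molgenfhir")),
                      error = function(e) "0.0.0")
  bundle <- list(
    resourceType = "Bundle",
    identifier = list(system = mg_ext_url(config, "builder"),
                      value = sprintf("molgenfhir-%s-seed-%d", version, as.integer(seed))),
    type = "collection",
    entry = entries
  )
  structure(bundle, class = c("molgen_bundle", "list"))
}

#' Serialize a bundle to FHIR JSON
#'
#' @param bundle A `molgen_bundle` (or any FHIR list structure).
#' @param path Optional output file.
#' @param ndjson Emit one resource per line instead of a single Bundle object.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_bundle <- function(bundle, path = NULL, ndjson = FALSE) {
  if (ndjson) {
    txt <- paste(vapply(bundle$entry, function(e) mg_to_json(e$resource, pretty = FALSE),
                        character(1)), collapse = "\n")
  } else {
    txt <- mg_to_json(unclass(bundle))
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
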