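#' @title Bundle parsing (inverse mapping)
#' @description Recovers the internal report model from a FHIR bundle the
#'   builder produced; foreign bundles are parsed best-effort and resources
#'   outside the MolGen profile set are listed in the `unparsed_resources`
#'   attribute of the result.
#' @name fhir_parser
NULL

mg_first <- function(x) if (is.null(x) || length(x) == 0L) NULL else x[[1]]

mg_as_bundle <- function(x) {
  if (is.character(x)) x <- mg_parse_document(x)
  if (!is.list(x) || !identical(x$resourceType, "Bundle")) {
    mg_structural_error("not a FHIR Bundle")
  }
  x
}

mg_collect_references <- function(x) {
  refs <- character(0)
  walk <- function(node) {
    if (!is.list(node)) return(invisible())
    if (!is.null(node$reference) && is.character(node$reference)) {
      refs <<- c(refs, node$reference)
    }
    for (child in node) walk(child)
  }
  walk(x)
  refs
}

mg_entry_profile <- function(entry) {
  prof <- entry$resource$meta$profile
  if (is.null(prof) || length(prof) == 0L) return(NA_character_)
  basename(unlist(prof)[1])
}

mg_concept_from_cc <- function(cc) {
  cd <- mg_first(cc$coding)
  if (is.null(cd)) return(NULL)
  out <- list(system = cd$system, code = cd$code)
  if (!is.null(cd$display)) out$display <- cd$display
  out
}

mg_comp_by_slice <- function(obs, slice, registry) {
  want <- registry$component_slice_codes[[slice]]
  for (comp in obs$component %||% list()) {
    cd <- mg_first(comp$code$coding) %||% list()
    if (identical(cd$code, want$code) && identical(cd$system, want$system)) return(comp)
  }
  NULL
}

mg_comps_by_slice <- function(obs, slice, registry) {
  want <- registry$component_slice_codes[[slice]]
  Filter(function(comp) {
    cd <- mg_first(comp$code$coding) %||% list()
    identical(cd$code, want$code) && identical(cd$system, want$system)
  }, obs$component %||% list())
}

mg_rev_token <- function(map, cc) {
  cd <- mg_first(cc$coding) %||% list()
  for (token in names(map)) if (identical(map[[token]]$code, cd$code)) return(token)
  cd$code %||% NULL
}

#' Parse a FHIR bundle back into a MolGen report
#'
#' Structural preconditions: the bundle holds exactly one DiagnosticReport and
#' every internal `urn:` reference resolves to an entry `fullUrl` (referential
#' closure). For bundles produced by [build_bundle()] the round trip
#' `parse_bundle(build_bundle(r))` preserves every registry-mapped field.
#'
#' @param x A bundle list, JSON text or a path to a JSON file.
#' @return A `molgen_report`; resources that could not be mapped are listed in
#'   the `unparsed_resources` attribute.
#' @export
parse_bundle <- function(x) {
  bundle <- mg_as_bundle(x)
  registry <- load_registry()
  entries <- bundle$entry %||% list()
  urls <- vapply(entries, function(e) e$fullUrl %||% NA_character_, character(1))

  refs <- mg_collect_references(entries)
  urn_refs <- refs[startsWith(refs, "urn:")]
  dangling <- setdiff(urn_refs, urls)
  if (length(dangling)) {
    mg_referential_error(sprintf("unresolvable reference(s): %s",
                                 paste(unique(dangling), collapse = ", ")))
  }

  profiles <- vapply(entries, mg_entry_profile, character(1))
  rtypes <- vapply(entries, function(e) e$resource$resourceType %||% "", character(1))
  if (sum(rtypes == "DiagnosticReport") == 0L) {
    mg_structural_error("bundle contains no DiagnosticReport")
  }
  if (sum(rtypes == "DiagnosticReport") > 1L) {
    mg_structural_error("bundle contains more than one DiagnosticReport")
  }
  res_of <- function(profile_id) {
    lapply(entries[which(profiles == profile_id)], function(e) e$resource)
  }
  first_of <- function(profile_id) {
    hits <- res_of(profile_id)
    if (length(hits)) hits[[1]] else NULL
  }

  patient <- list()
  p <- first_of("patient")
  if (!is.null(p)) {
    patient$identifier <- mg_first(p$identifier)$value %||% NULL
    if (!is.null(p$name)) {
      patient$name <- list(family = p$name[[1]]$family,
                           given = p$name[[1]]$given %||% NULL)
    }
    patient$gender <- p$gender
    patient$birth_date <- p$birthDate
    for (ext in p$extension %||% list()) {
      if (endsWith(ext$url %||% "", "patient-age")) patient$age <- ext$valueDecimal
    }
  }

  specimen <- list()
  s <- first_of("specimen")
  if (!is.null(s)) {
    specimen$id <- mg_first(s$identifier)$value %||% NULL
    specimen$status <- s$status
    specimen$type <- mg_concept_from_cc(s$type %||% list())
    specimen$collected <- s$collection$collectedDateTime
    specimen$method <- mg_concept_from_cc(s$collection$method %||% list())
    specimen$body_site <- mg_concept_from_cc(s$collection$bodySite %||% list())
    if (!is.null(s$container)) {
      specimen$additives <- lapply(s$container, function(cn)
        mg_concept_from_cc(cn$additiveCodeableConcept %||% list()))
    }
    specimen$received <- s$receivedTime
    if (!is.null(s$condition)) specimen$conditions <- lapply(s$condition, mg_concept_from_cc)
    specimen$parent_id <- mg_first(s$parent)$display %||% NULL
    if (!is.null(s$note)) specimen$notes <- vapply(s$note, function(n) n$text, character(1))
  }

  request <- list()
  sr <- first_of("request")
  if (!is.null(sr)) {
    request$id <- mg_first(sr$identifier)$value %||% NULL
    request$status <- sr$status
    request$intent <- sr$intent
    request$code <- mg_concept_from_cc(sr$code %||% list())
    request$requester <- sr$requester$display %||% NULL
    request$authored_on <- sr$authoredOn
    if (!is.null(sr$reasonCode)) request$reasons <- lapply(sr$reasonCode, mg_concept_from_cc)
    if (!is.null(sr$reasonReference)) {
      request$reason_phenotypes <- vapply(sr$reasonReference,
                                          function(r) r$display %||% "", character(1))
    }
    supp <- Filter(function(si) is.null(si$reference) && !is.null(si$display),
                   sr$supportingInfo %||% list())
    if (length(supp)) request$supporting_info <- vapply(supp, function(si) si$display, character(1))
    request$performer_requested <- mg_first(sr$performer)$display %||% NULL
  }

  fams <- res_of("family-medical-history")
  if (length(fams)) {
    request$family_history <- lapply(fams, function(fmh) {
      out <- list()
      axis <- list()
      for (ext in fmh$relationship$extension %||% list()) {
        if (endsWith(ext$url %||% "", "relationship-components")) {
          for (sub in ext$extension %||% list()) {
            if (!is.null(sub$valueCoding)) axis <- c(axis, list(sub$valueCoding))
          }
        }
      }
      if (!length(axis)) axis <- fmh$relationship$coding %||% list()
      triple <- decompose_relationship(axis)
      out$relation <- unclass(triple)
      conds <- fmh$condition %||% list()
      if (length(conds)) {
        out$conditions <- lapply(conds, function(cn) mg_concept_from_cc(cn$code %||% list()))
        onset <- conds[[1]]$onsetAge$value %||% NULL
        if (!is.null(onset)) out$age_at_onset <- onset
      }
      if (!is.null(fmh$deceasedBoolean)) out$deceased <- fmh$deceasedBoolean
      out
    })
  }

  charge <- NULL
  for (e in entries) if (identical(e$resource$resourceType, "ChargeItem")) charge <- e$resource
  if (!is.null(charge)) {
    request$ebm_code <- mg_first(charge$code$coding)$code %||% NULL
  }

  methods <- list()
  results <- list()
  vars <- res_of("variant")
  if (length(vars)) {
    first <- vars[[1]]
    methods$test_method <- first$method$text %||% NULL
    methods$device <- first$device$display %||% NULL
    if (!is.null(first$note)) methods$notes <- vapply(first$note, function(n) n$text, character(1))
    cmp <- function(slice) mg_comp_by_slice(first, slice, registry)
    methods$read_depth <- cmp("read-depth")$valueQuantity$value %||% NULL
    methods$coverage <- cmp("coverage")$valueQuantity$value %||% NULL
    methods$primer <- cmp("primer")$valueString %||% NULL
    methods$reference_assembly <- cmp("ref-sequence-assembly")$valueString %||% NULL

    results$variants <- lapply(vars, function(obs) {
      v <- list()
      g <- function(slice) mg_comp_by_slice(obs, slice, registry)
      if (!is.null(obs$identifier)) {
        v$variant_id <- list(system = mg_first(obs$identifier)$system,
                             code = mg_first(obs$identifier)$value)
      }
      v$gene <- mg_concept_from_cc(g("gene-studied")$valueCodeableConcept %||% list())
      v$dna_change_c <- mg_first(g("dna-chg")$valueCodeableConcept$coding)$code %||% NULL
      v$dna_change_g <- mg_first(g("genomic-dna-chg")$valueCodeableConcept$coding)$code %||% NULL
      v$protein_change <- mg_first(g("amino-acid-chg")$valueCodeableConcept$coding)$code %||% NULL
      vo <- g("variant-origin")
      if (!is.null(vo)) v$origin <- mg_rev_token(MG_ORIGIN_CODES, vo$valueCodeableConcept)
      v$cytogenetic_location <- mg_first(g("cytogenetic-location")$valueCodeableConcept$coding)$code %||% NULL
      as_ <- g("allelic-state")
      if (!is.null(as_)) v$allelic_state <- mg_rev_token(MG_ALLELIC_CODES, as_$valueCodeableConcept)
      v$allele_fraction <- g("sample-allelic-frequency")$valueQuantity$value %||% NULL
      dl <- g("detection-limit")$valueQuantity$value %||% NULL
      if (!is.null(dl)) v$detection_limit <- dl / 100
      v$copy_number <- g("copy-number")$valueQuantity$value %||% NULL
      v$variant_type <- mg_first(g("variation-code")$valueCodeableConcept$coding)$code %||% NULL
      v$transcript_ref <- mg_first(g("transcript-ref-seq")$valueCodeableConcept$coding)$code %||% NULL
      v$genomic_ref <- mg_first(g("genomic-ref-seq")$valueCodeableConcept$coding)$code %||% NULL
      se <- g("exact-start-end")
      if (!is.null(se)) {
        v$exact_start <- se$valueRange$low$value %||% NULL
        v$exact_end <- se$valueRange$high$value %||% NULL
      }
      v
    })
  }

  reg_obs <- first_of("region-studied")
  if (!is.null(reg_obs)) {
    methods$region_description <-
      mg_comp_by_slice(reg_obs, "description-of-ranges", registry)$valueString %||% NULL
    genes <- mg_comps_by_slice(reg_obs, "gene-studied", registry)
    if (length(genes)) {
      methods$gene_panel <- vapply(genes, function(cm)
        mg_first(cm$valueCodeableConcept$coding)$code, character(1))
    }
  }

  msi <- first_of("microsatellite-instability")
  if (!is.null(msi)) results$msi_status <- mg_rev_token(MG_MSI_CODES, msi$valueCodeableConcept)
  tmb <- first_of("mutational-burden")
  if (!is.null(tmb)) results$mutational_burden <- tmb$valueQuantity$value
  summ <- first_of("result-summary")
  if (!is.null(summ)) results$summary <- summ$valueString
  gt <- first_of("genotype")
  if (!is.null(gt)) results$genotype <- gt$valueString

  ras <- res_of("polygenic-risk-score")
  if (length(ras)) {
    results$prs <- lapply(ras, function(ra) {
      pred <- ra$prediction[[1]]
      p <- list(trait = mg_concept_from_cc(pred$outcome %||% list()))
      if (!is.null(pred$probabilityDecimal)) {
        p$score_type <- "probability"
        p$value <- pred$probabilityDecimal
      } else {
        p$score_type <- "qualitative"
        p$value <- mg_first(pred$qualitativeRisk$coding)$code %||% NULL
      }
      factors <- Filter(function(e) endsWith(e$url %||% "", "influence-factor"),
                        pred$extension %||% list())
      if (length(factors)) {
        p$influence_factors <- lapply(factors, function(e)
          mg_concept_from_cc(e$valueCodeableConcept %||% list()))
      }
      p
    })
  }

  interpretation <- list()
  di <- first_of("diagnostic-implication")
  if (!is.null(di)) {
    cs <- mg_comp_by_slice(di, "clinical-significance", registry)
    if (!is.null(cs)) {
      interpretation$clinical_significance <- mg_rev_token(MG_SIG_CODES, cs$valueCodeableConcept)
    }
    interpretation$evidence_level <-
      mg_comp_by_slice(di, "evidence-level", registry)$valueCodeableConcept$text %||% NULL
    phen <- mg_comps_by_slice(di, "associated-phenotype", registry)
    if (length(phen)) {
      interpretation$associated_phenotypes <- lapply(phen, function(cm)
        mg_concept_from_cc(cm$valueCodeableConcept))
    }
  }
  ti <- first_of("therapeutic-implication")
  if (!is.null(ti)) {
    interpretation$medication_assessed <-
      mg_comp_by_slice(ti, "medication-assessed", registry)$valueCodeableConcept$text %||% NULL
    interpretation$therapeutic_implication <-
      mg_comp_by_slice(ti, "predicted-therapeutic-implication", registry)$valueCodeableConcept$text %||% NULL
  }
  medtask <- first_of("medication-recommendation")
  if (!is.null(medtask)) interpretation$medication_recommendation <- medtask$code$text %||% NULL
  futask <- first_of("recommended-follow-up")
  if (!is.null(futask)) {
    interpretation$general_recommendation <- futask$code$text %||% NULL
    interpretation$recommended_action_target <- futask$focus$display %||% NULL
  }

  misc <- list()
  dr <- NULL
  for (e in entries) if (identical(e$resource$resourceType, "DiagnosticReport")) dr <- e$resource
  misc$report_id <- mg_first(dr$identifier)$value %||% NULL
  misc$status <- dr$status
  misc$issued <- dr$issued
  interpretation$summary <- dr$conclusion %||% NULL
  if (!is.null(dr$performer)) {
    org_name <- mg_first(dr$performer)$display %||% NULL
    contact <- NULL
    for (e in entries) {
      if (identical(e$resource$resourceType, "Organization")) {
        org_name <- e$resource$name %||% org_name
        contact <- mg_first(e$resource$telecom)$value %||% NULL
      }
    }
    misc$performer <- list(name = org_name, contact = contact)
  }
  attachments <- list()
  for (ext in dr$extension %||% list()) {
    if (endsWith(ext$url %||% "", "genomics-file")) {
      attachments <- c(attachments, list(list(title = ext$valueAttachment$title,
                                              mime = ext$valueAttachment$contentType)))
    }
  }
  for (m in dr$media %||% list()) {
    attachments <- c(attachments, list(list(title = m$link$display, mime = m$comment)))
  }
  if (length(attachments)) misc$attachments <- attachments

  known <- c("patient", "specimen", "request", "family-medical-history", "variant",
             "region-studied", "microsatellite-instability", "mutational-burden",
             "result-summary", "genotype", "diagnostic-implication",
             "therapeutic-implication", "medication-recommendation",
             "recommended-follow-up", "polygenic-risk-score", "molgen-finding-report")
  unparsed <- rtypes[!(profiles %in% known) & !rtypes %in% c("ChargeItem", "Organization")]

  report <- molgen_report(specimen = specimen, patient = patient, request = request,
                          methods = methods, results = results,
                          interpretation = interpretation, misc = misc)
  if (length(unparsed)) attr(report, "unparsed_resources") <- unparsed
  report
}
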