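#' @title Internal MolGen report model
#' @description A profile-agnostic representation of a complete molecular
#'   genomics report, mirroring the six dataset categories (specimen with its
#'   patient sub-block, request, methods, results, interpretation,
#'   miscellaneous). JSON and YAML are accepted on input; canonical key-sorted
#'   JSON is emitted on output. Detection limits are stored as dimensionless
#'   fractions (percentages are normalized on input); allele fractions must
#'   already lie in [0, 1].
#' @name report_model
NULL

MG_ORIGINS <- c("somatic", "germline", "unknown")
MG_REPORT_STATUS <- c("registered", "partial", "preliminary", "final", "amended", "corrected")
MG_GENDERS <- c("female", "male", "other", "unknown")
MG_ALLELIC_STATES <- c("homozygous", "heterozygous", "hemizygous")
MG_MSI <- c("stable", "unstable-low", "unstable-high")
MG_SIGNIFICANCE <- c("pathogenic", "likely-pathogenic", "uncertain", "likely-benign", "benign")
MG_QUAL_RISK <- c("negligible", "low", "moderate", "high", "certain")

# Allowed keys per block; used both for unknown-key reporting and the schema
# export. Concepts are {system, code, display}; lists of concepts are arrays.
mg_report_schema_keys <- function() {
  concept <- c("system", "code", "display")
  list(
    specimen = list(id = NULL, type = concept, status = NULL, collected = NULL,
                    method = concept, body_site = concept, additives = concept,
                    received = NULL, conditions = concept, parent_id = NULL, notes = NULL),
    patient = list(name = c("family", "given"), birth_date = NULL, age = NULL,
                   gender = NULL, identifier = NULL),
    request = list(id = NULL, status = NULL, intent = NULL, code = concept,
                   requester = NULL, authored_on = NULL, reasons = concept,
                   reason_phenotypes = NULL, supporting_info = NULL,
                   family_history = c("relation", "conditions", "age_at_onset", "deceased"),
                   ebm_code = NULL, performer_requested = NULL),
    methods = list(test_method = NULL, device = NULL, read_depth = NULL,
                   coverage = NULL, primer = NULL, region_description = NULL,
                   gene_panel = NULL, reference_assembly = NULL, notes = NULL),
    results = list(variants = c("variant_id", "gene", "dna_change_c", "dna_change_g",
                                "protein_change", "origin", "cytogenetic_location",
                                "detection_limit", "allelic_state", "allele_fraction",
                                "copy_number", "variant_type", "transcript_ref",
                                "genomic_ref", "exact_start", "exact_end"),
                   msi_status = NULL, mutational_burden = NULL, summary = NULL,
                   genotype = NULL,
                   prs = c("trait", "score_type", "value", "influence_factors")),
    interpretation = list(clinical_significance = NULL, evidence_level = NULL,
                          associated_phenotypes = concept, medication_assessed = NULL,
                          medication_recommendation = NULL, general_recommendation = NULL,
                          therapeutic_implication = NULL, summary = NULL,
                          recommended_action_target = NULL),
    misc = list(report_id = NULL, status = NULL, issued = NULL,
                attachments = c("title", "mime"),
                performer = c("name", "contact"))
  )
}

mg_has <- function(x) {
  if (is.null(x) || length(x) == 0L) return(FALSE)
  if (is.character(x)) return(any(nzchar(x)))
  TRUE
}

mg_collect_unknown_keys <- function(doc) {
  schema <- mg_report_schema_keys()
  unknown <- character(0)
  note <- function(path) unknown <<- c(unknown, path)
  blocks <- names(doc)
  for (b in blocks) {
    if (!b %in% names(schema)) { note(b); next }
    blk <- doc[[b]]
    if (!is.list(blk)) next
    for (k in names(blk)) {
      if (!k %in% names(schema[[b]])) note(paste(b, k, sep = "."))
    }
  }
  unknown
}

# Normalize a parsed document into canonical internal form: percent detection
# limits to fractions, relationship phrases to triples, key-sorted lists.
mg_normalize_report <- function(doc) {
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  chr <- function(x) if (is.null(x) || length(x) == 0L) NULL else as.character(unlist(x))
  doc$specimen$notes <- chr(doc$specimen$notes)
  doc$methods$notes <- chr(doc$methods$notes)
  doc$methods$gene_panel <- chr(doc$methods$gene_panel)
  doc$request$reason_phenotypes <- chr(doc$request$reason_phenotypes)
  doc$request$supporting_info <- chr(doc$request$supporting_info)
  doc$results$variants <- lapply(doc$results$variants %||% list(), function(v) {
    v$detection_limit <- num(v$detection_limit)
    if (mg_has(v$detection_limit) && v$detection_limit > 1 && v$detection_limit <= 100) {
      v$detection_limit <- v$detection_limit / 100
    }
    v$allele_fraction <- num(v$allele_fraction)
    v$copy_number <- num(v$copy_number)
    v$exact_start <- num(v$exact_start)
    v$exact_end <- num(v$exact_end)
    v
  })
  doc$request$family_history <- lapply(doc$request$family_history %||% list(), function(fh) {
    rel <- fh$relation
    if (is.character(rel)) {
      rel <- unclass(decompose_relationship(rel))
    } else if (is.list(rel)) {
      rel <- unclass(relationship_triple(rel$relation_type, rel$lineage %||% "unspecified"))
    }
    fh$relation <- rel
    fh$age_at_onset <- num(fh$age_at_onset)
    fh
  })
  doc$results$prs <- lapply(doc$results$prs %||% list(), function(p) {
    if (identical(p$score_type, "probability")) p$value <- num(p$value)
    p
  })
  doc$results$mutational_burden <- num(doc$results$mutational_burden)
  doc$methods$read_depth <- num(doc$methods$read_depth)
  doc$methods$coverage <- num(doc$methods$coverage)
  doc$patient$age <- num(doc$patient$age)
  mg_canonical(doc)
}

mg_report_violations <- function(report) {
  bad <- character(0)
  fail <- function(field, rule) bad <<- c(bad, sprintf("%s: %s", field, rule))
  misc <- report$misc
  if (mg_has(misc$status) && !misc$status %in% MG_REPORT_STATUS) {
    fail("misc.status", paste("must be one of", paste(MG_REPORT_STATUS, collapse = ", ")))
  }
  if (identical(misc$status, "final") && length(report$results$variants %||% list()) == 0L) {
    fail("results.variants", "must be non-empty when misc.status is 'final'")
  }
  if (mg_has(report$patient$gender) && !report$patient$gender %in% MG_GENDERS) {
    fail("patient.gender", paste("must be one of", paste(MG_GENDERS, collapse = ", ")))
  }
  for (i in seq_along(report$results$variants %||% list())) {
    v <- report$results$variants[[i]]
    at <- function(f) sprintf("results.variants[%d].%s", i, f)
    if (!mg_has(v$dna_change_c) && !mg_has(v$dna_change_g) && !mg_has(v$protein_change)) {
      fail(at("dna_change_c|dna_change_g|protein_change"),
           "at least one HGVS change must be present")
    }
    if (!mg_has(v$origin)) {
      fail(at("origin"), "variant origin is a required data element")
    } else if (!v$origin %in% MG_ORIGINS) {
      fail(at("origin"), paste("must be one of", paste(MG_ORIGINS, collapse = ", ")))
    }
    if (mg_has(v$allele_fraction) && (v$allele_fraction < 0 || v$allele_fraction > 1)) {
      fail(at("allele_fraction"), "must lie in [0, 1]")
    }
    if (mg_has(v$detection_limit) && (v$detection_limit < 0 || v$detection_limit > 1)) {
      fail(at("detection_limit"), "must lie in [0, 1] after percent normalization")
    }
    if (mg_has(v$allelic_state) && !v$allelic_state %in% MG_ALLELIC_STATES) {
      fail(at("allelic_state"), paste("must be one of", paste(MG_ALLELIC_STATES, collapse = ", ")))
    }
  }
  if (mg_has(report$results$msi_status) && !report$results$msi_status %in% MG_MSI) {
    fail("results.msi_status", paste("must be one of", paste(MG_MSI, collapse = ", ")))
  }
  cond_vs <- "vs-condition-code"
  for (i in seq_along(report$request$family_history %||% list())) {
    fh <- report$request$family_history[[i]]
    for (j in seq_along(fh$conditions %||% list())) {
      if (!code_in_valueset(fh$conditions[[j]], cond_vs)) {
        fail(sprintf("request.family_history[%d].conditions[%d]", i, j),
             "condition must be coded in SNOMED CT, ICD-10-GM, Alpha-ID or Orphanet")
      }
    }
  }
  for (i in seq_along(report$results$prs %||% list())) {
    p <- report$results$prs[[i]]
    at <- sprintf("results.prs[%d].value", i)
    if (identical(p$score_type, "probability")) {
      if (!mg_has(p$value) || !is.numeric(p$value) || p$value < 0 || p$value > 1) {
        fail(at, "probability score must lie in [0, 1]")
      }
    } else if (identical(p$score_type, "qualitative")) {
      if (!mg_has(p$value) || !p$value %in% MG_QUAL_RISK) {
        fail(at, paste("qualitative risk must be one of", paste(MG_QUAL_RISK, collapse = ", ")))
      }
    } else {
      fail(sprintf("results.prs[%d].score_type", i), "must be 'probability' or 'qualitative'")
    }
  }
  if (mg_has(report$interpretation$clinical_significance) &&
      !report$interpretation$clinical_significance %in% MG_SIGNIFICANCE) {
    fail("interpretation.clinical_significance",
         paste("must be one of", paste(MG_SIGNIFICANCE, collapse = ", ")))
  }
  if (mg_has(report$request$ebm_code) && !mg_ebm_ok(report$request$ebm_code)) {
    fail("request.ebm_code", "EBM code must be a five-digit fee schedule position")
  }
  bad
}

#' Construct a MolGen report from block lists
#'
#' Normalizes the blocks (percent-to-fraction conversion, relationship phrase
#' decomposition, canonical key order) and enforces the model's type
#' invariants.
#'
#' @param specimen,patient,request,methods,results,interpretation,misc Named
#'   lists; see the package vignette for the full field catalogue.
#' @return A `molgen_report`.
#' @export
molgen_report <- function(specimen = list(), patient = list(), request = list(),
                          methods = list(), results = list(),
                          interpretation = list(), misc = list()) {
  doc <- list(specimen = specimen, patient = patient, request = request,
              methods = methods, results = results,
              interpretation = interpretation, misc = misc)
  doc <- mg_normalize_report(doc)
  report <- structure(doc %||% list(), class = c("molgen_report", "list"))
  bad <- mg_report_violations(report)
  if (length(bad)) {
    mg_validation_error(paste0("report violates model invariants:\n  ",
                               paste(bad, collapse = "\n  ")))
  }
  report
}

#' @export
print.molgen_report <- function(x, ...) {
  nv <- length(x$results$variants %||% list())
  nf <- length(x$request$family_history %||% list())
  np <- length(x$results$prs %||% list())
  cat(sprintf("MolGen report %s [%s]: %d variant(s), %d family member(s), %d risk score(s)\n",
              x$misc$report_id %||% "<unidentified>", x$misc$status %||% "<no status>",
              nv, nf, np))
  invisible(x)
}

#' Read a MolGen report document
#'
#' Parses a JSON or YAML report document, reports (but keeps) unknown keys in
#' the `unknown_keys` attribute with a warning, normalizes units and
#' relationship phrases, and enforces the model invariants.
#'
#' @param x Path to a document or the document text itself.
#' @return A `molgen_report`.
#' @export
read_report <- function(x) {
  doc <- mg_parse_document(x)
  unknown <- mg_collect_unknown_keys(doc)
  report <- molgen_report(specimen = doc$specimen %||% list(),
                          patient = doc$patient %||% list(),
                          request = doc$request %||% list(),
                          methods = doc$methods %||% list(),
                          results = doc$results %||% list(),
                          interpretation = doc$interpretation %||% list(),
                          misc = doc$misc %||% list())
  if (length(unknown)) {
    attr(report, "unknown_keys") <- unknown
    warning(sprintf("unknown report keys kept but not modeled: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  report
}

#' Write a MolGen report as canonical JSON
#'
#' Emits key-sorted JSON with unset optional fields omitted; two deep-equal
#' reports serialize to byte-identical text and
#' `read_report(write_report(r))` is the identity on the model.
#'
#' @param report A `molgen_report`.
#' @param path Optional output file.
#' @return The JSON text (invisibly when written to `path`).
#' @export
write_report <- function(report, path = NULL) {
  txt <- mg_to_json(mg_canonical(unclass(report)))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# One predicate per registry element: is the element populated in the report?
# The map is total over the 76 registry elements (checked by a test).
mg_element_map <- function() {
  any_var <- function(field) function(r) {
    any(vapply(r$results$variants %||% list(), function(v) mg_has(v[[field]]), logical(1)))
  }
  any_fh <- function(field) function(r) {
    any(vapply(r$request$family_history %||% list(), function(f) mg_has(f[[field]]), logical(1)))
  }
  any_prs <- function(field) function(r) {
    any(vapply(r$results$prs %||% list(), function(p) mg_has(p[[field]]), logical(1)))
  }
  list(
    "sp-01" = function(r) mg_has(r$specimen$id),
    "sp-02" = function(r) mg_has(r$specimen$type),
    "sp-03" = function(r) mg_has(r$specimen$status),
    "sp-04" = function(r) mg_has(r$specimen$collected),
    "sp-05" = function(r) mg_has(r$specimen$method),
    "sp-06" = function(r) mg_has(r$specimen$body_site),
    "sp-07" = function(r) mg_has(r$specimen$additives),
    "sp-08" = function(r) mg_has(r$specimen$received),
    "sp-09" = function(r) mg_has(r$specimen$conditions),
    "sp-10" = function(r) mg_has(r$specimen$parent_id),
    "sp-11" = function(r) mg_has(r$specimen$notes),
    "pt-01" = function(r) mg_has(r$patient$name),
    "pt-02" = function(r) mg_has(r$patient$birth_date) || mg_has(r$patient$age),
    "pt-03" = function(r) mg_has(r$patient$gender),
    "pt-04" = function(r) mg_has(r$patient$identifier),
    "pt-05" = function(r) mg_has(r$patient),
    "rq-01" = function(r) mg_has(r$request$id),
    "rq-02" = function(r) mg_has(r$request$status),
    "rq-03" = function(r) mg_has(r$request$intent),
    "rq-04" = function(r) mg_has(r$request$code),
    "rq-05" = function(r) mg_has(r$request$requester),
    "rq-06" = function(r) mg_has(r$request$authored_on),
    "rq-07" = function(r) mg_has(r$request$reasons),
    "rq-08" = function(r) mg_has(r$request$reason_phenotypes),
    "rq-09" = function(r) mg_has(r$request$supporting_info),
    "rq-10" = any_fh("relation"),
    "rq-11" = any_fh("conditions"),
    "rq-12" = function(r) mg_has(r$request$ebm_code),
    "rq-13" = function(r) mg_has(r$request$performer_requested),
    "mt-01" = function(r) mg_has(r$methods$test_method),
    "mt-02" = function(r) mg_has(r$methods$device),
    "mt-03" = function(r) mg_has(r$methods$read_depth),
    "mt-04" = function(r) mg_has(r$methods$coverage),
    "mt-05" = any_var("detection_limit"),
    "mt-06" = function(r) mg_has(r$methods$primer),
    "mt-07" = function(r) mg_has(r$methods$region_description),
    "mt-08" = function(r) mg_has(r$methods$reference_assembly),
    "mt-09" = function(r) mg_has(r$methods$gene_panel),
    "mt-10" = function(r) mg_has(r$methods$notes),
    "rs-01" = any_var("variant_id"),
    "rs-02" = any_var("gene"),
    "rs-03" = any_var("dna_change_c"),
    "rs-04" = any_var("dna_change_g"),
    "rs-05" = any_var("protein_change"),
    "rs-06" = any_var("origin"),
    "rs-07" = any_var("cytogenetic_location"),
    "rs-08" = any_var("allelic_state"),
    "rs-09" = any_var("allele_fraction"),
    "rs-10" = any_var("copy_number"),
    "rs-11" = any_var("variant_type"),
    "rs-12" = any_var("transcript_ref"),
    "rs-13" = any_var("genomic_ref"),
    "rs-14" = any_var("exact_start"),
    "rs-15" = function(r) mg_has(r$results$msi_status),
    "rs-16" = function(r) mg_has(r$results$mutational_burden),
    "rs-17" = function(r) mg_has(r$results$summary),
    "rs-18" = function(r) mg_has(r$results$genotype),
    "rs-19" = any_prs("value"),
    "rs-20" = any_prs("influence_factors"),
    "in-01" = function(r) mg_has(r$interpretation$clinical_significance),
    "in-02" = function(r) mg_has(r$interpretation$evidence_level),
    "in-03" = function(r) mg_has(r$interpretation$associated_phenotypes),
    "in-04" = function(r) mg_has(r$interpretation$medication_assessed),
    "in-05" = function(r) mg_has(r$interpretation$medication_recommendation),
    "in-06" = function(r) mg_has(r$interpretation$general_recommendation),
    "in-07" = function(r) mg_has(r$interpretation$therapeutic_implication),
    "in-08" = function(r) mg_has(r$interpretation$summary),
    "in-09" = function(r) mg_has(r$interpretation$recommended_action_target),
    "ms-01" = function(r) mg_has(r$misc$report_id),
    "ms-02" = function(r) mg_has(r$misc$status),
    "ms-03" = function(r) mg_has(r$misc$issued),
    "ms-04" = function(r) mg_has(r$misc$attachments),
    "ms-05" = function(r) any(vapply(r$misc$attachments %||% list(),
                                     function(a) mg_has(a$mime), logical(1))),
    "ms-06" = function(r) mg_has(r$misc$performer$name),
    "ms-07" = function(r) mg_has(r$misc$performer$contact),
    "ms-08" = function(r) mg_has(r$request$ebm_code)
  )
}

#' Required-element completeness of a report
#'
#' Compares the populated fields against the registry's requirement flags.
#'
#' @param report A `molgen_report`.
#' @param registry A registry as returned by [load_registry()].
#' @return A list with `missing_required` (element ids) and
#'   `coverage_fraction` (populated required / total required).
#' @export
completeness <- function(report, registry = load_registry()) {
  map <- mg_element_map()
  req <- registry$elements$element_id[registry$elements$requirement == "required"]
  populated <- vapply(req, function(id) isTRUE(map[[id]](report)), logical(1))
  list(missing_required = req[!populated],
       coverage_fraction = if (length(req)) sum(populated) / length(req) else 1)
}

#' Export the report document schema
#'
#' A compact JSON-schema style description of the report model's blocks and
#' keys, for consumers writing report documents by hand.
#'
#' @return JSON text.
#' @export
report_schema <- function() {
  keys <- mg_report_schema_keys()
  props <- lapply(keys, function(blk) {
    list(type = "object",
         properties = lapply(blk, function(sub) {
           if (is.null(sub)) list(type = c("string", "number", "array")) else
             list(type = c("object", "array"), keys = sub)
         }))
  })
  mg_to_json(list(`$schema` = "http://json-schema.org/draft-07/schema#",
                  title = "MolGen report document", type = "object",
                  properties = props))
}
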