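#' @title Declarative profile-conformance validation
#' @description Validates FHIR bundles against the registered MolGen profile
#'   specifications: cardinalities, fixed codes, value-set bindings (required
#'   bindings raise errors, extensible ones warnings), the condition-code
#'   slice (SNOMED CT / ICD-10-GM / Alpha-ID / Orphanet), syntactic HGVS
#'   checks on variant components, fraction and percent ranges, ISCN system
#'   fixing on cytogenetic locations, EBM code shape on ChargeItem,
#'   referential closure of the bundle and must-support presence notes
#'   (information level, never errors). Validation is performed against the
#'   packaged declarative rules, not by an external FHIR validator.
#' @name validator
NULL

mg_issue <- function(severity, profile_id, path, rule_id, message, entry_index) {
  data.frame(severity = severity, profile_id = profile_id, path = path,
             rule_id = rule_id, message = message, entry_index = entry_index,
             stringsAsFactors = FALSE)
}

mg_empty_issues <- function() {
  mg_issue(character(0), character(0), character(0), character(0),
           character(0), integer(0))[0, ]
}

# Resolve a constraint path within a resource. Handles dotted segments,
# `component:slice` (discriminated by the packaged slice codes),
# `extension:name` (discriminated by url suffix) and `value[x]` choices.
# Arrays are traversed transparently. Returns the list of matched nodes.
mg_resolve_path <- function(resource, path, registry) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]][-1]  # drop resource type
  nodes <- list(resource)
  for (seg in segs) {
    nxt <- list()
    for (node in nodes) {
      items <- if (!is.null(names(node))) list(node) else node
      for (it in items) {
        if (!is.list(it)) next
        if (seg == "value[x]" || grepl("\\[x\\]$", seg)) {
          stem <- sub("\\[x\\]$", "", seg)
          keys <- names(it)[startsWith(names(it), stem)]
          for (k in keys) nxt <- c(nxt, list(it[[k]]))
        } else if (startsWith(seg, "component:")) {
          slice <- sub("^component:", "", seg)
          hit <- mg_comps_by_slice(it, slice, registry)
          nxt <- c(nxt, hit)
        } else if (startsWith(seg, "extension:")) {
          name <- sub("^extension:", "", seg)
          for (ext in it$extension %||% list()) {
            if (endsWith(ext$url %||% "", name)) nxt <- c(nxt, list(ext))
          }
        } else {
          val <- it[[seg]]
          if (is.null(val)) next
          if (is.list(val) && is.null(names(val))) {
            nxt <- c(nxt, val)
          } else {
            nxt <- c(nxt, list(val))
          }
        }
      }
    }
    nodes <- nxt
  }
  nodes
}

# Collect codings carried by a resolved node: a CodeableConcept, a Coding, a
# component (its value[x]) or an extension (its valueCoding/-CodeableConcept).
mg_node_codings <- function(node) {
  if (!is.list(node)) return(list())
  if (is.character(node$system %||% NULL) && is.character(node$code %||% NULL)) {
    return(list(node))  # a bare Coding
  }
  out <- list()
  if (!is.null(node$coding)) out <- c(out, node$coding)
  # note: a component's slice discriminator (its `code`) is deliberately not
  # collected; bindings apply to the component's value
  for (key in c("valueCodeableConcept", "valueCoding")) {
    sub <- node[[key]]
    if (is.list(sub)) {
      if (!is.null(sub$coding)) out <- c(out, sub$coding)
      else if (!is.null(sub$system)) out <- c(out, list(sub))
    }
  }
  out
}

mg_node_number <- function(node) {
  if (is.numeric(node)) return(node)
  if (!is.list(node)) return(NULL)
  for (key in c("valueQuantity", "probabilityDecimal", "value")) {
    v <- node[[key]]
    if (is.numeric(v)) return(v)
    if (is.list(v) && is.numeric(v$value)) return(v$value)
  }
  NULL
}

mg_node_string <- function(node) {
  if (is.character(node)) return(node)
  if (!is.list(node)) return(NULL)
  if (is.character(node$valueString %||% NULL)) return(node$valueString)
  cds <- mg_node_codings(node)
  if (length(cds)) return(cds[[1]]$code %||% NULL)
  NULL
}

mg_validate_resource <- function(resource, profile, entry_index, registry) {
  issues <- list()
  pid <- profile$profile_id
  push <- function(severity, path, kind, message) {
    issues[[length(issues) + 1L]] <<- mg_issue(
      severity, pid, sprintf("entry[%d].%s", entry_index, path),
      paste(pid, path, kind, sep = "/"), message, entry_index)
  }
  for (rule in profile$constraints) {
    nodes <- mg_resolve_path(resource, rule$path, registry)
    n <- length(nodes)
    if (n < rule$min) {
      push("error", rule$path, "card-min",
           sprintf("expected at least %d occurrence(s), found %d", rule$min, n))
      next
    }
    if (!identical(rule$max, "many") && n > as.numeric(rule$max)) {
      push("error", rule$path, "card-max",
           sprintf("expected at most %s occurrence(s), found %d", rule$max, n))
    }
    if (n == 0L) {
      if (isTRUE(rule$must_support)) {
        push("information", rule$path, "must-support",
             "must-support element is absent")
      }
      next
    }
    if (!is.null(rule$fixed)) {
      ok <- any(vapply(nodes, function(nd) {
        any(vapply(mg_node_codings(nd), function(cd) {
          identical(cd$system, rule$fixed$system) && identical(cd$code, rule$fixed$code)
        }, logical(1)))
      }, logical(1)))
      if (!ok) {
        push("error", rule$path, "fixed-value",
             sprintf("fixed coding %s|%s not present", rule$fixed$system, rule$fixed$code))
      }
    }
    if (!is.null(rule$binding)) {
      severity <- if (identical(rule$binding$strength, "required")) "error" else "warning"
      for (nd in nodes) {
        cds <- mg_node_codings(nd)
        if (!length(cds)) next  # text-only concepts pass open bindings
        ok <- any(vapply(cds, function(cd) code_in_valueset(cd, rule$binding$vs_id), logical(1)))
        if (!ok) {
          push(severity, rule$path, "binding",
               sprintf("no coding from value set %s (%s binding)",
                       rule$binding$vs_id, rule$binding$strength))
        }
      }
    }
    if (!is.null(rule$slice_systems)) {
      vs <- value_set(rule$slice_systems)
      allowed <- unlist(vs$systems)
      for (nd in nodes) {
        cds <- mg_node_codings(nd)
        ok <- length(cds) > 0 &&
          any(vapply(cds, function(cd) (cd$system %||% "") %in% allowed, logical(1)))
        if (!ok) {
          push("error", rule$path, "slice-systems",
               sprintf("code must come from one of the permitted systems: %s",
                       paste(allowed, collapse = ", ")))
        }
      }
    }
    if (!is.null(rule$system_fixed)) {
      for (nd in nodes) {
        cds <- mg_node_codings(nd)
        ok <- length(cds) > 0 &&
          all(vapply(cds, function(cd) identical(cd$system, rule$system_fixed), logical(1)))
        if (!ok) {
          push("error", rule$path, "system-fixed",
               sprintf("codings must use system %s", rule$system_fixed))
        }
      }
    }
    if (!is.null(rule$hgvs_level)) {
      for (nd in nodes) {
        expr <- mg_node_string(nd)
        if (is.null(expr)) next
        res <- validate_hgvs(expr, rule$hgvs_level)
        if (!res$valid) {
          push("error", rule$path, "hgvs",
               sprintf("'%s' is not valid HGVS %s.: %s", expr, rule$hgvs_level, res$reason))
        }
      }
    }
    if (isTRUE(rule$fraction_range)) {
      for (nd in nodes) {
        val <- mg_node_number(nd)
        if (!is.null(val) && (val < 0 || val > 1)) {
          push("error", rule$path, "fraction-range",
               sprintf("value %s outside [0, 1]", format(val)))
        }
      }
    }
    if (isTRUE(rule$percent_range)) {
      for (nd in nodes) {
        val <- mg_node_number(nd)
        if (!is.null(val) && (val < 0 || val > 100)) {
          push("error", rule$path, "percent-range",
               sprintf("value %s outside [0, 100]", format(val)))
        }
      }
    }
  }
  issues
}

#' Validate a FHIR bundle against the MolGen profiles
#'
#' @param bundle A bundle list, JSON text or path to a JSON file.
#' @param profile_set Optional character vector of profile ids to restrict the
#'   checks to.
#' @return A data.frame of validation issues (`severity`, `profile_id`,
#'   `path`, `rule_id`, `message`, `entry_index`), deterministically ordered
#'   by entry index then path; zero rows iff fully conformant.
#' @export
validate_bundle <- function(bundle, profile_set = NULL) {
  bundle <- mg_as_bundle(bundle)
  registry <- load_registry()
  entries <- bundle$entry %||% list()
  issues <- list()

  urls <- vapply(entries, function(e) e$fullUrl %||% NA_character_, character(1))
  refs <- unique(mg_collect_references(entries))
  dangling <- setdiff(refs[startsWith(refs, "urn:")], urls)
  for (d in dangling) {
    issues[[length(issues) + 1L]] <- mg_issue(
      "error", "bundle", "Bundle.entry", "bundle/reference-closure",
      sprintf("reference %s does not resolve to an entry fullUrl", d), 0L)
  }

  n_dr <- sum(vapply(entries, function(e)
    identical(e$resource$resourceType, "DiagnosticReport"), logical(1)))
  if (n_dr != 1L) {
    issues[[length(issues) + 1L]] <- mg_issue(
      "error", "bundle", "Bundle.entry", "bundle/single-diagnostic-report",
      sprintf("bundle must contain exactly one DiagnosticReport, found %d", n_dr), 0L)
  }

  for (i in seq_along(entries)) {
    res <- entries[[i]]$resource
    if (identical(res$resourceType, "ChargeItem")) {
      code <- mg_first(res$code$coding)$code %||% ""
      if (!mg_ebm_ok(code)) {
        issues[[length(issues) + 1L]] <- mg_issue(
          "error", "chargeitem", sprintf("entry[%d].ChargeItem.code", i),
          "chargeitem/ebm-shape",
          sprintf("'%s' is not a five-digit EBM fee schedule position", code), i)
      }
      next
    }
    pid <- mg_entry_profile(entries[[i]])
    if (is.na(pid) || is.null(registry$profiles[[pid]])) next
    if (!is.null(profile_set) && !pid %in% profile_set) next
    prof <- registry$profiles[[pid]]
    if (!identical(res$resourceType, prof$base_resource)) {
      issues[[length(issues) + 1L]] <- mg_issue(
        "error", pid, sprintf("entry[%d].resourceType", i), paste0(pid, "/base-resource"),
        sprintf("resource claims profile %s but is a %s, not a %s",
                pid, res$resourceType %||% "?", prof$base_resource), i)
      next
    }
    issues <- c(issues, mg_validate_resource(res, prof, i, registry))
  }

  if (!length(issues)) return(mg_empty_issues())
  out <- do.call(rbind, issues)
  out <- out[order(out$entry_index, out$path, out$rule_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Materialize the SearchParameter definitions
#'
#' The seven additional SearchParameter resources of the specification:
#' `ServiceRequest.reasonCode`/`reasonReference`,
#' `FamilyMemberHistory.reasonCode`/`reasonReference` and `Task.for`/
#' `reasonCode`/`reasonReference`.
#'
#' @param config A [molgen_config()] for the canonical URL base.
#' @return A list of FHIR `SearchParameter` structures in stable (sp_id) order.
#' @export
emit_search_parameters <- function(config = molgen_config()) {
  sp <- load_registry()$search_parameters
  lapply(seq_len(nrow(sp)), function(i) {
    row <- sp[i, ]
    list(
      resourceType = "SearchParameter",
      id = row$sp_id,
      url = paste0(sub("/StructureDefinition$", "", config$canonical_base),
                   "/SearchParameter/", row$sp_id),
      name = row$sp_id,
      status = "active",
      code = tolower(sub("^[A-Za-z]+\\.", "", row$expression)),
      base = list(row$base_resource),
      type = row$type,
      expression = row$expression
    )
  })
}
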