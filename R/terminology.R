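#' @title Terminology layer
#' @description Code-system metadata, the value sets bound by the MolGen
#'   profiles and a syntactic HGVS validator. All checks run from packaged
#'   data; there is no terminology-server integration and no network access.
#' @name terminology
NULL

mg_terminology <- function() {
  if (is.null(.mg_cache$terminology)) {
    .mg_cache$terminology <- jsonlite::fromJSON(mg_data_file("value_sets.json"),
                                                simplifyVector = FALSE)
  }
  .mg_cache$terminology
}

#' Known code systems
#'
#' The code systems the MolGen specification relies on: SNOMED CT, LOINC,
#' HGVS, ICD-10-GM, Alpha-ID, Orphanet, EBM, ISCN (under NCBI's OID
#' `urn:oid:2.16.840.1.113883.6.335`) and v3.RoleCode, among others.
#'
#' @return A data.frame with columns `name` and `uri_or_oid`.
#' @export
known_systems <- function() {
  sys <- mg_terminology()$systems
  data.frame(
    name = vapply(sys, function(s) s$name, character(1)),
    uri_or_oid = vapply(sys, function(s) s$uri_or_oid, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Retrieve a packaged value set definition
#'
#' @param vs_id Value set token, e.g. `"vs-condition-code"`.
#' @return A list with `vs_id`, `description`, `systems` and optional explicit
#'   `members`.
#' @export
value_set <- function(vs_id) {
  vss <- mg_terminology()$value_sets
  ids <- vapply(vss, function(v) v$vs_id, character(1))
  hit <- which(ids == vs_id)
  if (length(hit) != 1L) {
    mg_not_found_error(sprintf("unknown value set '%s'; available: %s",
                               vs_id, paste(ids, collapse = ", ")))
  }
  vss[[hit]]
}

#' Construct a coded concept
#'
#' @param system Canonical URI or OID of the code system (non-empty).
#' @param code Code token (non-empty, no surrounding whitespace).
#' @param display Optional display text.
#' @return A `coded_concept` list.
#' @export
coded_concept <- function(system, code, display = NULL) {
  if (!is.character(system) || length(system) != 1L || !nzchar(system)) {
    mg_domain_error("coded_concept: system must be a non-empty string")
  }
  if (!is.character(code) || length(code) != 1L || !nzchar(code) || code != trimws(code)) {
    mg_domain_error("coded_concept: code must be non-empty without surrounding whitespace")
  }
  out <- list(system = system, code = code)
  if (!is.null(display)) out$display <- display
  structure(out, class = c("coded_concept", "list"))
}

#' Test value-set membership of a coded concept
#'
#' For system-enumerated value sets the concept matches when its system is one
#' of the listed systems; when the value set carries explicit members the code
#' must additionally be listed. Pure function of its inputs.
#'
#' @param concept A [coded_concept()] or a list with `system` and `code`.
#' @param vs_id Value set token.
#' @return `TRUE` or `FALSE`.
#' @export
code_in_valueset <- function(concept, vs_id) {
  vs <- value_set(vs_id)
  system <- concept$system %||% ""
  code <- concept$code %||% ""
  if (!nzchar(system) || !nzchar(code)) return(FALSE)
  systems <- unlist(vs$systems)
  if (!system %in% systems) return(FALSE)
  if (is.null(vs$members)) return(TRUE)
  any(vapply(vs$members, function(m) m$system == system && m$code == code, logical(1)))
}

# --- HGVS -------------------------------------------------------------------

MG_AA3 <- "(?:Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Sec|Ser|Thr|Trp|Tyr|Val)"

mg_hgvs_refseq <- "(?:(?:N[CGMPRTW]_[0-9]+(?:\\.[0-9]+)?|LRG_[0-9]+(?:[pt][0-9]+)?):)?"

mg_hgvs_nuc_body <- function() {
  pos <- "[*-]?[0-9]+(?:[+-][0-9]+)?"
  rng <- sprintf("%s(?:_%s)?", pos, pos)
  paste0(
    "(?:",
    sprintf("%s[ACGT]>[ACGT]", pos), "|",                     # substitution
    sprintf("%sdelins[ACGT]+", rng), "|",                     # deletion-insertion
    sprintf("%s(?:del|dup)(?:[ACGT]+|[0-9]+)?", rng), "|",    # deletion / duplication
    sprintf("%s_%sins[ACGT]+", pos, pos),                     # insertion
    ")"
  )
}

mg_hgvs_prot_body <- function() {
  aa <- MG_AA3
  paste0(
    "(?:",
    sprintf("%s[0-9]+(?:%s|Ter|\\*)", aa, aa), "|",                      # substitution / stop gain
    sprintf("%s[0-9]+(?:%s)?fs(?:(?:Ter|\\*)[0-9]+)?", aa, aa), "|",     # frameshift
    sprintf("%s[0-9]+(?:_%s[0-9]+)?(?:del|dup)", aa, aa),                # deletion / duplication
    ")"
  )
}

#' Syntactic HGVS validation
#'
#' Validates a sequence-variant expression against an explicit grammar subset
#' of the HGVS nomenclature: substitutions, deletions, duplications,
#' insertions and deletion-insertions at the coding (`c.`), genomic (`g.`) and
#' non-coding (`n.`) DNA levels, and three-letter substitutions, frameshifts
#' (`fs`), stop gains (`Ter`) and in-frame del/dup at the protein (`p.`)
#' level, each with an optional RefSeq/LRG reference-sequence prefix.
#' Expressions outside the subset (RNA `r.` level, mosaicism, complex
#' rearrangements) return `valid = FALSE` with a reason; the function never
#' raises on arbitrary non-empty text.
#'
#' @param expr The HGVS expression (surrounding whitespace is ignored).
#' @param level Expected description level: `"c"`, `"g"`, `"n"` or `"p"`.
#' @return A list with `valid` (logical) and `reason` (`NULL` when valid).
#' @examples
#' validate_hgvs("NM_004333.4:c.1799T>A", "c")$valid  # TRUE
#' validate_hgvs("p.Val600Glu", "p")$valid            # TRUE
#' @export
validate_hgvs <- function(expr, level = c("c", "g", "p", "n")) {
  level <- match.arg(level)
  if (!is.character(expr) || length(expr) != 1L || is.na(expr) || !nzchar(trimws(expr))) {
    mg_domain_error("validate_hgvs: expr must be non-empty text")
  }
  expr <- trimws(expr)
  invalid <- function(reason) list(valid = FALSE, reason = reason)

  m <- regmatches(expr, regexec(paste0("^", mg_hgvs_refseq, "([a-z])\\.(.*)$"), expr))[[1]]
  if (length(m) == 0L) {
    return(invalid("expression lacks a '<level>.' description prefix"))
  }
  found_level <- m[2]
  body <- m[3]
  if (found_level != level) {
    return(invalid(sprintf("expected a '%s.' expression but found '%s.'", level, found_level)))
  }
  if (!nzchar(body)) return(invalid("empty description after level prefix"))

  body_re <- if (level == "p") mg_hgvs_prot_body() else mg_hgvs_nuc_body()
  if (grepl(paste0("^", body_re, "$"), body, perl = TRUE)) {
    return(list(valid = TRUE, reason = NULL))
  }
  if (level != "p" && grepl(">[ACGT]?$", body) && !grepl("[ACGT]>[ACGT]$", body)) {
    return(invalid("substitution is missing the alternate base after '>'"))
  }
  if (level != "p" && grepl("[ACGT]$", body) && grepl("^[*-]?[0-9]", body) && !grepl("[>_a-z]", body)) {
    return(invalid("substitution is missing the '>' and alternate base"))
  }
  invalid(sprintf("'%s' does not match the supported %s. grammar subset", body, level))
}

# EBM billing codes are validated by shape only (five-digit fee schedule
# positions); the fee schedule content itself is out of scope.
mg_ebm_ok <- function(code) {
  is.character(code) && length(code) == 1L && grepl("^[0-9]{5}$", code)
}

#' Export packaged value sets as FHIR ValueSet JSON stubs
#'
#' @param path Optional directory to write one `<vs_id>.json` per value set.
#' @return A named list of FHIR `ValueSet` structures (invisibly when written).
#' @export
export_value_sets <- function(path = NULL) {
  vss <- mg_terminology()$value_sets
  out <- lapply(vss, function(v) {
    compose <- lapply(unlist(v$systems), function(s) {
      inc <- list(system = s)
      if (!is.null(v$members)) {
        codes <- Filter(function(m) m$system == s, v$members)
        if (length(codes)) {
          inc$concept <- lapply(codes, function(m) list(code = m$code, display = m$display %||% m$code))
        }
      }
      inc
    })
    list(resourceType = "ValueSet", id = v$vs_id, status = "active",
         description = v$description, compose = list(include = compose))
  })
  names(out) <- vapply(vss, function(v) v$vs_id, character(1))
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (id in names(out)) {
      writeLines(mg_to_json(out[[id]]), file.path(path, paste0(id, ".json")))
    }
    return(invisible(out))
  }
  out
}
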