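`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
mg_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "molgenfhir_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

mg_load_error <- function(msg, ...) mg_abort(msg, "molgenfhir_load_error", ...)
mg_link_error <- function(msg, ...) mg_abort(msg, "molgenfhir_link_error", ...)
mg_domain_error <- function(msg, ...) mg_abort(msg, "molgenfhir_domain_error", ...)
mg_not_found_error <- function(msg, ...) mg_abort(msg, "molgenfhir_not_found_error", ...)
mg_validation_error <- function(msg, ...) mg_abort(msg, "molgenfhir_validation_error", ...)
mg_format_error <- function(msg, ...) mg_abort(msg, "molgenfhir_format_error", ...)
mg_structural_error <- function(msg, ...) mg_abort(msg, "molgenfhir_structural_error", ...)
mg_referential_error <- function(msg, ...) mg_abort(msg, "molgenfhir_referential_error", ...)
mg_mapping_error <- function(msg, ...) mg_abort(msg, "molgenfhir_mapping_error", ...)
mg_ambiguity_error <- function(msg, ...) mg_abort(msg, "molgenfhir_ambiguity_error", ...)
mg_unsupported_mapping_error <- function(msg, ...) mg_abort(msg, "molgenfhir_unsupported_mapping_error", ...)

#' @noRd
mg_data_file <- function(...) {
  path <- system.file("extdata", "registry", ..., package = "molgenfhir")
  if (!nzchar(path)) {
    mg_load_error(sprintf("packaged registry file not found: %s", paste(c(...), collapse = "/")))
  }
  path
}

# Drop NULLs and zero-length branches recursively; sort names. Canonical form
# shared by the report writer and deep-equality checks.
mg_canonical <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, mg_canonical)
    x <- x[!vapply(x, is.null, logical(1))]
    if (length(x) == 0L) return(NULL)
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm, method = "radix")]
    return(x)
  }
  if (length(x) == 0L) return(NULL)
  x
}

#' @noRd
mg_to_json <- function(x, pretty = TRUE) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                                na = "null", pretty = pretty))
}

# Parse JSON or YAML text/file into plain nested lists.
mg_parse_document <- function(x) {
  is_path <- length(x) == 1L && !grepl("[\n{]", x) && file.exists(x)
  txt <- if (is_path) paste(readLines(x, warn = FALSE), collapse = "\n") else paste(x, collapse = "\n")
  trimmed <- sub("^[[:space:]]+", "", txt)
  if (startsWith(trimmed, "{") || startsWith(trimmed, "[")) {
    out <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                    error = function(e) mg_format_error(sprintf("JSON parse failure: %s", conditionMessage(e))))
  } else {
    out <- tryCatch(yaml::yaml.load(txt),
                    error = function(e) mg_format_error(sprintf("YAML parse failure: %s", conditionMessage(e))))
  }
  if (!is.list(out)) mg_format_error("document did not parse to an object")
  out
}
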