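#' @title Kinship coding
#' @description Family relationships are coded on three axes -- lineage
#'   (maternal/paternal blood relation), degree of relationship and the
#'   relationship type itself -- because some reporting sites record a single
#'   combined concept while others split it into the three components. The
#'   expected autosomal shared-DNA fraction follows the geometric law
#'   0.5^degree (first degree 50%, second degree 25%, and so on); special
#'   cases that break the law (identical twins, X-linked sharing) are out of
#'   scope.
#' @name kinship
NULL

mg_kinship <- function() {
  if (is.null(.mg_cache$kinship)) {
    .mg_cache$kinship <- jsonlite::fromJSON(mg_data_file("kinship.json"),
                                            simplifyVector = FALSE)
  }
  .mg_cache$kinship
}

#' Packaged relationship vocabulary
#'
#' @return A data.frame with `relation_type`, `degree`, `shared_dna`
#'   (0.5^degree) and `lineage_applicable`.
#' @export
kinship_vocabulary <- function() {
  rt <- mg_kinship()$relation_types
  data.frame(
    relation_type = vapply(rt, function(r) r$relation_type, character(1)),
    degree = vapply(rt, function(r) as.integer(r$degree), integer(1)),
    shared_dna = vapply(rt, function(r) 0.5^r$degree, double(1)),
    lineage_applicable = vapply(rt, function(r) isTRUE(r$lineage_applicable), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Degree and expected shared DNA of a relationship type
#'
#' @param relation_type Token from [kinship_vocabulary()], e.g. `"parent"`.
#' @return A list with `degree` (integer >= 1) and `shared_dna` (0.5^degree).
#' @examples
#' degree_of("parent")       # degree 1, shared_dna 0.5
#' degree_of("grandparent")  # degree 2, shared_dna 0.25
#' @export
degree_of <- function(relation_type) {
  voc <- kinship_vocabulary()
  hit <- which(voc$relation_type == relation_type)
  if (length(hit) != 1L) {
    mg_not_found_error(sprintf("unknown relation_type '%s'; vocabulary: %s",
                               as.character(relation_type)[1],
                               paste(voc$relation_type, collapse = ", ")))
  }
  list(degree = voc$degree[hit], shared_dna = voc$shared_dna[hit])
}

#' Construct a relationship triple
#'
#' @param relation_type Token from the packaged vocabulary.
#' @param lineage `"maternal"`, `"paternal"` or `"unspecified"`. Must be
#'   `"unspecified"` for relation types where lineage is undefined (e.g.
#'   `child`).
#' @return A `relationship_triple` with `lineage`, `degree`, `relation_type`.
#' @export
relationship_triple <- function(relation_type, lineage = "unspecified") {
  if (!lineage %in% c("maternal", "paternal", "unspecified")) {
    mg_domain_error("lineage must be maternal, paternal or unspecified")
  }
  voc <- kinship_vocabulary()
  d <- degree_of(relation_type)
  applicable <- voc$lineage_applicable[voc$relation_type == relation_type]
  if (!applicable && lineage != "unspecified") {
    mg_domain_error(sprintf("lineage is undefined for relation type '%s'", relation_type))
  }
  structure(list(lineage = lineage, degree = d$degree, relation_type = relation_type),
            class = c("relationship_triple", "list"))
}

mg_combined_table <- function() {
  cc <- mg_kinship()$combined_concepts
  data.frame(
    display = vapply(cc, function(x) x$display, character(1)),
    lineage = vapply(cc, function(x) x$lineage, character(1)),
    relation_type = vapply(cc, function(x) x$relation_type, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Canonical display phrase of a relationship triple
#'
#' @param triple A [relationship_triple()].
#' @return The canonical combined-concept display, or `NA` when the packaged
#'   table has no entry.
#' @export
relationship_display <- function(triple) {
  tab <- mg_combined_table()
  hit <- which(tab$lineage == triple$lineage & tab$relation_type == triple$relation_type)
  if (length(hit) != 1L) return(NA_character_)
  tab$display[hit]
}

#' Decompose a combined relationship concept or phrase
#'
#' Accepts a combined-concept phrase (`"maternal grandmother"`), a single
#' combined [coded_concept()] from the v3.RoleCode or SNOMED FamilyMember
#' tables, or a list of axis concepts as produced by
#' [compose_relationship()], and returns the lineage/degree/type triple.
#'
#' @param x Phrase, coded concept, or list of coded concepts.
#' @return A [relationship_triple()].
#' @examples
#' decompose_relationship("maternal grandmother")  # maternal / 2 / grandparent
#' @export
decompose_relationship <- function(x) {
  kin <- mg_kinship()
  tab <- mg_combined_table()

  if (is.character(x) && length(x) == 1L) {
    phrase <- tolower(trimws(x))
    if (phrase %in% c("self", "proband", "patient")) {
      mg_ambiguity_error(sprintf("'%s' is not a family member relationship", phrase))
    }
    hit <- which(tab$display == phrase)
    if (length(hit) == 0L) {
      aliases <- kin$phrase_aliases
      anames <- vapply(aliases, function(a) a$phrase, character(1))
      ahit <- which(anames == phrase)
      if (length(ahit) == 1L) {
        hit <- which(tab$display == aliases[[ahit]]$display)
      }
    }
    if (length(hit) == 0L) {
      # partial matches produce an ambiguity error listing candidates
      cand <- tab$display[grepl(phrase, tab$display, fixed = TRUE)]
      if (length(cand) > 1L) {
        mg_ambiguity_error(sprintf("phrase '%s' is ambiguous; candidates: %s",
                                   phrase, paste(cand, collapse = ", ")))
      }
      if (length(cand) == 1L) hit <- which(tab$display == cand)
    }
    if (length(hit) != 1L) {
      mg_not_found_error(sprintf("unrecognized relationship phrase '%s'", phrase))
    }
    return(relationship_triple(tab$relation_type[hit], tab$lineage[hit]))
  }

  if (is.list(x) && !is.null(x$code)) x <- list(x)  # single concept
  if (is.list(x)) {
    sn <- kin$snomed_axis_codes
    v3 <- kin$v3_rolecode$codes
    lineage <- "unspecified"; rtype <- NULL
    for (concept in x) {
      code <- concept$code %||% ""
      system <- concept$system %||% ""
      if (system == "http://terminology.hl7.org/CodeSystem/v3-RoleCode") {
        keys <- names(v3)
        khit <- keys[vapply(v3, function(v) v$code == code, logical(1))]
        if (length(khit) == 1L) {
          parts <- strsplit(khit, "|", fixed = TRUE)[[1]]
          return(relationship_triple(parts[2], parts[1]))
        }
        mg_not_found_error(sprintf("unrecognized v3.RoleCode relationship code '%s'", code))
      }
      for (ln in names(sn$lineage)) if (sn$lineage[[ln]]$code == code) lineage <- ln
      for (ty in names(sn$type)) if (sn$type[[ty]]$code == code) rtype <- ty
    }
    if (is.null(rtype)) {
      mg_not_found_error("no relationship-type concept recognized in the supplied coding")
    }
    return(relationship_triple(rtype, lineage))
  }
  mg_domain_error("decompose_relationship: expected a phrase or coded concept(s)")
}

#' Compose a relationship triple into coded concepts
#'
#' Under `snomed_familymember` the triple is emitted as up to three axis
#' concepts (lineage, degree, type). SNOMED degree concepts exist only for
#' first and second degree blood relatives; for degrees three and four the
#' type concept is emitted together with a textual degree annotation (in the
#' `degree_annotation` attribute) instead of a degree concept. Under
#' `v3_rolecode` a single combined role concept is emitted; triples without a
#' v3 representation raise an unsupported-mapping error.
#'
#' @param triple A [relationship_triple()].
#' @param scheme `"snomed_familymember"` or `"v3_rolecode"`.
#' @return A list of [coded_concept()]s; for degree > 2 under SNOMED the list
#'   carries a `degree_annotation` attribute.
#' @export
compose_relationship <- function(triple, scheme = c("snomed_familymember", "v3_rolecode")) {
  scheme <- match.arg(scheme)
  kin <- mg_kinship()
  if (scheme == "v3_rolecode") {
    key <- paste(triple$lineage, triple$relation_type, sep = "|")
    entry <- kin$v3_rolecode$codes[[key]]
    if (is.null(entry)) {
      mg_unsupported_mapping_error(sprintf(
        "no v3.RoleCode concept for %s %s", triple$lineage, triple$relation_type))
    }
    return(list(coded_concept("http://terminology.hl7.org/CodeSystem/v3-RoleCode",
                              entry$code, entry$display)))
  }
  sn <- kin$snomed_axis_codes
  out <- list()
  if (triple$lineage != "unspecified") {
    ln <- sn$lineage[[triple$lineage]]
    out <- c(out, list(coded_concept(ln$system, ln$code, ln$display)))
  }
  if (triple$degree <= 2) {
    dg <- sn$degree[[as.character(triple$degree)]]
    out <- c(out, list(coded_concept(dg$system, dg$code, dg$display)))
  }
  ty <- sn$type[[triple$relation_type]]
  if (is.null(ty)) {
    mg_unsupported_mapping_error(sprintf("no SNOMED type concept for '%s'", triple$relation_type))
  }
  out <- c(out, list(coded_concept(ty$system, ty$code, ty$display)))
  if (triple$degree > 2) {
    ordinal <- c("first", "second", "third", "fourth", "fifth")[triple$degree]
    attr(out, "degree_annotation") <- sprintf("%s degree relative", ordinal)
  }
  out
}

#' Export the relationship vocabulary
#'
#' @param format `"csv"` or `"json"`.
#' @return Serialized vocabulary text.
#' @export
kinship_export <- function(format = c("csv", "json")) {
  format <- match.arg(format)
  voc <- kinship_vocabulary()
  if (format == "csv") {
    con <- textConnection("out_csv", "w", local = TRUE)
    utils::write.csv(voc, con, row.names = FALSE)
    close(con)
    return(paste(out_csv, collapse = "\n"))
  }
  mg_to_json(lapply(seq_len(nrow(voc)), function(i) as.list(voc[i, ])))
}
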