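#' @title ISO/TS 20428:2017 conformance mapping
#' @description The packaged table maps dataset elements to the required and
#'   optional fields of ISO/TS 20428:2017 (structured clinical genomic
#'   sequencing reports in EHRs): 30 dataset elements map to required ISO
#'   fields, and exactly four required ISO fields have no counterpart in the
#'   dataset definition -- order received date, addendum creation date,
#'   subject of care ethnicity, and medical specialty of ordering physician.
#'   The table is a replaceable data file; ISO text is not reproduced.
#' @name iso20428
NULL

mg_iso_table <- function() {
  if (is.null(.mg_cache$iso)) {
    tab <- utils::read.csv(mg_data_file("iso20428_mapping.csv"),
                           stringsAsFactors = FALSE, na.strings = "")
    reg_ids <- load_registry()$elements$element_id
    bad <- setdiff(tab$element_id[!is.na(tab$element_id)], reg_ids)
    if (length(bad)) {
      mg_link_error(sprintf("ISO mapping references unknown element_id(s): %s",
                            paste(bad, collapse = ", ")))
    }
    .mg_cache$iso <- tab
  }
  .mg_cache$iso
}

#' Dataset / ISO-field conformance report
#'
#' @return A list with `mapped_elements` (distinct dataset elements mapped to
#'   required ISO fields), `missing_required_iso_fields` (required ISO fields
#'   with no dataset counterpart) and `rows` (the full mapping table).
#' @examples
#' conformance_report()$mapped_elements  # 30
#' @export
conformance_report <- function() {
  tab <- mg_iso_table()
  req <- tab[tab$iso_requirement == "required", , drop = FALSE]
  mapped <- unique(req$element_id[req$status == "mapped" & !is.na(req$element_id)])
  missing <- unique(req$iso_field[req$status == "unmapped_iso_side"])
  list(mapped_elements = length(mapped),
       missing_required_iso_fields = missing,
       rows = tab)
}

#' Check a report instance against the ISO required fields
#'
#' A required ISO field is satisfied when at least one of its mapped dataset
#' elements is populated in the report. The four structurally unmapped fields
#' can never be satisfied and are flagged as structural gaps.
#'
#' @param report A `molgen_report`.
#' @return A list with `satisfied_required_fields` (count), `unsatisfied`
#'   (field labels) and `structural_gaps` (the subset of `unsatisfied` that no
#'   report can satisfy).
#' @export
check_report_against_iso <- function(report) {
  tab <- mg_iso_table()
  req <- tab[tab$iso_requirement == "required", , drop = FALSE]
  map <- mg_element_map()
  fields <- unique(req$iso_field)
  gaps <- unique(req$iso_field[req$status == "unmapped_iso_side"])
  satisfied <- vapply(fields, function(f) {
    ids <- req$element_id[req$iso_field == f & !is.na(req$element_id)]
    length(ids) > 0 && any(vapply(ids, function(id) isTRUE(map[[id]](report)), logical(1)))
  }, logical(1))
  list(satisfied_required_fields = sum(satisfied),
       unsatisfied = fields[!satisfied],
       structural_gaps = gaps)
}
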