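test_that("builder output validates with zero error-severity issues for every archetype", {
  for (a in molgenfhir:::MG_ARCHETYPES) {
    iss <- validate_bundle(base_bundle_for(a))
    expect_equal(sum(iss$severity == "error"), 0, label = a)
  }
})

test_that("a single removed required element yields exactly one error at that path", {
  b <- modify_resource(base_bundle_for("hboc_germline_family"),
                       "molgen-finding-report", function(r) { r$status <- NULL; r })
  iss <- validate_bundle(b)
  err <- iss[iss$severity == "error", ]
  expect_equal(nrow(err), 1)
  expect_match(err$path, "DiagnosticReport\\.status")
  expect_equal(err$rule_id, "molgen-finding-report/DiagnosticReport.status/card-min")
})

test_that("family conditions coded outside the slice name the four permitted systems", {
  b <- modify_resource(base_bundle_for("hboc_germline_family"),
                       "family-medical-history", function(r) {
    r$condition[[1]]$code$coding[[1]]$system <- "http://loinc.org"
    r
  })
  iss <- validate_bundle(b)
  err <- iss[iss$severity == "error" & grepl("slice-systems", iss$rule_id), ]
  expect_equal(nrow(err), 1)
  for (sys in c("snomed", "icd-10-gm", "alpha-id", "orpha")) {
    expect_match(err$message, sys, ignore.case = TRUE)
  }
})

test_that("validation is idempotent and deterministically ordered", {
  b <- base_bundle_for("onc_cnv_msi_tmb")
  b$entry[[entry_index_of(b, "patient")]]$resource$gender <- NULL
  b <- modify_resource(b, "variant", function(r) drop_component(r, "variant-origin"))
  i1 <- validate_bundle(b)
  i2 <- validate_bundle(b)
  expect_identical(i1, i2)
  expect_false(is.unsorted(i1$entry_index))
})

test_that("must-support absences are information-level, never errors", {
  b <- modify_resource(base_bundle_for("prs_report"), "molgen-finding-report",
                       function(r) { r$conclusion <- NULL; r })
  iss <- validate_bundle(b)
  ms <- iss[grepl("DiagnosticReport.conclusion", iss$path, fixed = TRUE), ]
  expect_true(all(ms$severity == "information"))
  expect_equal(sum(iss$severity == "error"), 0)
})

test_that("each catalogued mutation triggers its rule and only corrupt bundles fail", {
  catalog <- mutation_catalog()
  expect_gte(length(catalog), 20)
  for (m in catalog) {
    base <- base_bundle_for(m$archetype)
    expect_equal(sum(validate_bundle(base)$severity == "error"), 0,
                 label = paste("clean baseline for", m$name))
    iss <- validate_bundle(m$fn(base))
    hits <- iss[iss$severity == "error" & iss$rule_id == m$rule, ]
    expect_gte(nrow(hits), 1)
    if (nrow(hits) == 0) print(m$name)
  }
})

test_that("exactly seven SearchParameter definitions are materialized with stable content", {
  sps <- emit_search_parameters()
  expect_length(sps, 7)
  ids <- vapply(sps, function(s) s$id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  exprs <- vapply(sps, function(s) s$expression, character(1))
  expect_setequal(exprs, c("ServiceRequest.reasonCode", "ServiceRequest.reasonReference",
                           "FamilyMemberHistory.reasonCode", "FamilyMemberHistory.reasonReference",
                           "Task.for", "Task.reasonCode", "Task.reasonReference"))
  fmh <- Filter(function(s) s$base[[1]] == "FamilyMemberHistory" &&
                  endsWith(s$expression, "reasonReference"), sps)
  expect_length(fmh, 1)
  expect_identical(emit_search_parameters(), sps)
  for (s in sps) expect_silent(jsonlite::fromJSON(molgenfhir:::mg_to_json(s)))
})

test_that("unreadable input is a format error, not an issue list", {
  expect_error(validate_bundle("{ nonsense"), class = "molgenfhir_format_error")
})
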