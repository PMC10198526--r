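test_that("the germline family report builds the expected resource multiset", {
  r <- generate_report("hboc_germline_family", seed = 42, include_prs = TRUE)
  b <- build_bundle(r, seed = 42)
  expect_equal(b$type, "collection")
  types <- table(vapply(b$entry, function(e) e$resource$resourceType, character(1)))
  # frozen by building once and reviewing against the profile list:
  # 2 family members -> 2 FamilyMemberHistory; 1 variant + region studied +
  # result summary + diagnostic implication -> 4 Observations; 1 PRS ->
  # 1 RiskAssessment; plus Patient/Specimen/Organization/ServiceRequest/
  # ChargeItem/Task/DiagnosticReport.
  expect_equal(as.list(types), list(
    ChargeItem = 1L, DiagnosticReport = 1L, FamilyMemberHistory = 2L,
    Observation = 4L, Organization = 1L, Patient = 1L, RiskAssessment = 1L,
    ServiceRequest = 1L, Specimen = 1L, Task = 1L))
})

test_that("absent report content maps to absent resources", {
  r <- generate_report("onc_somatic_snv", seed = 9)
  b <- build_bundle(r, seed = 9)
  types <- vapply(b$entry, function(e) e$resource$resourceType, character(1))
  expect_false("FamilyMemberHistory" %in% types)
  expect_false("RiskAssessment" %in% types)
})

test_that("exactly one DiagnosticReport references the request and every result observation", {
  b <- base_bundle_for("hboc_germline_family")
  drs <- Filter(function(e) e$resource$resourceType == "DiagnosticReport", b$entry)
  expect_length(drs, 1)
  dr <- drs[[1]]$resource
  obs_urls <- vapply(Filter(function(e) e$resource$resourceType == "Observation", b$entry),
                     function(e) e$fullUrl, character(1))
  result_refs <- vapply(dr$result, function(x) x$reference, character(1))
  expect_setequal(result_refs, obs_urls)
  sr_url <- Filter(function(e) e$resource$resourceType == "ServiceRequest", b$entry)[[1]]$fullUrl
  expect_equal(dr$basedOn[[1]]$reference, sr_url)
})

test_that("bundles are referentially closed and deterministic under a fixed seed", {
  for (a in molgenfhir:::MG_ARCHETYPES) {
    r <- generate_report(a, seed = 13)
    b1 <- build_bundle(r, seed = 13)
    urls <- vapply(b1$entry, function(e) e$fullUrl, character(1))
    refs <- molgenfhir:::mg_collect_references(b1$entry)
    expect_true(all(refs[startsWith(refs, "urn:")] %in% urls), label = a)
    expect_false(anyDuplicated(urls) > 0)
    b2 <- build_bundle(generate_report(a, seed = 13), seed = 13)
    expect_identical(write_bundle(b1), write_bundle(b2), label = a)
    b3 <- build_bundle(r, seed = 14)
    expect_false(identical(write_bundle(b1), write_bundle(b3)))
  }
})

test_that("every emitted coding uses a known system and every emitted HGVS string validates", {
  systems <- known_systems()$uri_or_oid
  collect_codings <- function(node, acc = list()) {
    if (!is.list(node)) return(acc)
    if (!is.null(node$coding)) acc <- c(acc, node$coding)
    for (child in node) acc <- collect_codings(child, acc)
    acc
  }
  for (r in generate_corpus(1, seed = 23)) {
    b <- build_bundle(r, seed = 23)
    codings <- collect_codings(b$entry)
    for (cd in codings) {
      expect_true(cd$system %in% systems, label = cd$system)
      if (identical(cd$system, "http://varnomen.hgvs.org")) {
        level <- if (grepl(":?p\\.", cd$code)) "p" else if (grepl("g\\.", cd$code)) "g" else "c"
        expect_true(validate_hgvs(cd$code, level)$valid, label = cd$code)
      }
    }
  }
})

test_that("builds are refused for invalid reports with the terminology reason", {
  r <- unclass(generate_report("onc_somatic_snv", seed = 2))
  r$results$variants[[1]]$dna_change_c <- "c.76A>"
  expect_error(build_bundle(do.call(molgen_report, r)),
               class = "molgenfhir_validation_error")
  broken <- generate_report("onc_somatic_snv", seed = 2)
  broken$results$variants[[1]]$dna_change_c <- "c.76A>"  # bypass constructor
  expect_error(build_bundle(broken), "alternate base",
               class = "molgenfhir_validation_error")
  broken2 <- generate_report("onc_somatic_snv", seed = 2)
  broken2$results$variants[[1]][c("dna_change_c", "dna_change_g", "protein_change")] <- NULL
  expect_error(build_bundle(broken2), "HGVS change",
               class = "molgenfhir_validation_error")
})

test_that("parse_bundle inverts build_bundle on every corpus report", {
  strip <- function(x) {
    x <- unclass(x)
    attr(x, "archetype") <- NULL
    attr(x, "seed") <- NULL
    x
  }
  for (r in generate_corpus(1, seed = 31)) {
    b <- build_bundle(r, seed = 31)
    r2 <- parse_bundle(b)
    expect_identical(strip(r2), strip(r), label = attr(r, "archetype"))
    # also through JSON serialization
    r3 <- parse_bundle(write_bundle(b))
    expect_identical(strip(r3), strip(r), label = paste(attr(r, "archetype"), "json"))
  }
})

test_that("structural and referential parse failures are classed errors", {
  empty <- list(resourceType = "Bundle", type = "collection", entry = list())
  expect_error(parse_bundle(empty), "no DiagnosticReport",
               class = "molgenfhir_structural_error")
  expect_error(parse_bundle(list(resourceType = "Patient")),
               class = "molgenfhir_structural_error")
  b <- base_bundle_for("hboc_germline_family")
  i <- entry_index_of(b, "request")
  b$entry[[i]]$resource$supportingInfo[[1]]$reference <- "urn:uuid:not-there"
  expect_error(parse_bundle(b), "urn:uuid:not-there",
               class = "molgenfhir_referential_error")
})

test_that("ndjson output carries one resource per line", {
  b <- base_bundle_for("prs_report")
  nd <- write_bundle(b, ndjson = TRUE)
  lines <- strsplit(nd, "\n", fixed = TRUE)[[1]]
  expect_length(lines, length(b$entry))
  first <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  expect_true(!is.null(first$resourceType))
})
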