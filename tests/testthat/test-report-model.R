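test_that("a minimal valid document parses into a report", {
  r <- read_report(minimal_report_doc())
  expect_s3_class(r, "molgen_report")
  expect_equal(r$misc$status, "final")
  expect_length(r$results$variants, 1)
})

test_that("model invariants are enforced with errors naming field and rule", {
  doc <- jsonlite::fromJSON(minimal_report_doc(), simplifyVector = FALSE)
  doc$results$variants[[1]]$allele_fraction <- 1.7
  expect_error(read_report(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "allele_fraction", class = "molgenfhir_validation_error")

  doc <- jsonlite::fromJSON(minimal_report_doc(), simplifyVector = FALSE)
  doc$results$variants[[1]][c("dna_change_c")] <- NULL
  expect_error(read_report(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "HGVS change", class = "molgenfhir_validation_error")

  doc <- jsonlite::fromJSON(minimal_report_doc(), simplifyVector = FALSE)
  doc$results$variants[[1]]$origin <- NULL
  expect_error(read_report(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "origin", class = "molgenfhir_validation_error")

  doc <- jsonlite::fromJSON(minimal_report_doc(), simplifyVector = FALSE)
  doc$results <- NULL  # status "final" demands results
  expect_error(read_report(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "final", class = "molgenfhir_validation_error")
})

test_that("YAML input is accepted and unknown keys are reported, not dropped", {
  yml <- "
patient:
  name: {family: Muster, given: [Alex]}
  gender: female
  identifier: PID-1
  shoe_size: 42
request:
  id: REQ-1
results:
  variants:
    - gene: {system: 'http://www.genenames.org', code: BRAF}
      dna_change_c: 'NM_004333.4:c.1799T>A'
      origin: somatic
misc:
  status: preliminary
"
  expect_warning(r <- read_report(yml), "shoe_size")
  expect_equal(attr(r, "unknown_keys"), "patient.shoe_size")
  expect_equal(r$patient$name$family, "Muster")
})

test_that("percent detection limits are normalized to fractions", {
  doc <- jsonlite::fromJSON(minimal_report_doc(), simplifyVector = FALSE)
  doc$results$variants[[1]]$detection_limit <- 5  # five percent
  r <- read_report(jsonlite::toJSON(doc, auto_unbox = TRUE))
  expect_equal(r$results$variants[[1]]$detection_limit, 0.05)
})

test_that("write/read round trip is the identity and output is canonical", {
  strip <- function(x) {
    x <- unclass(x)
    attr(x, "archetype") <- NULL
    attr(x, "seed") <- NULL
    x
  }
  corpus <- generate_corpus(1, seed = 5)
  for (r in corpus) {
    txt <- write_report(r)
    r2 <- read_report(txt)
    expect_identical(strip(r2), strip(r), label = attr(r, "archetype"))
    expect_identical(write_report(r2), txt)
  }
  # deep-equal reports serialize byte-identically regardless of construction order
  a <- molgen_report(misc = list(status = "preliminary", report_id = "X"),
                     patient = list(identifier = "P1"))
  b <- molgen_report(patient = list(identifier = "P1"),
                     misc = list(report_id = "X", status = "preliminary"))
  expect_identical(write_report(a), write_report(b))
  expect_false(grepl("null", write_report(a), fixed = TRUE))
})

test_that("the element correspondence map is total over the registry", {
  map <- molgenfhir:::mg_element_map()
  reg <- load_registry()
  expect_setequal(names(map), reg$elements$element_id)
  full <- full_report()
  populated <- vapply(reg$elements$element_id, function(id) isTRUE(map[[id]](full)), logical(1))
  expect_true(all(populated),
              label = paste("unpopulated:", paste(names(populated)[!populated], collapse = ", ")))
})

test_that("completeness tracks required elements", {
  full <- full_report()
  comp <- completeness(full)
  expect_length(comp$missing_required, 0)
  expect_equal(comp$coverage_fraction, 1.0)

  empty <- molgen_report()
  comp0 <- completeness(empty)
  expect_equal(comp0$coverage_fraction, 0.0)

  # a report missing exactly the billing element
  r <- unclass(full_report())
  r$request$ebm_code <- NULL
  nb <- do.call(molgen_report, r)
  expect_equal(completeness(nb)$missing_required, "rq-12")
})

test_that("parse failures carry location context and are format errors", {
  expect_error(read_report("{ not json"), class = "molgenfhir_format_error")
})
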