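test_that("registry holds 76 distinct elements with the published per-category totals", {
  reg <- load_registry()
  expect_equal(nrow(reg$elements), 76)
  el <- reg$elements
  expect_equal(sum(el$category == "specimen" & el$sub_block %in% "specimen_sample"), 11)
  expect_equal(sum(el$category == "specimen" & el$sub_block %in% "patient"), 5)
  expect_equal(nrow(elements_by_category("request")), 14)
  expect_equal(nrow(elements_by_category("methods")), 10)
  expect_equal(nrow(elements_by_category("results")), 20)
  expect_equal(nrow(elements_by_category("interpretation")), 9)
  expect_equal(nrow(elements_by_category("miscellaneous")), 8)
  # one record is double-listed across blocks: block mentions sum to 77
  per_block <- 11 + 5 + 14 + 10 + 20 + 9 + 8
  expect_equal(per_block, 77)
  shared <- el[!is.na(el$also_category), , drop = FALSE]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$sub_block, "patient")
  expect_equal(shared$also_category, "request")
})

test_that("registry loading is idempotent and order-stable", {
  a <- load_registry(refresh = TRUE)
  b <- load_registry()
  expect_identical(a, b)
  expect_identical(a$elements$element_id, sort(a$elements$element_id, method = "radix"))
})

test_that("unknown category and unknown alias produce informative domain errors", {
  expect_error(elements_by_category("proteomics"), "valid categories",
               class = "molgenfhir_domain_error")
  expect_error(profile_by_alias("NoSuchProfile"), "available aliases",
               class = "molgenfhir_not_found_error")
})

test_that("alias lookup is case-insensitive and resolves base resources", {
  v <- profile_by_alias("Variant")
  expect_equal(v$base_resource, "Observation")
  expect_equal(v$origin, "genomics_reporting_ig")
  prs <- profile_by_alias("polygenic risk score")
  expect_equal(prs$base_resource, "RiskAssessment")
  expect_equal(prs$origin, "additional")
  fmh <- profile_by_alias("Family Medical History")
  expect_equal(fmh$base_resource, "FamilyMemberHistory")
})

test_that("profile registry totals: 16 profiles, 14 aliased, 7 search parameters", {
  reg <- load_registry()
  expect_length(reg$profiles, 16)
  aliased <- Filter(function(p) !is.null(p$alias_en), reg$profiles)
  expect_length(aliased, 14)
  expect_equal(sum(vapply(reg$profiles, function(p)
    identical(p$origin, "module_reference"), logical(1))), 2)
  expect_equal(nrow(reg$search_parameters), 7)
})

test_that("every element fhir_path is declared by its profile (no orphans)", {
  reg <- load_registry()
  for (i in seq_len(nrow(reg$elements))) {
    pid <- reg$elements$profile_id[i]
    path <- reg$elements$fhir_path[i]
    if (is.na(pid)) {
      expect_true(path %in% reg$core_resource_paths)
    } else {
      declared <- vapply(reg$profiles[[pid]]$constraints, function(cn) cn$path, character(1))
      expect_true(path %in% declared,
                  label = sprintf("%s -> %s declared in %s", reg$elements$element_id[i], path, pid))
    }
  }
})

test_that("corrupted registry files fail with errors naming the problem", {
  dir <- withr::local_tempdir()
  file.copy(list.files(dirname(molgenfhir:::mg_data_file("elements.csv")), full.names = TRUE),
            dir)
  el <- read.csv(file.path(dir, "elements.csv"), stringsAsFactors = FALSE, na.strings = "")
  el <- rbind(el, el[el$element_id == "sp-01", ])
  write.csv(el, file.path(dir, "elements.csv"), row.names = FALSE, na = "")
  expect_error(load_registry(dir = dir), "sp-01", class = "molgenfhir_link_error")

  el <- read.csv(file.path(dir, "elements.csv"), stringsAsFactors = FALSE, na.strings = "")
  el <- el[!duplicated(el$element_id), ]
  el$fhir_path[el$element_id == "ms-01"] <- "DiagnosticReport.nonexistent"
  write.csv(el, file.path(dir, "elements.csv"), row.names = FALSE, na = "")
  expect_error(load_registry(dir = dir), "ms-01", class = "molgenfhir_link_error")

  expect_error(load_registry(dir = tempfile()), "missing", class = "molgenfhir_load_error")
})

test_that("registry export emits one row per element in both formats", {
  csv <- registry_export("csv")
  parsed <- read.csv(text = csv, stringsAsFactors = FALSE)
  expect_equal(nrow(parsed), 76)
  js <- jsonlite::fromJSON(registry_export("json"), simplifyVector = FALSE)
  expect_length(js, 76)
})
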