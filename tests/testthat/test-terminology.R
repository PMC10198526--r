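test_that("known systems cover the specification's terminologies with unique identifiers", {
  ks <- known_systems()
  expect_equal(ks$uri_or_oid[ks$name == "ISCN"], "urn:oid:2.16.840.1.113883.6.335")
  for (nm in c("SNOMED CT", "ICD-10-GM", "Alpha-ID", "Orphanet", "LOINC",
               "HGVS", "EBM", "v3.RoleCode")) {
    expect_true(nm %in% ks$name, label = nm)
  }
  expect_false(anyDuplicated(ks$uri_or_oid) > 0)
})

test_that("the HGVS grammar subset accepts well-formed substitutions, indels and protein changes", {
  valid <- list(
    c("NM_004333.4:c.1799T>A", "c"),
    c("c.1799T>A", "c"),
    c("c.76-2A>G", "c"),
    c("c.*45T>C", "c"),
    c("NM_007294.4:c.68_69del", "c"),
    c("c.5946del", "c"),
    c("c.1521_1523del", "c"),
    c("c.2307_2308insA", "c"),
    c("c.145_147delinsTGG", "c"),
    c("c.123dup", "c"),
    c("NC_000017.11:g.43124027_43124028del", "g"),
    c("g.140453136A>T", "g"),
    c("n.211T>C", "n"),
    c("p.Val600Glu", "p"),
    c("NP_004324.2:p.Val600Glu", "p"),
    c("p.Arg130Ter", "p"),
    c("p.Glu23ValfsTer17", "p"),
    c("p.Arg123fs", "p"),
    c("p.Phe508del", "p"),
    c("p.Lys23_Val25dup", "p")
  )
  for (case in valid) {
    res <- validate_hgvs(case[1], case[2])
    expect_true(res$valid, label = case[1])
  }
})

test_that("expressions outside the grammar subset are rejected with reasons, never errors", {
  invalid <- list(
    c("c.76A>", "c"),
    c("c.76A", "c"),
    c("c.76_78con80_82", "c"),
    c("r.76a>g", "c"),
    c("p.V600E", "p"),         # one-letter amino acids are outside the subset
    c("p.Val600", "p"),
    c("g.=", "g"),
    c("not hgvs at all", "c"),
    c("c.1799T>A", "p")        # level mismatch
  )
  for (case in invalid) {
    res <- validate_hgvs(case[1], case[2])
    expect_false(res$valid, label = case[1])
    expect_true(nzchar(res$reason), label = case[1])
  }
  expect_match(validate_hgvs("c.76A>", "c")$reason, "alternate base")
})

test_that("HGVS validation is deterministic and whitespace-invariant, and empty input is a domain error", {
  a <- validate_hgvs("  NM_004333.4:c.1799T>A  ", "c")
  b <- validate_hgvs("NM_004333.4:c.1799T>A", "c")
  expect_identical(a, b)
  expect_error(validate_hgvs("", "c"), class = "molgenfhir_domain_error")
  expect_error(validate_hgvs("   ", "c"), class = "molgenfhir_domain_error")
})

test_that("value-set membership honours systems and explicit member lists", {
  expect_true(code_in_valueset(
    coded_concept("http://fhir.de/CodeSystem/bfarm/icd-10-gm", "C50.9"), "vs-condition-code"))
  expect_true(code_in_valueset(
    coded_concept("http://www.orpha.net", "ORPHA:558"), "vs-condition-code"))
  expect_false(code_in_valueset(
    coded_concept("http://loinc.org", "12345-6"), "vs-family-member-snomed"))
  expect_true(code_in_valueset(
    coded_concept("http://loinc.org", "LA6684-0"), "vs-variant-origin"))
  expect_false(code_in_valueset(
    coded_concept("http://loinc.org", "LA9999-9"), "vs-variant-origin"))
  expect_error(code_in_valueset(coded_concept("x", "y"), "vs-missing"),
               class = "molgenfhir_not_found_error")
})

test_that("coded concepts reject blank systems and padded codes", {
  expect_error(coded_concept("", "C50.9"), class = "molgenfhir_domain_error")
  expect_error(coded_concept("http://snomed.info/sct", " 123 "),
               class = "molgenfhir_domain_error")
})

test_that("value sets export as FHIR ValueSet stubs", {
  vs <- export_value_sets()
  expect_true("vs-condition-code" %in% names(vs))
  expect_equal(vs[["vs-condition-code"]]$resourceType, "ValueSet")
  expect_length(vs[["vs-condition-code"]]$compose$include, 4)
})
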