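test_that("degrees and shared-DNA fractions follow the consanguinity ladder", {
  expect_equal(degree_of("parent"), list(degree = 1L, shared_dna = 0.5))
  expect_equal(degree_of("grandparent"), list(degree = 2L, shared_dna = 0.25))
  expect_equal(degree_of("first_cousin"), list(degree = 3L, shared_dna = 0.125))
  expect_equal(degree_of("half_sibling")$degree, 2L)
  expect_equal(degree_of("great_great_grandparent")$degree, 4L)
  expect_error(degree_of("imaginary_relative"), "vocabulary",
               class = "molgenfhir_not_found_error")
})

test_that("shared DNA follows the geometric law over the whole vocabulary", {
  voc <- kinship_vocabulary()
  expect_true(all(voc$shared_dna == 0.5^voc$degree))
  # halving between consecutive degrees
  for (d in sort(unique(voc$degree))) {
    if (any(voc$degree == d + 1)) {
      expect_equal(unique(voc$shared_dna[voc$degree == d]),
                   2 * unique(voc$shared_dna[voc$degree == d + 1]))
    }
  }
  expect_true(all(diff(voc$shared_dna[order(voc$degree)]) <= 0))
})

test_that("phrases decompose onto the three-axis scheme", {
  t1 <- decompose_relationship("maternal grandmother")
  expect_equal(t1$lineage, "maternal")
  expect_equal(t1$degree, 2L)
  expect_equal(t1$relation_type, "grandparent")
  t2 <- decompose_relationship("sibling")
  expect_equal(t2$lineage, "unspecified")
  expect_equal(t2$degree, 1L)
  expect_error(decompose_relationship("self"), class = "molgenfhir_ambiguity_error")
  expect_error(decompose_relationship("business partner"),
               class = "molgenfhir_not_found_error")
})

test_that("lineage is rejected where it is undefined", {
  expect_error(relationship_triple("child", "maternal"),
               class = "molgenfhir_domain_error")
  expect_silent(relationship_triple("grandparent", "paternal"))
})

test_that("SNOMED composition emits lineage, degree and type axes", {
  out <- compose_relationship(relationship_triple("grandparent", "maternal"),
                              "snomed_familymember")
  expect_length(out, 3)  # lineage + second-degree + grandparent
  systems <- vapply(out, function(cc) cc$system, character(1))
  expect_true(all(systems == "http://snomed.info/sct"))
  expect_null(attr(out, "degree_annotation"))
})

test_that("degrees beyond two get a textual annotation instead of a degree concept", {
  out <- compose_relationship(relationship_triple("first_cousin_once_removed"),
                              "snomed_familymember")
  expect_length(out, 1)  # type concept only
  expect_equal(attr(out, "degree_annotation"), "fourth degree relative")
  out3 <- compose_relationship(relationship_triple("first_cousin", "maternal"),
                               "snomed_familymember")
  expect_length(out3, 2)  # lineage + type, no degree concept
  expect_equal(attr(out3, "degree_annotation"), "third degree relative")
})

test_that("v3.RoleCode composition emits the combined role concept", {
  out <- compose_relationship(relationship_triple("parent"), "v3_rolecode")
  expect_length(out, 1)
  expect_equal(out[[1]]$code, "PRN")
  expect_equal(compose_relationship(relationship_triple("parent", "maternal"),
                                    "v3_rolecode")[[1]]$code, "MTH")
  expect_error(compose_relationship(relationship_triple("aunt_uncle"), "v3_rolecode"),
               class = "molgenfhir_unsupported_mapping_error")
})

test_that("compose and decompose are mutually inverse over the packaged vocabulary", {
  tab <- molgenfhir:::mg_combined_table()
  for (i in seq_len(nrow(tab))) {
    triple <- relationship_triple(tab$relation_type[i], tab$lineage[i])
    # display -> triple -> display
    expect_equal(unclass(decompose_relationship(tab$display[i])), unclass(triple),
                 label = tab$display[i])
    expect_equal(relationship_display(triple), tab$display[i])
    # triple -> SNOMED axis concepts -> triple
    axis <- compose_relationship(triple, "snomed_familymember")
    back <- decompose_relationship(lapply(axis, unclass))
    expect_equal(unclass(back), unclass(triple), label = tab$display[i])
  }
  # triple -> v3 combined code -> triple, where v3 has a representation
  v3keys <- names(molgenfhir:::mg_kinship()$v3_rolecode$codes)
  for (key in v3keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    triple <- relationship_triple(parts[2], parts[1])
    code <- compose_relationship(triple, "v3_rolecode")[[1]]
    expect_equal(unclass(decompose_relationship(unclass(code))), unclass(triple),
                 label = key)
  }
})
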