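test_that("generation is deterministic in archetype, knobs and seed", {
  a <- generate_report("hboc_germline_family", seed = 7)
  b <- generate_report("hboc_germline_family", seed = 7)
  expect_identical(unclass(a), unclass(b))
  c_ <- generate_report("hboc_germline_family", seed = 8)
  expect_false(identical(unclass(a), unclass(c_)))
})

test_that("knobs are honoured and bounded", {
  r <- generate_report("onc_somatic_snv", n_variants = 3, seed = 1)
  expect_length(r$results$variants, 3)
  origins <- vapply(r$results$variants, function(v) v$origin, character(1))
  expect_true(all(origins == "somatic"))
  r2 <- generate_report("hboc_germline_family", n_family_members = 5, seed = 1)
  expect_length(r2$request$family_history, 5)
  expect_error(generate_report("onc_somatic_snv", n_variants = 51),
               class = "molgenfhir_domain_error")
  expect_error(generate_report("hboc_germline_family", n_family_members = 21),
               class = "molgenfhir_domain_error")
})

test_that("archetypes populate their distinguishing content", {
  hboc <- generate_report("hboc_germline_family", seed = 4)
  expect_gte(length(hboc$request$family_history), 1)
  cond <- hboc$request$family_history[[1]]$conditions[[1]]
  expect_true(code_in_valueset(cond, "vs-condition-code"))

  cnv <- generate_report("onc_cnv_msi_tmb", seed = 4)
  expect_true(!is.null(cnv$results$msi_status))
  expect_true(is.numeric(cnv$results$mutational_burden))

  prs <- generate_report("prs_report", seed = 4)
  expect_gte(length(prs$results$prs), 1)
  expect_gte(length(prs$results$prs[[1]]$influence_factors), 1)

  rare <- generate_report("rare_disease_phenotype", seed = 4)
  expect_gte(length(rare$request$reason_phenotypes), 1)
})

test_that("the corpus is seeded, labelled and HGVS-closed", {
  corpus <- generate_corpus(2, seed = 1)
  expect_length(corpus, 10)
  expect_identical(lapply(generate_corpus(2, seed = 1), unclass),
                   lapply(corpus, unclass))
  labels <- vapply(corpus, function(r) attr(r, "archetype"), character(1))
  expect_setequal(unique(labels), molgenfhir:::MG_ARCHETYPES)
  for (r in corpus) {
    for (v in r$results$variants) {
      for (f in list(c("dna_change_c", "c"), c("dna_change_g", "g"),
                     c("protein_change", "p"))) {
        expr <- v[[f[1]]]
        if (!is.null(expr)) expect_true(validate_hgvs(expr, f[2])$valid, label = expr)
      }
    }
  }
})

test_that("packaged golden bundles are reproduced byte-identically", {
  gb <- golden_bundles()
  for (a in names(gb)) {
    path <- system.file("extdata", "golden", paste0(a, ".json"), package = "molgenfhir")
    expect_true(nzchar(path), label = a)
    packaged <- paste(readLines(path, warn = FALSE), collapse = "\n")
    expect_identical(gb[[a]], packaged, label = a)
  }
})
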