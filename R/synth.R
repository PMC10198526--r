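#' @title Synthetic report generation
#' @description Seeded generator of synthetic MolGen reports emulating the
#'   five example archetypes the specification's example bundles cover: an
#'   oncology somatic SNV panel, an oncology CNV/MSI/TMB report, a hereditary
#'   breast/ovarian cancer germline report with family history, a rare
#'   disease report with phenotype references and a polygenic risk score
#'   report. All content (genes, variants, names, dates) is synthetic and
#'   non-clinical; identical archetype, knobs and seed reproduce the report
#'   bit for bit.
#' @name synth
NULL

MG_ARCHETYPES <- c("onc_somatic_snv", "onc_cnv_msi_tmb", "hboc_germline_family",
                   "rare_disease_phenotype", "prs_report")

# Curated synthetic variant catalogue: internally consistent c./p./g. HGVS
# triples on well-known genes (content is illustrative, not clinical).
mg_variant_pool <- function() {
  list(
    list(gene = "BRAF", c = "NM_004333.4:c.1799T>A", p = "p.Val600Glu",
         g = "NC_000007.13:g.140453136A>T", cyto = "7q34", origin = "somatic"),
    list(gene = "KRAS", c = "NM_004985.5:c.35G>A", p = "p.Gly12Asp",
         g = "NC_000012.12:g.25245350C>T", cyto = "12p12.1", origin = "somatic"),
    list(gene = "EGFR", c = "NM_005228.5:c.2573T>G", p = "p.Leu858Arg",
         g = "NC_000007.14:g.55191822T>G", cyto = "7p11.2", origin = "somatic"),
    list(gene = "TP53", c = "NM_000546.6:c.743G>A", p = "p.Arg248Gln",
         g = "NC_000017.11:g.7674220C>T", cyto = "17p13.1", origin = "somatic"),
    list(gene = "PIK3CA", c = "NM_006218.4:c.3140A>G", p = "p.His1047Arg",
         g = "NC_000003.12:g.179234297A>G", cyto = "3q26.32", origin = "somatic"),
    list(gene = "BRCA1", c = "NM_007294.4:c.68_69del", p = "p.Glu23ValfsTer17",
         g = "NC_000017.11:g.43124027_43124028del", cyto = "17q21.31", origin = "germline"),
    list(gene = "BRCA2", c = "NM_000059.4:c.5946del", p = "p.Ser1982ArgfsTer22",
         g = "NC_000013.11:g.32340301del", cyto = "13q13.1", origin = "germline"),
    list(gene = "MLH1", c = "NM_000249.4:c.350C>T", p = "p.Thr117Met",
         g = "NC_000003.12:g.37012098C>T", cyto = "3p22.2", origin = "germline"),
    list(gene = "CFTR", c = "NM_000492.4:c.1521_1523del", p = "p.Phe508del",
         g = "NC_000007.14:g.117559590_117559592del", cyto = "7q31.2", origin = "germline"),
    list(gene = "PTEN", c = "NM_000314.8:c.388C>T", p = "p.Arg130Ter",
         g = "NC_000010.11:g.87933147C>T", cyto = "10q23.31", origin = "germline")
  )
}

mg_name_pool <- list(
  family = c("Muster", "Beispiel", "Probst", "Lehmann", "Fischer", "Weber"),
  given = c("Alex", "Kim", "Chris", "Robin", "Sascha", "Toni")
)

MG_ICD_BREAST <- list(system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
                      code = "C50.9", display = "Malignant neoplasm of breast, unspecified")
MG_ICD_OVARY <- list(system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
                     code = "C56", display = "Malignant neoplasm of ovary")
MG_SCT_BREAST <- list(system = "http://snomed.info/sct",
                      code = "254837009", display = "Malignant neoplasm of breast")
MG_ORPHA_MARFAN <- list(system = "http://www.orpha.net",
                        code = "ORPHA:558", display = "Marfan syndrome")

mg_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  force(expr)
}

#' Generate a synthetic MolGen report
#'
#' @param archetype One of `"onc_somatic_snv"`, `"onc_cnv_msi_tmb"`,
#'   `"hboc_germline_family"`, `"rare_disease_phenotype"`, `"prs_report"`.
#' @param n_variants Number of variant results (1--50); archetype default
#'   when `NULL`.
#' @param n_family_members Number of family history entries (0--20);
#'   archetype default when `NULL`.
#' @param include_prs Include a polygenic risk score entry; archetype default
#'   when `NULL`.
#' @param include_billing Include the EBM billing element.
#' @param seed Integer seed; identical arguments yield a deep-equal report.
#' @return A `molgen_report`.
#' @examples
#' r <- generate_report("hboc_germline_family", seed = 7)
#' length(r$request$family_history)
#' @export
generate_report <- function(archetype = MG_ARCHETYPES, n_variants = NULL,
                            n_family_members = NULL, include_prs = NULL,
                            include_billing = TRUE, seed = 1L) {
  archetype <- match.arg(archetype)
  defaults <- switch(archetype,
    onc_somatic_snv = list(nv = 2L, nf = 0L, prs = FALSE),
    onc_cnv_msi_tmb = list(nv = 2L, nf = 0L, prs = FALSE),
    hboc_germline_family = list(nv = 1L, nf = 2L, prs = FALSE),
    rare_disease_phenotype = list(nv = 1L, nf = 1L, prs = FALSE),
    prs_report = list(nv = 1L, nf = 0L, prs = TRUE))
  n_variants <- as.integer(n_variants %||% defaults$nv)
  n_family_members <- as.integer(n_family_members %||% defaults$nf)
  include_prs <- include_prs %||% defaults$prs
  if (n_variants < 1L || n_variants > 50L) {
    mg_domain_error("n_variants must lie in 1..50")
  }
  if (n_family_members < 0L || n_family_members > 20L) {
    mg_domain_error("n_family_members must lie in 0..20")
  }

  mg_with_seed(seed, {
    somatic <- archetype %in% c("onc_somatic_snv", "onc_cnv_msi_tmb")
    pool <- Filter(function(v) (v$origin == "somatic") == somatic, mg_variant_pool())
    picks <- sample(length(pool), n_variants, replace = n_variants > length(pool))
    variants <- lapply(seq_len(n_variants), function(i) {
      tpl <- pool[[picks[i]]]
      v <- list(
        gene = list(system = "http://www.genenames.org", code = tpl$gene, display = tpl$gene),
        dna_change_c = tpl$c, dna_change_g = tpl$g, protein_change = tpl$p,
        origin = tpl$origin, cytogenetic_location = tpl$cyto,
        transcript_ref = sub(":.*$", "", tpl$c),
        genomic_ref = sub(":.*$", "", tpl$g),
        variant_id = list(system = "https://www.ncbi.nlm.nih.gov/clinvar",
                          code = sprintf("VCV%06d", sample.int(999999, 1))),
        allelic_state = if (somatic) NULL else "heterozygous",
        allele_fraction = if (somatic) round(stats::runif(1, 0.05, 0.6), 2) else 0.5,
        detection_limit = 0.05
      )
      if (archetype == "onc_cnv_msi_tmb" && i == 1L) {
        v$variant_type <- "cnv"
        v$copy_number <- sample(4:12, 1)
      }
      v
    })

    birth_year <- sample(1940:1995, 1)
    patient <- list(
      name = list(family = sample(mg_name_pool$family, 1),
                  given = list(sample(mg_name_pool$given, 1))),
      birth_date = sprintf("%d-%02d-%02d", birth_year, sample(12, 1), sample(28, 1)),
      gender = sample(c("female", "male"), 1),
      identifier = sprintf("PID-%06d", sample.int(999999, 1))
    )

    specimen <- list(
      id = sprintf("SP-%05d", sample.int(99999, 1)),
      type = if (somatic) {
        list(system = "http://snomed.info/sct", code = "258415003", display = "Biopsy sample")
      } else {
        list(system = "http://snomed.info/sct", code = "119297000", display = "Blood specimen")
      },
      status = "available",
      collected = sprintf("2024-%02d-%02dT09:30:00+01:00", sample(12, 1), sample(28, 1)),
      body_site = if (somatic) {
        list(system = "http://snomed.info/sct", code = "76752008", display = "Breast structure")
      } else NULL,
      additives = if (somatic) NULL else {
        list(list(system = "http://snomed.info/sct", code = "446272009", display = "EDTA"))
      },
      received = "2024-06-02T08:00:00+01:00"
    )

    reason <- switch(archetype,
      onc_somatic_snv = list(MG_ICD_BREAST),
      onc_cnv_msi_tmb = list(MG_ICD_BREAST),
      hboc_germline_family = list(MG_ICD_BREAST, MG_ICD_OVARY),
      rare_disease_phenotype = list(MG_ORPHA_MARFAN),
      prs_report = list(MG_SCT_BREAST))

    family <- list()
    if (n_family_members > 0L) {
      rels <- c("mother", "maternal aunt", "sister", "maternal grandmother",
                "father", "paternal uncle")
      for (i in seq_len(n_family_members)) {
        family[[i]] <- list(
          relation = unclass(decompose_relationship(rels[((i - 1L) %% length(rels)) + 1L])),
          conditions = list(if (i %% 2L == 1L) MG_ICD_BREAST else MG_ICD_OVARY),
          age_at_onset = sample(35:70, 1),
          deceased = i %% 3L == 0L
        )
      }
    }

    request <- list(
      id = sprintf("REQ-%06d", sample.int(999999, 1)),
      status = "completed",
      intent = "order",
      code = list(system = "http://snomed.info/sct", code = "405825005",
                  display = "Molecular genetic test"),
      requester = "Dr. med. A. Beispiel, Onkologische Ambulanz",
      authored_on = "2024-05-28",
      reasons = reason,
      family_history = family,
      performer_requested = "MolGen Labor Standort Mitte"
    )
    if (archetype == "rare_disease_phenotype") {
      request$reason_phenotypes <- c("Phenotypic feature: tall stature (HP:0000098)",
                                     "Phenotypic feature: ectopia lentis (HP:0001083)")
      request$supporting_info <- "Prior laboratory report LAB-2024-0117"
    }
    if (include_billing) request$ebm_code <- "11513"

    methods <- list(
      test_method = "Targeted next-generation sequencing panel",
      device = "Illumina NextSeq 550",
      read_depth = 850,
      coverage = 99.2,
      region_description = "Coding exons and +/-20bp intronic flanks of panel genes",
      gene_panel = vapply(variants, function(v) v$gene$code, character(1)),
      reference_assembly = "GRCh38"
    )

    results <- list(
      variants = variants,
      summary = sprintf("%d reportable variant(s) detected.", n_variants)
    )
    if (archetype == "onc_cnv_msi_tmb") {
      results$msi_status <- "unstable-high"
      results$mutational_burden <- round(stats::runif(1, 4, 40), 1)
    }
    if (isTRUE(include_prs)) {
      results$prs <- list(list(
        trait = MG_SCT_BREAST,
        score_type = "probability",
        value = round(stats::runif(1, 0.05, 0.6), 3),
        influence_factors = list(
          list(system = "http://snomed.info/sct", code = "186034007",
               display = "Ethnicity / related nationality data"))
      ))
    }

    interpretation <- list(
      clinical_significance = if (somatic) "pathogenic" else
        sample(c("pathogenic", "likely-pathogenic"), 1),
      evidence_level = "Tier I (AMP/ASCO/CAP)",
      associated_phenotypes = reason[1],
      medication_assessed = if (somatic) "Vemurafenib" else NULL,
      medication_recommendation = if (somatic) "Consider BRAF/MEK inhibitor therapy" else NULL,
      general_recommendation = if (somatic) "Molecular tumor board review advised"
        else "Genetic counseling of first-degree relatives recommended",
      therapeutic_implication = if (somatic) "Predicted responsive to targeted therapy" else NULL,
      summary = "See structured results; findings consistent with the clinical indication.",
      recommended_action_target = "Clinical genetics outpatient service"
    )

    misc <- list(
      report_id = sprintf("MGR-2024-%05d", sample.int(99999, 1)),
      status = "final",
      issued = "2024-06-15T12:00:00+01:00",
      attachments = list(list(title = "variant_calls.vcf", mime = "text/x-vcf")),
      performer = list(name = "Institut fuer Humangenetik, Universitaetsklinikum",
                       contact = "molgen-lab@example.org")
    )

    molgen_report(specimen = specimen, patient = patient, request = request,
                  methods = methods, results = results,
                  interpretation = interpretation, misc = misc)
  })
}

#' Generate a corpus of synthetic reports
#'
#' Produces `5 * n_per_archetype` reports with per-report seeds derived
#' deterministically from the master seed; the archetype label is attached as
#' the `archetype` attribute of each report.
#'
#' @param n_per_archetype Reports per archetype (>= 1).
#' @param seed Master seed.
#' @return A list of `molgen_report`s.
#' @export
generate_corpus <- function(n_per_archetype = 1L, seed = 1L) {
  if (n_per_archetype < 1L) mg_domain_error("n_per_archetype must be >= 1")
  out <- list()
  for (a in seq_along(MG_ARCHETYPES)) {
    for (i in seq_len(n_per_archetype)) {
      sub_seed <- (as.integer(seed) * 131L + a * 17L + i) %% 2147483647L
      r <- generate_report(MG_ARCHETYPES[a], seed = sub_seed)
      attr(r, "archetype") <- MG_ARCHETYPES[a]
      attr(r, "seed") <- sub_seed
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

# Fixed seeds of the packaged golden example bundles, one per archetype.
MG_GOLDEN_SEEDS <- c(onc_somatic_snv = 101L, onc_cnv_msi_tmb = 202L,
                     hboc_germline_family = 303L, rare_disease_phenotype = 404L,
                     prs_report = 505L)

#' Regenerate the packaged golden example bundles
#'
#' One bundle per archetype at its fixed seed; regeneration reproduces the
#' packaged fixtures byte-identically.
#'
#' @return Named list of bundle JSON strings.
#' @export
golden_bundles <- function() {
  out <- lapply(names(MG_GOLDEN_SEEDS), function(a) {
    s <- MG_GOLDEN_SEEDS[[a]]
    write_bundle(build_bundle(generate_report(a, seed = s), seed = s))
  })
  names(out) <- names(MG_GOLDEN_SEEDS)
  out
}
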