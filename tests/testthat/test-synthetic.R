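test_that("the default cohort matches the emulated study setting", {
  dir <- tempfile()
  m <- generate_cohort(cohort_config(seed = 3), dir)
  files <- m$files
  # 3 subjects x (1 medication + 1 immunization) = 6 app files
  app <- files[files$resource_type %in% c("MedicationDispense", "Immunization"), ]
  expect_identical(nrow(app), 6L)
  # exactly one hospital bundle
  expect_identical(sum(files$resource_type == "Bundle"), 1L)
  expect_true(all(file.exists(file.path(dir, files$file))))
})

test_that("generation is byte-deterministic under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- generate_cohort(cohort_config(seed = 9), d1)
  m2 <- generate_cohort(cohort_config(seed = 9), d2)
  expect_identical(m1$files$md5, m2$files$md5)
  m3 <- generate_cohort(cohort_config(seed = 10), tempfile())
  expect_false(identical(m1$files$md5, m3$files$md5))
})

test_that("adding a subject does not perturb earlier subjects", {
  m3 <- generate_cohort(cohort_config(n_subjects = 3, seed = 4), tempfile())
  m4 <- generate_cohort(cohort_config(n_subjects = 4, seed = 4), tempfile())
  shared <- intersect(m3$files$file, m4$files$file)
  expect_length(shared, 7L)  # 6 app files + the subject-1 bundle
  for (f in shared) {
    expect_identical(m3$files$md5[m3$files$file == f],
                     m4$files$md5[m4$files$file == f], info = f)
  }
})

test_that("app exports carry the documented source-data pathologies", {
  co <- single_knob_cohort("p_undefined_system", seed = 6)
  md <- read_resource(file.path(co$dir, "subj-01-medication.json"))
  expect_identical(fhir_type(md), "MedicationDispense")
  types <- vapply(list_contained(md), fhir_type, character(1))
  expect_true(all(c("Patient", "Organization", "Medication") %in% types))
  med <- list_contained(md)[[which(types == "Medication")[1]]]
  expect_identical(unclass(med)$code$coding[[1]]$system, "undefined")

  co2 <- single_knob_cohort("p_redundant_nested", seed = 6)
  md2 <- read_resource(file.path(co2$dir, "subj-01-medication.json"))
  expect_false(is.null(unclass(md2)$subject$resource))
  expect_identical(unclass(md2)$subject$resource$resourceType, "Patient")
})

test_that("immunization exports align with their resource type", {
  co <- single_knob_cohort(NULL, seed = 8)
  imm <- read_resource(file.path(co$dir, "subj-01-immunization.json"))
  expect_identical(fhir_type(imm), "Immunization")
  tree <- unclass(imm)
  expect_false(is.null(tree$vaccineCode))
  expect_false(is.null(tree$protocolApplied[[1]]$targetDisease))
  expect_false(is.null(tree$lotNumber))
  expect_true(isTRUE(tree$primarySource))
})

test_that("the hospital bundle has the expected entry types and EDI procedures", {
  co <- single_knob_cohort(NULL, seed = 12)
  b <- read_resource(file.path(co$dir, "subj-01-snuh-bundle.json"))
  expect_identical(fhir_type(b), "Bundle")
  types <- vapply(bundle_entries(b), fhir_type, character(1))
  expect_true(all(c("MedicationRequest", "Procedure", "Patient", "Organization",
                    "Encounter") %in% types))
  proc <- bundle_entries(b)[[which(types == "Procedure")[1]]]
  sys <- unclass(proc)$code$coding[[1]]$system
  expect_identical(as.character(canonicalize_system(sys)),
                   ips_code_systems()[["edi"]])
})

test_that("clean-mode exports pass syntactic validation with no issues", {
  co <- single_knob_cohort(NULL, seed = 2)
  stages <- ipspipe:::.extract_stage(co$paths)
  for (r in stages$resources) {
    rep <- validate_syntax(r)
    expect_identical(nrow(rep$issues), 0L,
                     info = paste(fhir_type(r), fhir_id(r)))
  }
})

test_that("generated codes come from the packaged pools", {
  co <- single_knob_cohort(NULL, seed = 17)
  stages <- ipspipe:::.extract_stage(co$paths)
  edi_codes <- default_edi_snomed_map()$entries$source_code
  for (r in stages$resources) {
    if (identical(fhir_type(r), "Procedure")) {
      expect_true(unclass(r)$code$coding[[1]]$code %in% edi_codes)
    }
  }
})

test_that("configuration is validated", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(messiness = list(p_undefined_system = 2)), "\\[0, 1\\]")
  expect_error(cohort_config(messiness = list(p_typo = 1)), "unknown")
  expect_error(generate_cohort(cohort_config(n_subjects = 2, snuh_subject = 5),
                               tempfile()), "snuh_subject")
})
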