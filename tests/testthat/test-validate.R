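test_that("syntax tier flags bad status values and dates", {
  imm <- unclass(make_messy_immunization(inline_duplicate = FALSE))
  imm$status <- "done"
  rep <- validate_syntax(fhir_resource(imm))
  expect_false(rep$valid)
  expect_true("SYN-STATUS" %in% rep$issues$rule_id)
  expect_identical(rep$issues$path[rep$issues$rule_id == "SYN-STATUS"], "status")

  imm2 <- unclass(make_messy_immunization(inline_duplicate = FALSE))
  imm2$occurrenceDateTime <- "20/04/2024"
  rep2 <- validate_syntax(fhir_resource(imm2))
  expect_true("SYN-DATE" %in% rep2$issues$rule_id)

  imm3 <- unclass(make_messy_immunization(inline_duplicate = FALSE))
  imm3$status <- NULL
  rep3 <- validate_syntax(fhir_resource(imm3))
  expect_true("SYN-REQ" %in% rep3$issues$rule_id)
})

test_that("syntax tier checks reference form but not referential integrity", {
  proc <- unclass(make_messy_procedure())
  proc$subject <- list(reference = "not a reference!!")
  rep <- validate_syntax(fhir_resource(proc))
  expect_true("SYN-REF" %in% rep$issues$rule_id)

  # a well-formed reference to a resource that exists nowhere is fine
  proc2 <- unclass(make_messy_procedure())
  proc2$subject <- list(reference = "Patient/does-not-exist-anywhere")
  rep2 <- validate_syntax(fhir_resource(proc2))
  expect_false(any(rep2$issues$rule_id == "SYN-REF"))
})

test_that("inline resource objects inside reference elements are detected", {
  imm <- make_messy_immunization(inline_duplicate = TRUE)
  rep <- validate_syntax(imm)
  expect_true("REF-INLINE" %in% rep$issues$rule_id)
  flat <- transform_immunization(imm, transform_context())$output
  expect_false(any(validate_syntax(flat)$issues$rule_id == "REF-INLINE"))
})

test_that("profile tier enforces the IPS rules per resource type", {
  ctx <- transform_context()
  proc <- transform_procedure(worked_example_procedure(
    performed = "2024-02-10T11:00:00+09:00"), ctx)$output

  # clean output passes
  expect_true(validate_ips_profile(proc)$valid)

  # undefined coding system
  bad <- unclass(proc)
  bad$code$coding[[1]]$system <- "undefined"
  repa <- validate_ips_profile(fhir_resource(bad))
  expect_true(all(c("SYS-UNKNOWN", "PROC-SNOMED") %in% repa$issues$rule_id))

  # missing performedDateTime
  bad2 <- unclass(proc)
  bad2$performedDateTime <- NULL
  expect_true("PROC-DATE" %in% validate_ips_profile(fhir_resource(bad2))$issues$rule_id)

  # contained must be empty
  bad3 <- unclass(proc)
  bad3$contained <- list(fixture_patient("p9"))
  expect_true("IPS-CONTAINED" %in% validate_ips_profile(fhir_resource(bad3))$issues$rule_id)

  # MedicationRequest must not use a reference
  mr <- transform_medication_request(make_messy_medication_request(), ctx)$output
  bad4 <- unclass(mr)
  bad4$medicationReference <- list(reference = "Medication/m1")
  expect_true("MR-CODEABLE" %in% validate_ips_profile(fhir_resource(bad4))$issues$rule_id)

  # Medication narrative must be well-formed XHTML
  med <- transform_medication(make_messy_dispense(), ctx)$output
  bad5 <- unclass(med)
  bad5$text$div <- "<div><p>unclosed"
  expect_true("MED-NARRATIVE" %in% validate_ips_profile(fhir_resource(bad5))$issues$rule_id)

  # Immunization meta policy
  imm <- transform_immunization(make_messy_immunization(), ctx)$output
  bad6 <- unclass(imm)
  bad6$meta$versionId <- "9"
  expect_true("IMM-META" %in% validate_ips_profile(fhir_resource(bad6))$issues$rule_id)

  expect_error(validate_ips_profile(fhir_resource(fixture_patient())), "type error")
})

test_that("every reported rule is in the catalogue", {
  cat <- ips_rule_catalogue()
  expect_true(all(c("rule_id", "tier", "severity", "origin", "description")
                  %in% names(cat)))
  co <- single_knob_cohort("p_undefined_system", seed = 5)
  stages <- ipspipe:::.extract_stage(co$paths)
  for (r in stages$resources) {
    rep <- validate_resource(r, concept_map = default_edi_snomed_map())
    expect_true(all(rep$issues$rule_id %in% cat$rule_id))
  }
})

test_that("validate_set aggregates deterministically", {
  expect_identical(validate_set(list())$n_resources, 0L)
  expect_identical(validate_set(list())$n_error, 0L)

  ctx <- transform_context()
  outs <- list(
    transform_medication(make_messy_dispense(), ctx)$output,
    transform_immunization(make_messy_immunization(), ctx)$output
  )
  vs <- validate_set(outs)
  expect_identical(vs$n_resources, 2L)
  expect_identical(vs$n_valid, 2L)
  expect_identical(vs$n_error, 0L)
  # report order follows input order
  expect_identical(vapply(vs$reports, function(r) r$resource_type, character(1)),
                   c("Medication", "Immunization"))
})

test_that("each pathology knob flips its documented rule and transformation clears it", {
  knob_rule <- c(p_undefined_system = "SYS-UNKNOWN",
                 p_redundant_nested = "REF-INLINE",
                 p_missing_performed_date = "PROC-DATE",
                 p_unmapped_edi = "TERM-UNMAPPED")
  cm <- default_edi_snomed_map()

  rules_for <- function(paths) {
    stages <- ipspipe:::.extract_stage(paths)
    raw <- unlist(lapply(stages$resources, function(r) {
      validate_resource(r, concept_map = cm)$issues$rule_id
    }))
    ctx <- transform_context(concept_map = cm,
                             encounter_periods = stages$encounter_periods)
    outs <- lapply(transform_all(stages$resources, ctx)$reports,
                   function(r) r$output)
    post <- unlist(lapply(outs, function(r) {
      validate_resource(r, concept_map = cm)$issues$rule_id
    }))
    list(raw = raw, post = post)
  }

  base <- rules_for(single_knob_cohort(NULL, seed = 31)$paths)
  for (knob in names(knob_rule)) {
    rule <- knob_rule[[knob]]
    with_knob <- rules_for(single_knob_cohort(knob, seed = 31)$paths)
    # knob off: the rule does not fire on raw data; knob on: it does
    expect_false(rule %in% base$raw, info = knob)
    expect_true(rule %in% with_knob$raw, info = knob)
    # after transformation the issue is gone -- except unmapped codes,
    # which survive by design
    if (identical(knob, "p_unmapped_edi")) {
      expect_true(rule %in% with_knob$post)
    } else {
      expect_false(rule %in% with_knob$post, info = knob)
    }
  }
})

test_that("transform outputs are always base-valid", {
  co <- single_knob_cohort("p_missing_performed_date", seed = 13)
  stages <- ipspipe:::.extract_stage(co$paths)
  ctx <- transform_context(encounter_periods = stages$encounter_periods)
  for (rep in transform_all(stages$resources, ctx)$reports) {
    sy <- validate_syntax(rep$output)
    expect_true(sy$valid, info = fhir_id(rep$output))
  }
})

test_that("OperationOutcome export mirrors the issue list", {
  imm <- unclass(make_messy_immunization())
  imm$status <- "done"
  rep <- validate_syntax(fhir_resource(imm))
  oo <- as_operation_outcome(rep)
  expect_identical(oo$resourceType, "OperationOutcome")
  expect_identical(length(oo$issue), nrow(rep$issues))
  expect_match(oo$issue[[1]]$diagnostics, "SYN-")
})
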