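ctx0 <- transform_context()

test_that("immunization transform produces the IPS shape", {
  rep <- transform_immunization(make_messy_immunization(), ctx0)
  out <- unclass(rep$output)
  expect_identical(out$meta$profile,
                   list("http://hl7.org/fhir/uv/ips/StructureDefinition/Immunization-uv-ips"))
  expect_identical(out$meta$source, "https://myhealthway.go.kr")
  expect_null(out$meta$versionId)
  expect_null(out$meta$lastUpdated)
  expect_identical(out$patient, list(reference = "Patient/p1"))
  expect_identical(out$performer[[1]]$actor$reference, "Organization/org1")
  expect_null(out$encounter)
  expect_null(out$location)
  expect_null(out$note)
  expect_length(list_contained(rep$output), 0L)
  # preserve-list fields survive
  expect_identical(out$status, "completed")
  expect_identical(out$lotNumber, "LOT-0042")
  expect_true(isTRUE(out$primarySource))
  # protocolApplied incl. targetDisease is preserved
  expect_identical(out$protocolApplied[[1]]$targetDisease[[1]]$coding[[1]]$code,
                   "6142004")
  # undefined vaccineCode system is canonicalized to ATC
  expect_identical(out$vaccineCode$coding[[1]]$system, "http://www.whocc.no/atc")
  expect_true(any(vapply(rep$actions, function(a) a$kind == "code_defaulted",
                         logical(1))))
})

test_that("immunization transform rejects wrong types and unrecoverable ids", {
  expect_error(transform_immunization(make_messy_procedure(), ctx0), "type error")
  imm <- unclass(make_messy_immunization())
  imm$patient <- NULL
  expect_error(transform_immunization(fhir_resource(imm), ctx0), "missing-id")
})

test_that("medication transform extracts, cleans and narrates", {
  rep <- transform_medication(make_messy_dispense(), ctx0)
  out <- unclass(rep$output)
  expect_identical(out$resourceType, "Medication")
  expect_identical(out$id, "m1")
  expect_length(list_contained(rep$output), 0L)
  # substance removal is logged
  expect_true(any(vapply(rep$actions, function(a) {
    a$kind == "removed" && grepl("Substance", a$detail)
  }, logical(1))))
  # ingredient passes through with numerator value/unit intact
  ing <- out$ingredient[[1]]
  expect_identical(ing$strength$numerator$value, 500)
  expect_identical(ing$strength$numerator$unit, "mg")
  expect_identical(ing$strength$denominator$unit, "Tablet")
  expect_identical(ing$itemCodeableConcept$coding[[1]]$system,
                   "http://www.whocc.no/atc")
  # form is SNOMED-coded
  expect_identical(out$form$coding[[1]]$system, "http://snomed.info/sct")
  # narrative is well-formed XHTML naming the drug
  expect_match(out$text$div, "Paracetamol")
  expect_silent(xml2::read_xml(out$text$div))
})

test_that("a conformant Medication is a fixed point of the transform", {
  first <- transform_medication(make_messy_dispense(), ctx0)$output
  again <- transform_medication(first, ctx0)
  expect_identical(serialize_resource(again$output), serialize_resource(first))
})

test_that("medication transform fails without an extractable Medication", {
  md <- unclass(make_messy_dispense())
  md$contained <- Filter(function(x) x$resourceType != "Medication", md$contained)
  expect_error(transform_medication(fhir_resource(md), ctx0), "extraction error")
})

test_that("medication-request transform flattens and cleans up", {
  rep <- transform_medication_request(make_messy_medication_request("s1"), ctx0)
  out <- unclass(rep$output)
  expect_identical(out$meta$profile,
                   list("http://hl7.org/fhir/uv/ips/StructureDefinition/MedicationRequest-uv-ips"))
  expect_identical(out$subject, list(reference = "Patient/s1"))
  expect_null(out$requester)
  expect_null(out$encounter)
  expect_null(out$identifier)
  expect_null(out$reportedBoolean)
  expect_length(list_contained(rep$output), 0L)
  # removed requester is logged
  expect_true(any(vapply(rep$actions, function(a) {
    a$kind == "removed" && a$path == "requester"
  }, logical(1))))
  # medicationCodeableConcept kept verbatim, no reference conversion
  expect_identical(out$medicationCodeableConcept$coding[[1]]$code, "A10BA02")
  expect_null(out$medicationReference)
  # route SNOMED coding preserved byte-for-byte
  input_route <- unclass(make_messy_medication_request("s1"))$dosageInstruction[[1]]$route
  expect_identical(out$dosageInstruction[[1]]$route, input_route)
})

test_that("procedure transform maps EDI codes through the concept map", {
  rep <- transform_procedure(worked_example_procedure(), ctx0)
  out <- unclass(rep$output)
  expect_identical(out$code$coding[[1]]$code, "11466000")
  expect_identical(out$code$coding[[1]]$system, "http://snomed.info/sct")
  expect_identical(out$code$text, out$code$coding[[1]]$display)
  expect_identical(out$subject, list(reference = "Patient/p1"))
  # meta reduced to the keep-list (tag dropped)
  expect_setequal(names(out$meta), c("versionId", "lastUpdated", "source"))
  expect_true(any(vapply(rep$actions, function(a) a$kind == "code_mapped",
                         logical(1))))
})

test_that("procedure transform defaults a missing system to SNOMED CT", {
  rep <- transform_procedure(make_messy_procedure(system = ""), ctx0)
  expect_identical(unclass(rep$output)$code$coding[[1]]$system,
                   "http://snomed.info/sct")
  expect_true(any(vapply(rep$actions, function(a) a$kind == "code_defaulted",
                         logical(1))))
})

test_that("procedure transform keeps only coding[0]", {
  rep <- transform_procedure(make_messy_procedure(n_codings = 3L), ctx0)
  expect_length(unclass(rep$output)$code$coding, 1L)
})

test_that("performedDateTime is backfilled from the encounter, never invented", {
  proc <- make_messy_procedure(performed = NULL)
  ctx_enc <- transform_context(
    encounter_periods = list("enc-1" = "2024-02-10T08:00:00+09:00"))
  rep <- transform_procedure(proc, ctx_enc)
  expect_identical(unclass(rep$output)$performedDateTime,
                   "2024-02-10T08:00:00+09:00")
  expect_true(any(vapply(rep$actions, function(a) {
    a$kind == "defaulted_element" && a$path == "performedDateTime"
  }, logical(1))))

  # no encounter period known: lenient warns, strict stops
  rep2 <- transform_procedure(proc, ctx0)
  expect_null(unclass(rep2$output)$performedDateTime)
  expect_gt(length(rep2$warnings), 0L)
  ctx_strict <- transform_context(mode = "strict")
  expect_error(transform_procedure(proc, ctx_strict), "performedDateTime")
})

test_that("unmapped EDI codes error in strict mode and are flagged in lenient", {
  proc <- make_messy_procedure(code = "X9999", display = "Unlisted")
  expect_error(transform_procedure(proc, transform_context(mode = "strict")),
               "X9999")
  rep <- transform_procedure(proc, ctx0)
  expect_true(any(vapply(rep$actions, function(a) a$kind == "code_unmapped",
                         logical(1))))
  expect_match(rep$warnings, "X9999", all = FALSE)
})

test_that("transform_all routes by resource type and skips the rest", {
  resources <- list(make_messy_dispense(), make_messy_immunization(),
                    make_messy_medication_request(), make_messy_procedure(),
                    fhir_resource(fixture_patient("x")))
  res <- transform_all(resources, ctx0)
  expect_length(res$reports, 4L)
  expect_setequal(vapply(res$reports, function(r) fhir_type(r$output),
                         character(1)),
                  c("Medication", "Immunization", "MedicationRequest",
                    "Procedure"))
  expect_identical(res$skipped$resource_type, "Patient")

  only_admin <- list(fhir_resource(fixture_patient("a")),
                     fhir_resource(fixture_patient("b")))
  res2 <- transform_all(only_admin, ctx0)
  expect_length(res2$reports, 0L)
  expect_identical(nrow(res2$skipped), 2L)
})

test_that("all four transformers are projections with replayable logs", {
  co <- single_knob_cohort("p_undefined_system")
  stages <- ipspipe:::.extract_stage(co$paths)
  ctx <- transform_context(encounter_periods = stages$encounter_periods)
  res <- transform_all(stages$resources, ctx)
  expect_gt(length(res$reports), 0L)
  for (rep in res$reports) {
    out <- rep$output
    # idempotence: f(f(x)) == f(x)
    again <- transform_all(list(out), ctx)$reports[[1]]
    expect_identical(serialize_resource(again$output), serialize_resource(out))
    # log completeness: replaying the actions rebuilds the output
    expect_identical(serialize_resource(replay_transform(rep)),
                     serialize_resource(out))
    # containment purge
    expect_length(list_contained(out), 0L)
  }
})

test_that("transformed output never invents codes", {
  co <- single_knob_cohort("p_redundant_nested", seed = 23)
  stages <- ipspipe:::.extract_stage(co$paths)
  ctx <- transform_context(encounter_periods = stages$encounter_periods)
  res <- transform_all(stages$resources, ctx)
  cm <- default_edi_snomed_map()$entries
  allowed_codes <- c(cm$source_code, cm$target_code)
  for (i in seq_along(res$reports)) {
    input_json <- serialize_resource(stages$resources[[
      which(vapply(stages$resources, function(r) {
        identical(fhir_id(r), res$reports[[i]]$input_id)
      }, logical(1)))[1]]])
    codings <- ipspipe:::.collect_codings(unclass(res$reports[[i]]$output))
    for (pc in codings) {
      code <- pc$coding$code
      expect_true(grepl(code, input_json, fixed = TRUE) ||
                    code %in% allowed_codes,
                  info = sprintf("code %s at %s", code, pc$path))
    }
  }
})
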