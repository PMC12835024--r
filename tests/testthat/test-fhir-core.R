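test_that("parsing exposes type, id and contained resources", {
  r <- parse_resource('{"resourceType":"Immunization","status":"completed"}')
  expect_s3_class(r, "fhir_resource")
  expect_identical(fhir_type(r), "Immunization")
  expect_length(list_contained(r), 0L)

  dispense <- make_messy_dispense()
  expect_identical(fhir_type(dispense), "MedicationDispense")
  expect_length(list_contained(dispense), 4L)
  types <- vapply(list_contained(dispense), fhir_type, character(1))
  expect_true("Medication" %in% types)
})

test_that("parse errors name the defect", {
  expect_error(parse_resource('{"status":"completed"}'), "resourceType")
  expect_error(parse_resource('{"resourceType":"Widget"}'), "Widget")
  expect_error(parse_resource('{"resourceType":"Patient", '), "byte offset")
})

test_that("serialize/parse round-trips and is byte-deterministic", {
  fixtures <- list(make_messy_dispense(), make_messy_immunization(),
                   make_messy_medication_request(), make_messy_procedure())
  for (f in fixtures) {
    s1 <- serialize_resource(f)
    s2 <- serialize_resource(f)
    expect_identical(s1, s2)
    r1 <- parse_resource(s1)
    expect_identical(serialize_resource(parse_resource(serialize_resource(r1))),
                     serialize_resource(r1))
  }
})

test_that("unknown elements survive parsing and serialization", {
  r <- make_messy_procedure()
  tree <- unclass(r)
  tree$extensionLikeLocalField <- list(valueString = "keep-me")
  r2 <- parse_resource(serialize_resource(fhir_resource(tree)))
  expect_identical(r2$extensionLikeLocalField$valueString, "keep-me")
})

test_that("contained entries must be registered resources with ids", {
  bad <- list(resourceType = "Immunization",
              contained = list(list(resourceType = "Patient")))
  expect_error(fhir_resource(bad), "no id")
  bad2 <- list(resourceType = "Immunization",
               contained = list(list(id = "x")))
  expect_error(fhir_resource(bad2), "resourceType")
})

test_that("rewrite_reference flattens, drops inline objects and is idempotent", {
  imm <- make_messy_immunization(inline_duplicate = TRUE)
  expect_true(!is.null(unclass(imm)$patient$resource))
  flat <- rewrite_reference(imm, "patient", "Patient", "p1")
  expect_identical(unclass(flat)$patient, list(reference = "Patient/p1"))
  flat2 <- rewrite_reference(flat, "patient", "Patient", "p1")
  expect_identical(serialize_resource(flat2), serialize_resource(flat))

  expect_error(rewrite_reference(imm, "nothere", "Patient", "p1"), "path-not-found")
  expect_error(rewrite_reference(imm, "patient", "Patient", ""), "invalid-argument")
})

test_that("reference kinds are classified deterministically", {
  expect_identical(reference_kind("#med1"), "local")
  expect_identical(reference_kind("Patient/p1"), "relative")
  expect_identical(reference_kind("https://example.org/fhir/Patient/p1"), "absolute")
  expect_identical(reference_kind("urn:uuid:1234"), "absolute")
})

test_that("bundles preserve entry order and NDJSON round-trips", {
  entries <- list(fhir_resource(fixture_patient("a")),
                  fhir_resource(fixture_patient("b")),
                  make_messy_procedure())
  b <- make_bundle(entries, id = "b1")
  got <- bundle_entries(b)
  expect_identical(vapply(got, fhir_id, character(1)), c("a", "b", "proc-1"))

  path <- tempfile(fileext = ".ndjson")
  write_ndjson(got, path)
  back <- read_ndjson(path)
  expect_identical(lapply(back, serialize_resource),
                   lapply(got, function(r) serialize_resource(parse_resource(serialize_resource(r)))))
})

test_that("dotted paths address nested elements with zero-based indices", {
  proc <- make_messy_procedure(n_codings = 2L)
  tree <- unclass(proc)
  expect_identical(ipspipe:::path_get(tree, "code.coding.0.code"), "Q2861")
  expect_true(ipspipe:::path_exists(tree, "code.coding.1"))
  expect_false(ipspipe:::path_exists(tree, "code.coding.2"))
  t2 <- ipspipe:::path_set(tree, "code.coding.0.system", "http://snomed.info/sct")
  expect_identical(ipspipe:::path_get(t2, "code.coding.0.system"),
                   "http://snomed.info/sct")
  t3 <- ipspipe:::path_drop(tree, "code.coding.1")
  expect_length(ipspipe:::path_get(t3, "code.coding"), 1L)
})
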