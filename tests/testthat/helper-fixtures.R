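# Fixture builders used across the suite. All fixtures are constructed in
# code; no binary or stored payloads.

fixture_patient <- function(id = "p1") {
  list(resourceType = "Patient", id = id,
       name = list(list(family = "Hong", given = list("Gildong"))),
       gender = "male", birthDate = "1980-04-02")
}

# App-style immunization export: contained resources, tag-like meta.source,
# undefined vaccineCode system, inline duplicate patient.
make_messy_immunization <- function(undefined_system = TRUE,
                                    inline_duplicate = TRUE) {
  pat <- fixture_patient("p1")
  tree <- list(
    resourceType = "Immunization", id = "imm-1",
    meta = list(versionId = "3", lastUpdated = "2024-05-01T10:00:00+09:00",
                source = "#SystemGenerated"),
    contained = list(pat, list(resourceType = "Organization", id = "org1",
                               name = "Public Health Center")),
    status = "completed",
    vaccineCode = list(coding = list(list(
      system = if (undefined_system) "undefined" else "http://www.whocc.no/atc",
      code = "J07BB02", display = "Influenza vaccine")),
      text = "Influenza vaccine"),
    patient = c(list(reference = "#p1"),
                if (inline_duplicate) list(resource = pat)),
    encounter = list(reference = "Encounter/enc-9"),
    occurrenceDateTime = "2024-04-20",
    primarySource = TRUE,
    location = list(display = "Public Health Center"),
    lotNumber = "LOT-0042",
    performer = list(list(actor = list(reference = "#org1"))),
    note = list(list(text = "app export")),
    protocolApplied = list(list(
      targetDisease = list(list(coding = list(list(
        system = "http://snomed.info/sct", code = "6142004",
        display = "Influenza")))),
      doseNumberPositiveInt = 1L))
  )
  fhir_resource(tree)
}

# App-style medication record: MedicationDispense with contained
# Patient/Organization/Medication/Substance.
make_messy_dispense <- function(undefined_system = TRUE, strength = 500,
                                unit = "mg", form = "Tablet") {
  sys_atc <- if (undefined_system) "undefined" else "http://www.whocc.no/atc"
  med <- list(
    resourceType = "Medication", id = "m1",
    code = list(coding = list(list(system = sys_atc, code = "N02BE01",
                                   display = "Paracetamol")),
                text = "Paracetamol"),
    form = list(coding = list(list(
      system = if (undefined_system) "resource identifier (undefined)"
               else "http://snomed.info/sct",
      code = "385055001", display = form)), text = form),
    ingredient = list(list(
      itemCodeableConcept = list(coding = list(list(
        system = sys_atc, code = "N02BE01", display = "Paracetamol"))),
      strength = list(numerator = list(value = strength, unit = unit),
                      denominator = list(value = 1, unit = form))))
  )
  tree <- list(
    resourceType = "MedicationDispense", id = "md-1",
    meta = list(versionId = "2", lastUpdated = "2024-03-02T09:00:00+09:00",
                source = "#SystemGenerated"),
    contained = list(fixture_patient("p1"),
                     list(resourceType = "Organization", id = "org1",
                          name = "Pharmacy"),
                     med,
                     list(resourceType = "Substance", id = "sub1",
                          code = list(text = "Paracetamol"))),
    status = "completed",
    medicationReference = list(reference = "#m1"),
    subject = list(reference = "#p1"),
    whenHandedOver = "2024-03-02T09:00:00+09:00"
  )
  fhir_resource(tree)
}

make_messy_medication_request <- function(patient_id = "s1") {
  pat <- fixture_patient(patient_id)
  tree <- list(
    resourceType = "MedicationRequest", id = "mr-1",
    meta = list(versionId = "4", lastUpdated = "2024-06-01T08:00:00+09:00",
                source = "https://snuh.org"),
    contained = list(pat),
    identifier = list(list(system = "urn:hospital:order", value = "ORD-7")),
    status = "completed", intent = "order", reportedBoolean = FALSE,
    medicationCodeableConcept = list(coding = list(list(
      system = "http://www.whocc.no/atc", code = "A10BA02",
      display = "Metformin")), text = "Metformin"),
    subject = list(reference = paste0("#", patient_id), resource = pat),
    encounter = list(reference = "Encounter/enc-1"),
    authoredOn = "2024-06-01T08:00:00+09:00",
    requester = list(reference = "Practitioner/dr-1", display = "Dr. Kang"),
    dosageInstruction = list(list(
      text = "1 tablet twice daily",
      timing = list(`repeat` = list(frequency = 2L, period = 1,
                                    periodUnit = "d")),
      route = list(coding = list(list(system = "http://snomed.info/sct",
                                      code = "26643006",
                                      display = "Oral route"))),
      doseAndRate = list(list(doseQuantity = list(value = 1, unit = "tablet")))))
  )
  fhir_resource(tree)
}

make_messy_procedure <- function(code = "Q2861", system = "EDI",
                                 display = "Appendectomy",
                                 performed = "2024-02-10T11:00:00+09:00",
                                 n_codings = 1L) {
  codings <- rep(list(list(system = system, code = code, display = display)),
                 n_codings)
  if (identical(system, "")) {
    codings <- lapply(codings, function(cc) cc[c("code", "display")])
  }
  tree <- list(
    resourceType = "Procedure", id = "proc-1",
    meta = list(versionId = "1", lastUpdated = "2024-02-10T12:00:00+09:00",
                source = "https://snuh.org", tag = list(list(code = "mydata"))),
    contained = list(fixture_patient("p1")),
    status = "completed",
    code = list(coding = codings, text = display),
    subject = list(reference = "#p1"),
    encounter = list(reference = "Encounter/enc-1"),
    performer = list(list(actor = list(reference = "Practitioner/dr-1")))
  )
  if (!is.null(performed)) tree$performedDateTime <- performed
  fhir_resource(tree)
}

# The worked-example Procedure: its EDI source code is the packaged
# excerpt's entry targeting SNOMED CT 11466000.
worked_example_procedure <- function(performed = NULL) {
  excerpt <- default_edi_snomed_map()$entries
  row <- excerpt[excerpt$target_code == "11466000", ]
  stopifnot(nrow(row) == 1L)
  make_messy_procedure(code = row$source_code, system = "EDI",
                       display = row$target_display, performed = performed)
}

# Independent brute-force coverage oracle: exhaustive loops over
# (component, profile, mapping) triples, no shared code with
# compute_gap_report().
oracle_coverage <- function(registry) {
  comps <- unique(registry$components$component)
  n_mapped <- 0L
  for (cm in comps) {
    profs <- registry$components$ips_profile[registry$components$component == cm]
    mapped <- FALSE
    for (p in profs) {
      for (i in seq_len(nrow(registry$mappings))) {
        if (identical(registry$mappings$ips_profile[[i]], p) &&
            nzchar(registry$mappings$kr_profile[[i]])) {
          mapped <- TRUE
        }
      }
    }
    if (mapped) n_mapped <- n_mapped + 1L
  }
  list(n_mapped = n_mapped,
       pct = as.integer(floor(100 * n_mapped / length(comps) + 0.5)))
}

# Random registry written to temp CSVs and loaded through the normal path.
random_registry <- function() {
  n_comp <- sample(2:6, 1)
  comp_rows <- list()
  map_rows <- list()
  for (i in seq_len(n_comp)) {
    n_prof <- sample(1:3, 1)
    for (j in seq_len(n_prof)) {
      prof <- sprintf("Profile-%d-%d (IPS)", i, j)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        component = sprintf("Component-%d", i),
        tier = sample(c("required", "recommended"), 1),
        ips_profile = prof, stringsAsFactors = FALSE)
      n_kr <- sample(0:2, 1)
      if (n_kr == 0) {
        map_rows[[length(map_rows) + 1L]] <- data.frame(
          ips_profile = prof, kr_profile = "", stringsAsFactors = FALSE)
      } else {
        for (k in seq_len(n_kr)) {
          map_rows[[length(map_rows) + 1L]] <- data.frame(
            ips_profile = prof, kr_profile = sprintf("KR-%d-%d-%d", i, j, k),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  dir <- tempfile()
  dir.create(dir)
  cfile <- file.path(dir, "components.csv")
  mfile <- file.path(dir, "mappings.csv")
  dfile <- file.path(dir, "deltas.csv")
  write.csv(do.call(rbind, comp_rows), cfile, row.names = FALSE)
  write.csv(do.call(rbind, map_rows), mfile, row.names = FALSE)
  write.csv(data.frame(ips_profile = character(), ips_system = character(),
                       kr_system = character()), dfile, row.names = FALSE)
  load_gap_registry(cfile, mfile, dfile)
}

# Generate a cohort with exactly one messiness knob enabled.
single_knob_cohort <- function(knob, seed = 11, out_dir = tempfile()) {
  knobs <- list(p_undefined_system = 0, p_redundant_nested = 0,
                p_missing_performed_date = 0, p_unmapped_edi = 0)
  if (!is.null(knob)) knobs[[knob]] <- 1.0
  cfg <- cohort_config(n_subjects = 1, seed = seed, messiness = knobs)
  manifest <- generate_cohort(cfg, out_dir)
  list(dir = out_dir, manifest = manifest,
       paths = file.path(out_dir, manifest$files$file))
}
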