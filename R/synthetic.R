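# Seedable generator of messy source data emulating Korean
# personal-health-record exports: per-subject medication-record files
# (MedicationDispense with contained Patient/Organization/Medication/
# Substance), immunization files (Immunization with contained resources),
# and one hospital "Medical MyData" bundle (MedicationRequest, Procedure,
# Patient, Organization, Encounter; EDI-coded procedures).
#
# Messiness knobs reproduce the documented source-data pathologies:
#   p_undefined_system      code systems emitted as the literal "undefined"
#   p_redundant_nested      duplicate inline resource inside reference elements
#   p_missing_performed_date Procedure lacking performedDateTime
#   p_unmapped_edi          EDI codes outside the packaged mapping excerpt
#
# Each subject draws from its own seeded substream, so adding a subject
# never perturbs the files of earlier subjects; identical configs produce
# byte-identical files.

.MED_POOL <- data.frame(
  code = c("N02BE01", "A02BC01", "A10BA02", "C09AA03", "J01CA04"),
  name = c("Paracetamol", "Omeprazole", "Metformin", "Lisinopril", "Amoxicillin"),
  strength = c(500, 20, 500, 10, 250),
  unit = "mg",
  form = c("Tablet", "Capsule", "Tablet", "Tablet", "Capsule"),
  stringsAsFactors = FALSE
)

.VACCINE_POOL <- data.frame(
  code = c("J07BB02", "J07BC01", "J07AL02"),
  name = c("Influenza, inactivated, split virus or surface antigen",
           "Hepatitis B vaccine", "Pneumococcal vaccine"),
  disease_code = c("6142004", "66071002", "16814004"),
  disease_name = c("Influenza", "Type B viral hepatitis", "Pneumococcal infection"),
  stringsAsFactors = FALSE
)

.GIVEN_NAMES <- c("Minjun", "Seoyeon", "Jihoo", "Haeun", "Dohyun", "Yuna")
.FAMILY_NAMES <- c("Kim", "Lee", "Park", "Choi", "Jung", "Han")

.UNMAPPED_EDI_POOL <- c("X9901", "X9902", "X9903")

.sub_seed <- function(seed, k) as.integer((seed * 1009 + k * 7919) %% 2147483647L)

.rand_date <- function(year = 2024) {
  sprintf("%d-%02d-%02d", year, sample(1:12, 1), sample(1:28, 1))
}

.rand_datetime <- function(year = 2024) {
  sprintf("%sT%02d:%02d:00+09:00", .rand_date(year), sample(8:18, 1), sample(0:59, 1))
}

#' Cohort generation configuration
#'
#' Defaults reproduce the study setting the generator emulates: three
#' subjects with one medication-record file and one immunization file
#' each (six app-export files), plus one hospital bundle for a single
#' designated subject. The default messiness has undefined code systems
#' and redundant nesting always on, half of the procedures missing a
#' performed date, and no unmappable EDI codes.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; identical configs yield byte-identical
#'   output.
#' @param snuh_subject 1-based index of the subject with a hospital
#'   bundle, or `NA` for none.
#' @param messiness Named list of probabilities `p_undefined_system`,
#'   `p_redundant_nested`, `p_missing_performed_date`, `p_unmapped_edi`,
#'   each in `[0, 1]`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 3, seed = 1, snuh_subject = 1,
                          messiness = list()) {
  defaults <- list(p_undefined_system = 1.0, p_redundant_nested = 1.0,
                   p_missing_performed_date = 0.5, p_unmapped_edi = 0.0)
  unknown <- setdiff(names(messiness), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown messiness knob(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  m <- utils::modifyList(defaults, messiness)
  probs <- unlist(m)
  if (any(probs < 0 | probs > 1)) {
    stop("messiness probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be >= 1", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 snuh_subject = snuh_subject, messiness = m),
            class = "cohort_config")
}

#' All-knobs-off variant of a cohort configuration
#'
#' @param config A `cohort_config`.
#' @return The same configuration with every messiness probability 0.
#' @export
clean_config <- function(config = cohort_config()) {
  config$messiness <- lapply(config$messiness, function(x) 0.0)
  config
}

# Subject profile: demographics plus the med/vaccine/procedure draws.
.subject_profile <- function(i, config, edi_pool) {
  set.seed(.sub_seed(config$seed, i))
  m <- config$messiness
  sid <- sprintf("subj-%02d", i)
  med <- .MED_POOL[sample(nrow(.MED_POOL), 1), ]
  vac <- .VACCINE_POOL[sample(nrow(.VACCINE_POOL), 1), ]
  n_proc <- sample(1:2, 1)
  procs <- lapply(seq_len(n_proc), function(k) {
    use_unmapped <- stats::runif(1) < m$p_unmapped_edi
    if (use_unmapped) {
      list(code = sample(.UNMAPPED_EDI_POOL, 1), name = "Unlisted procedure",
           date = .rand_datetime())
    } else {
      row <- edi_pool[sample(nrow(edi_pool), 1), ]
      list(code = row$source_code, name = row$target_display,
           date = .rand_datetime())
    }
  })
  list(
    subject_id = sid,
    patient_id = paste0("pat-", sid),
    given = sample(.GIVEN_NAMES, 1),
    family = sample(.FAMILY_NAMES, 1),
    gender = sample(c("male", "female"), 1),
    birth_date = sprintf("%d-%02d-%02d", sample(1950:2000, 1),
                         sample(1:12, 1), sample(1:28, 1)),
    med = med, vaccine = vac, procedures = procs,
    knobs = list(
      undefined_system = stats::runif(1) < m$p_undefined_system,
      redundant_nested = stats::runif(1) < m$p_redundant_nested,
      missing_performed = vapply(seq_len(n_proc), function(k) {
        stats::runif(1) < m$p_missing_performed_date
      }, logical(1))
    )
  )
}

.patient_tree <- function(profile, id = profile$patient_id) {
  list(resourceType = "Patient", id = id,
       name = list(list(family = profile$family, given = list(profile$given))),
       gender = profile$gender, birthDate = profile$birth_date)
}

.org_tree <- function(id, name) {
  list(resourceType = "Organization", id = id, name = name)
}

.maybe_undefined <- function(system, on) if (on) "undefined" else system

# Reference element; with the redundancy knob on, the full resource is
# duplicated inline next to the reference string.
.ref_element <- function(ref, inline = NULL) {
  el <- list(reference = ref)
  if (!is.null(inline)) el$resource <- inline
  el
}

#' Generate one messy medication-record export
#'
#' A MedicationDispense with contained Patient, Organization, Medication
#' and Substance; the subject's RNG substream must already be seeded
#' (call via [generate_cohort()] for reproducible output).
#'
#' @param profile Subject profile produced internally by
#'   [generate_cohort()].
#' @return A `fhir_resource`.
#' @keywords internal
generate_medication_dispense <- function(profile) {
  k <- profile$knobs
  med <- profile$med
  sysu <- k$undefined_system
  atc <- ips_code_systems()[["atc"]]
  snomed <- ips_code_systems()[["snomed"]]
  med_id <- paste0("med-", profile$subject_id)
  patient <- .patient_tree(profile)
  med_tree <- list(
    resourceType = "Medication", id = med_id,
    code = list(coding = list(list(system = .maybe_undefined(atc, sysu),
                                   code = med$code, display = med$name)),
                text = med$name),
    form = list(coding = list(list(
      system = .maybe_undefined(snomed, sysu),
      code = unname(.DOSE_FORMS[[med$form]]), display = med$form)),
      text = med$form),
    ingredient = list(list(
      itemCodeableConcept = list(coding = list(list(
        system = .maybe_undefined(atc, sysu), code = med$code,
        display = med$name))),
      strength = list(numerator = list(value = med$strength, unit = med$unit),
                      denominator = list(value = 1, unit = med$form))
    ))
  )
  substance <- list(resourceType = "Substance", id = "sub-1",
                    code = list(text = med$name))
  tree <- list(
    resourceType = "MedicationDispense",
    id = paste0("md-", profile$subject_id, "-1"),
    meta = list(versionId = "2", lastUpdated = .rand_datetime(),
                source = "#SystemGenerated"),
    contained = list(patient, .org_tree("org-1", "Community Pharmacy"),
                     med_tree, substance),
    status = "completed",
    medicationReference = list(reference = paste0("#", med_id)),
    subject = .ref_element(paste0("#", profile$patient_id),
                           inline = if (k$redundant_nested) patient),
    performer = list(list(actor = list(reference = "#org-1"))),
    quantity = list(value = 30, unit = med$form),
    daysSupply = list(value = 30, unit = "days"),
    whenHandedOver = .rand_datetime()
  )
  fhir_resource(tree)
}

#' Generate one messy immunization export
#'
#' @inheritParams generate_medication_dispense
#' @return A `fhir_resource` of type Immunization.
#' @keywords internal
generate_immunization <- function(profile) {
  k <- profile$knobs
  vac <- profile$vaccine
  atc <- ips_code_systems()[["atc"]]
  snomed <- ips_code_systems()[["snomed"]]
  patient <- .patient_tree(profile)
  tree <- list(
    resourceType = "Immunization",
    id = paste0("imm-", profile$subject_id, "-1"),
    meta = list(versionId = "1", lastUpdated = .rand_datetime(),
                source = "#SystemGenerated"),
    contained = list(patient, .org_tree("org-2", "Public Health Center")),
    status = "completed",
    vaccineCode = list(coding = list(list(
      system = .maybe_undefined(atc, k$undefined_system),
      code = vac$code, display = vac$name)), text = vac$name),
    patient = .ref_element(paste0("#", profile$patient_id),
                           inline = if (k$redundant_nested) patient),
    encounter = list(reference = "Encounter/enc-ext-1"),
    occurrenceDateTime = .rand_date(),
    primarySource = TRUE,
    location = list(display = "Public Health Center"),
    lotNumber = sprintf("LOT-%04d", sample(1000:9999, 1)),
    performer = list(list(actor = list(reference = "#org-2"))),
    note = list(list(text = "exported from mobile app")),
    protocolApplied = list(list(
      targetDisease = list(list(coding = list(list(
        system = snomed, code = vac$disease_code, display = vac$disease_name)))),
      doseNumberPositiveInt = 1L))
  )
  fhir_resource(tree)
}

#' Generate one messy hospital "Medical MyData" bundle
#'
#' @inheritParams generate_medication_dispense
#' @return A `fhir_resource` of type Bundle containing Patient,
#'   Organization, Encounter, MedicationRequest and Procedure entries.
#' @keywords internal
generate_snuh_bundle <- function(profile) {
  k <- profile$knobs
  med <- profile$med
  atc <- ips_code_systems()[["atc"]]
  snomed <- ips_code_systems()[["snomed"]]
  patient <- .patient_tree(profile)
  enc_start <- .rand_datetime()
  encounter <- list(
    resourceType = "Encounter", id = "enc-1", status = "finished",
    class = list(system = "http://terminology.hl7.org/CodeSystem/v3-ActCode",
                 code = "AMB", display = "ambulatory"),
    subject = list(reference = paste0("Patient/", profile$patient_id)),
    period = list(start = enc_start)
  )
  mr <- list(
    resourceType = "MedicationRequest",
    id = paste0("mr-", profile$subject_id, "-1"),
    meta = list(versionId = "4", lastUpdated = .rand_datetime(),
                source = "https://snuh.org"),
    contained = list(patient),
    identifier = list(list(system = "urn:snuh:order", value = "ORD-1024")),
    status = "completed", intent = "order",
    reportedBoolean = FALSE,
    medicationCodeableConcept = list(coding = list(list(
      system = atc, code = med$code, display = med$name)), text = med$name),
    subject = .ref_element(paste0("#", profile$patient_id),
                           inline = if (k$redundant_nested) patient),
    encounter = list(reference = "Encounter/enc-1"),
    authoredOn = .rand_datetime(),
    requester = list(reference = "Practitioner/dr-1", display = "Dr. Kang"),
    dosageInstruction = list(list(
      text = "1 tablet twice daily",
      timing = list(`repeat` = list(frequency = 2L, period = 1, periodUnit = "d")),
      route = list(coding = list(list(system = snomed, code = "26643006",
                                      display = "Oral route"))),
      doseAndRate = list(list(doseQuantity = list(value = 1, unit = "tablet")))
    ))
  )
  procs <- lapply(seq_along(profile$procedures), function(j) {
    p <- profile$procedures[[j]]
    tree <- list(
      resourceType = "Procedure",
      id = sprintf("proc-%s-%d", profile$subject_id, j),
      meta = list(versionId = "1", lastUpdated = .rand_datetime(),
                  source = "https://snuh.org", tag = list(list(code = "mydata"))),
      contained = list(patient),
      status = "completed",
      code = list(coding = c(
        list(list(system = "EDI", code = p$code, display = p$name)),
        if (k$undefined_system) {
          list(list(system = "undefined", code = p$code, display = p$name))
        }),
        text = p$name),
      subject = .ref_element(paste0("#", profile$patient_id),
                             inline = if (k$redundant_nested) patient),
      encounter = list(reference = "Encounter/enc-1"),
      performer = list(list(actor = list(reference = "Practitioner/dr-1")))
    )
    if (!k$missing_performed[[j]]) tree$performedDateTime <- p$date
    fhir_resource(tree)
  })
  entries <- c(
    list(fhir_resource(patient),
         fhir_resource(.org_tree("org-snuh", "Seoul National University Hospital")),
         fhir_resource(encounter), fhir_resource(mr)),
    procs
  )
  make_bundle(entries, type = "collection",
              id = paste0("snuh-", profile$subject_id))
}

#' Generate a synthetic source-data cohort on disk
#'
#' Writes one medication-record file and one immunization file per
#' subject plus one hospital bundle for the designated subject, along
#' with a `manifest.json` listing every file with its MD5 hash. The same
#' configuration always produces byte-identical files.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: a list with `seed`, `n_subjects`,
#'   `messiness` and a data.frame `files` (file, resource_type,
#'   subject_id, md5).
#' @examples
#' \donttest{
#' dir <- tempfile()
#' m <- generate_cohort(cohort_config(seed = 7), dir)
#' nrow(m$files)  # 7 files: 6 app exports + 1 hospital bundle
#' }
#' @export
generate_cohort <- function(config = cohort_config(), out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("I/O error: cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  edi_pool <- default_edi_snomed_map()$entries
  files <- list()
  add_file <- function(resource, fname, rtype, sid) {
    path <- file.path(out_dir, fname)
    write_resource(resource, path)
    files[[length(files) + 1L]] <<- data.frame(
      file = fname, resource_type = rtype, subject_id = sid,
      md5 = md5_file(path), stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$n_subjects)) {
    profile <- .subject_profile(i, config, edi_pool)
    sid <- profile$subject_id
    add_file(generate_medication_dispense(profile),
             sprintf("%s-medication.json", sid), "MedicationDispense", sid)
    add_file(generate_immunization(profile),
             sprintf("%s-immunization.json", sid), "Immunization", sid)
  }
  if (!is.na(config$snuh_subject)) {
    i <- config$snuh_subject
    if (i < 1 || i > config$n_subjects) {
      stop("snuh_subject must index an existing subject", call. = FALSE)
    }
    profile <- .subject_profile_reuse(i, config, edi_pool)
    add_file(generate_snuh_bundle(profile),
             sprintf("%s-snuh-bundle.json", profile$subject_id), "Bundle",
             profile$subject_id)
  }
  manifest <- list(seed = config$seed, n_subjects = config$n_subjects,
                   messiness = config$messiness,
                   files = do.call(rbind, files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(manifest)
}

# The hospital bundle reuses the subject's profile (same demographics and
# procedure list) but draws its own dates from a dedicated substream.
.subject_profile_reuse <- function(i, config, edi_pool) {
  profile <- .subject_profile(i, config, edi_pool)
  set.seed(.sub_seed(config$seed, 900000L + i))
  profile
}
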