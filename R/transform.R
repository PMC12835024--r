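# Deterministic rule engine producing IPS-conformant resources from messy
# Korean personal-health-record exports. Four rule-sets are supported --
# Immunization, Medication (from MedicationDispense), MedicationRequest and
# Procedure. The declarative parts of each rule-set (retain/remove lists,
# profile URIs, meta and code policies) are shipped as JSON under
# extdata/rulesets so the rules are inspectable and editable; the
# type-specific mechanics (contained extraction, reference resolution,
# narrative generation) live here.
#
# Every transformer is a projection: applying it to its own output is the
# identity. Every element placed in an output is logged as one action
# (with the value placed), so replaying a report's actions against an
# empty tree reproduces the output exactly.

IPS_PROFILE_IMMUNIZATION <- "http://hl7.org/fhir/uv/ips/StructureDefinition/Immunization-uv-ips"
IPS_PROFILE_MEDICATION_REQUEST <- "http://hl7.org/fhir/uv/ips/StructureDefinition/MedicationRequest-uv-ips"
MYHEALTHWAY_SOURCE <- "https://myhealthway.go.kr"

# Dose-form display -> SNOMED CT dose-form concept, used to (re)build the
# Medication.form coding when the source system is unusable.
.DOSE_FORMS <- c(
  "Tablet" = "385055001",
  "Capsule" = "385049006",
  "Oral solution" = "385023001",
  "Solution for injection" = "385219001",
  "Syrup" = "385032004"
)

#' Load the packaged transformation rule-sets
#'
#' @return Named list (immunization, medication, medication_request,
#'   procedure) of rule-set definitions as parsed from the packaged JSON.
#' @export
load_rulesets <- function() {
  files <- c("immunization", "medication", "medication_request", "procedure")
  out <- lapply(files, function(f) {
    jsonlite::fromJSON(.pkg_extdata("rulesets", paste0(f, ".json")),
                       simplifyVector = FALSE)
  })
  names(out) <- files
  out
}

#' Transformation context
#'
#' Shared state handed to the transformers: the EDI to SNOMED CT concept
#' map (set to `NULL` to disable procedure code mapping), the error mode,
#' and the encounter periods used to backfill a missing
#' `performedDateTime` (taken from Encounter resources travelling in the
#' same bundle; a date is never fabricated).
#'
#' @param concept_map A `concept_map` or `NULL`.
#' @param mode `"lenient"` (collect warnings) or `"strict"` (stop on the
#'   first defect).
#' @param encounter_periods Named list: encounter id -> period start
#'   dateTime.
#' @param default_performed_date Fallback dateTime for procedures whose
#'   encounter is unknown, or `NULL`.
#' @return A list of class `transform_ctx`.
#' @export
transform_context <- function(concept_map = default_edi_snomed_map(),
                              mode = c("lenient", "strict"),
                              encounter_periods = list(),
                              default_performed_date = NULL) {
  mode <- match.arg(mode)
  structure(list(concept_map = concept_map, mode = mode,
                 encounter_periods = encounter_periods,
                 default_performed_date = default_performed_date,
                 rulesets = load_rulesets()),
            class = "transform_ctx")
}

# ---- report / action machinery --------------------------------------------

.new_builder <- function(input) {
  env <- new.env(parent = emptyenv())
  env$input <- input
  env$out <- list()
  env$actions <- list()
  env$warnings <- character()
  env
}

# Log an action; when `value` is given the output tree is also set at
# `path`, which is what makes the log replayable.
.act <- function(b, kind, path, detail, value = NULL, set = !is.null(value)) {
  if (set) b$out <- path_set(b$out, path, value)
  b$actions[[length(b$actions) + 1L]] <-
    list(kind = kind, path = path, detail = detail, value = value)
  invisible(b)
}

.warn <- function(b, msg) {
  b$warnings <- c(b$warnings, msg)
  invisible(b)
}

.finish <- function(b) {
  structure(list(
    input_id = b$input[["id"]] %||% "",
    input_type = fhir_type(b$input),
    output = fhir_resource(b$out),
    actions = b$actions,
    warnings = b$warnings
  ), class = "transform_report")
}

#' @export
print.transform_report <- function(x, ...) {
  cat(sprintf("<transform_report> %s/%s -> %s/%s: %d actions, %d warnings\n",
              x$input_type, x$input_id, fhir_type(x$output),
              fhir_id(x$output) %||% "", length(x$actions), length(x$warnings)))
  invisible(x)
}

#' Replay a transform report's action log
#'
#' Applies every value-bearing action in order to an empty tree. By the
#' log-completeness invariant this reconstructs the report's output
#' exactly.
#'
#' @param report A `transform_report`.
#' @return A `fhir_resource`.
#' @export
replay_transform <- function(report) {
  stopifnot(inherits(report, "transform_report"))
  out <- list()
  for (a in report$actions) {
    if (!is.null(a$value)) out <- path_set(out, a$path, a$value)
  }
  fhir_resource(out)
}

# ---- reference resolution --------------------------------------------------

# Resolve the (type, id) a reference-bearing element points at, looking
# through flat references, contained resources and inline duplicates.
.resolve_ref <- function(tree, element, expect_type = NULL) {
  if (is.null(element)) return(NULL)
  ref <- element[["reference"]]
  if (non_empty_string(ref)) {
    kind <- reference_kind(ref)
    if (kind == "relative") {
      parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
      if (length(parts) == 2L) return(list(type = parts[[1]], id = parts[[2]]))
    }
    if (kind == "local") {
      want <- sub("^#", "", ref)
      for (cr in tree[["contained"]] %||% list()) {
        if (identical(cr[["id"]], want)) {
          return(list(type = cr[["resourceType"]], id = cr[["id"]]))
        }
      }
      # dangling local reference: the id itself is still usable
      if (!is.null(expect_type) && nzchar(want)) {
        return(list(type = expect_type, id = want))
      }
    }
  }
  # inline duplicate resource object embedded in the reference element
  for (m in element) {
    if (is.list(m) && non_empty_string(m[["resourceType"]]) &&
        non_empty_string(m[["id"]])) {
      return(list(type = m[["resourceType"]], id = m[["id"]]))
    }
  }
  # contained fallback by expected type
  if (!is.null(expect_type)) {
    for (cr in tree[["contained"]] %||% list()) {
      if (identical(cr[["resourceType"]], expect_type)) {
        return(list(type = expect_type, id = cr[["id"]]))
      }
    }
  }
  NULL
}

.flatten_subject <- function(b, tree, element_name, expect_type = "Patient") {
  el <- tree[[element_name]]
  if (is.null(el)) {
    stop(sprintf("missing-id: no %s element to flatten", element_name), call. = FALSE)
  }
  res <- .resolve_ref(tree, el, expect_type = expect_type)
  if (is.null(res) || !non_empty_string(res$id)) {
    stop(sprintf("missing-id: cannot recover %s id for %s", expect_type, element_name),
         call. = FALSE)
  }
  .act(b, "flattened", element_name,
       sprintf("reference flattened to %s/%s", res$type, res$id),
       value = list(reference = paste0(res$type, "/", res$id)))
}

# Canonicalize the system of every coding in a CodeableConcept; unusable
# systems are replaced by `default_system` when given. Returns the
# (possibly modified) concept plus whether any system was defaulted.
.normalize_concept <- function(concept, default_system) {
  changed <- FALSE
  codings <- concept[["coding"]] %||% list()
  for (i in seq_along(codings)) {
    canon <- canonicalize_system(codings[[i]][["system"]])
    if (identical(as.character(canon), IPS_UNKNOWN_SYSTEM)) {
      if (!is.null(default_system)) {
        codings[[i]][["system"]] <- default_system
        changed <- TRUE
      }
    } else if (!identical(codings[[i]][["system"]], as.character(canon))) {
      codings[[i]][["system"]] <- as.character(canon)
      changed <- TRUE
    }
  }
  if (length(codings)) concept[["coding"]] <- codings
  list(concept = concept, changed = changed)
}

# Log one `removed` action per input element that was not carried over.
.log_removals <- function(b, tree, kept) {
  for (nm in names(tree)) {
    if (!nm %in% kept) {
      .act(b, "removed", nm, sprintf("element '%s' not retained by rule-set", nm))
    }
  }
  invisible(b)
}

.check_type <- function(resource, allowed) {
  if (!fhir_type(resource) %in% allowed) {
    stop(sprintf("type error: expected %s, got %s",
                 paste(allowed, collapse = "/"), fhir_type(resource)),
         call. = FALSE)
  }
}

# ---- Immunization ----------------------------------------------------------

#' Transform an Immunization export into its IPS shape
#'
#' Keeps the preserve-list elements (status, vaccineCode,
#' occurrenceDateTime, lotNumber, primarySource, plus protocolApplied with
#' its targetDisease when present), stamps the IPS Immunization profile,
#' strips versionId/lastUpdated, sets `meta.source` to the MyHealthway
#' URI, flattens patient and performer references, and removes encounter,
#' location, note and all contained resources. Unusable vaccineCode
#' systems are replaced by the rule-set's default (ATC).
#'
#' @param resource A `fhir_resource` of type Immunization.
#' @param ctx A [transform_context()].
#' @return A `transform_report` (fields `input_id`, `output`, `actions`,
#'   `warnings`).
#' @export
transform_immunization <- function(resource, ctx = transform_context()) {
  .check_type(resource, "Immunization")
  tree <- unclass(resource)
  rs <- ctx$rulesets$immunization
  b <- .new_builder(tree)

  .act(b, "retained", "resourceType", "resourceType preserved", value = "Immunization")
  if (non_empty_string(tree[["id"]])) {
    .act(b, "retained", "id", "id preserved", value = tree[["id"]])
  }

  meta <- list(profile = list(rs$ips_profile_uri), source = rs$meta_policy$source_uri)
  .act(b, "profile_stamped", "meta",
       sprintf("meta.profile set to %s", rs$ips_profile_uri), value = meta)
  .act(b, "source_set", "meta.source",
       sprintf("meta.source set to %s (no tag-like strings)", rs$meta_policy$source_uri))
  for (m in intersect(c("versionId", "lastUpdated"), names(tree[["meta"]] %||% list()))) {
    .act(b, "removed", paste0("meta.", m),
         sprintf("meta.%s removed (server-assigned)", m))
  }

  for (el in c("status", "occurrenceDateTime", "lotNumber", "primarySource")) {
    if (!is.null(tree[[el]])) {
      .act(b, "retained", el, sprintf("'%s' preserved", el), value = tree[[el]])
    }
  }

  vc <- tree[["vaccineCode"]]
  if (!is.null(vc)) {
    norm <- .normalize_concept(vc, rs$code_policy$default_system)
    kind <- if (norm$changed) "code_defaulted" else "retained"
    .act(b, kind, "vaccineCode",
         if (norm$changed) "vaccineCode system canonicalized/defaulted"
         else "vaccineCode preserved",
         value = norm$concept)
  }

  b <- .flatten_subject(b, tree, "patient", "Patient")

  perf <- tree[["performer"]]
  if (!is.null(perf)) {
    flat <- lapply(perf, function(p) {
      res <- .resolve_ref(tree, p[["actor"]], expect_type = "Organization")
      out <- list()
      if (!is.null(p[["function"]])) out[["function"]] <- p[["function"]]
      if (!is.null(res)) {
        out[["actor"]] <- list(reference = paste0(res$type, "/", res$id))
      } else if (!is.null(p[["actor"]])) {
        out[["actor"]] <- p[["actor"]]
      }
      out
    })
    .act(b, "flattened", "performer", "performer actor references flattened",
         value = flat)
  }

  if (!is.null(tree[["protocolApplied"]])) {
    .act(b, "retained", "protocolApplied",
         "protocolApplied preserved (incl. targetDisease)",
         value = tree[["protocolApplied"]])
  }

  .log_removals(b, tree, kept = names(b$out))
  .finish(b)
}

# ---- Medication ------------------------------------------------------------

.medication_narrative <- function(med) {
  name <- med[["code"]][["text"]] %||%
    (med[["code"]][["coding"]] %||% list(list()))[[1]][["display"]] %||%
    "Medication"
  bits <- character()
  ing <- (med[["ingredient"]] %||% list(NULL))[[1]]
  num <- ing[["strength"]][["numerator"]]
  if (!is.null(num[["value"]])) {
    bits <- c(bits, paste0(num[["value"]], " ", num[["unit"]] %||% ""))
  }
  form <- med[["form"]][["text"]] %||%
    (med[["form"]][["coding"]] %||% list(list()))[[1]][["display"]]
  if (non_empty_string(form)) bits <- c(bits, form)
  desc <- if (length(bits)) paste0(": ", paste(trimws(bits), collapse = " per ")) else ""
  sprintf('<div xmlns="http://www.w3.org/1999/xhtml"><p><b>%s</b>%s</p></div>',
          name, desc)
}

#' Transform a medication-record export into a conformant Medication
#'
#' Accepts either a bare Medication or a MedicationDispense export whose
#' `contained` list carries the Medication (the MyHealthway shape).
#' Contained Substance resources are dropped, code/form/ingredient
#' systems are canonicalized (ATC for the drug code, SNOMED CT for the
#' dose form), the ingredient strength denominator unit is taken from the
#' dose-form display (flagged in the report), identifiers get a proper
#' URL system, and a well-formed XHTML narrative carrying the drug name
#' is generated when absent.
#'
#' @inheritParams transform_immunization
#' @param resource A `fhir_resource` of type MedicationDispense or
#'   Medication.
#' @return A `transform_report`.
#' @export
transform_medication <- function(resource, ctx = transform_context()) {
  .check_type(resource, c("MedicationDispense", "Medication"))
  tree <- unclass(resource)
  rs <- ctx$rulesets$medication
  b <- .new_builder(tree)

  if (identical(fhir_type(resource), "MedicationDispense")) {
    contained <- tree[["contained"]] %||% list()
    types <- vapply(contained, function(x) x[["resourceType"]] %||% "", character(1))
    med_i <- which(types == "Medication")
    if (!length(med_i)) {
      stop("extraction error: MedicationDispense has no contained Medication",
           call. = FALSE)
    }
    med <- contained[[med_i[[1]]]]
    .act(b, "extracted_from_contained", sprintf("contained.%d", med_i[[1]] - 1L),
         sprintf("Medication '%s' extracted from contained", med[["id"]] %||% "?"))
    for (i in which(types == "Substance")) {
      .act(b, "removed", sprintf("contained.%d", i - 1L),
           "Substance resource removed from contained")
    }
  } else {
    med <- tree
  }

  .act(b, "retained", "resourceType", "output resourceType is Medication",
       value = "Medication")

  med_id <- sub("^#", "", med[["id"]] %||% "")
  if (!nzchar(med_id)) {
    canon <- as.character(jsonlite::toJSON(med, auto_unbox = TRUE, digits = NA))
    med_id <- paste0("med-", substr(md5_string(canon), 1, 12))
    .act(b, "defaulted_element", "id",
         "no source id; deterministic content-hash id assigned", value = med_id)
  } else {
    .act(b, "retained", "id", "Medication id preserved", value = med_id)
  }

  if (!is.null(med[["meta"]])) {
    .act(b, "retained", "meta", "meta preserved", value = med[["meta"]])
  }

  ident <- med[["identifier"]]
  if (!is.null(ident)) {
    fixed <- FALSE
    for (i in seq_along(ident)) {
      sys <- ident[[i]][["system"]]
      if (!non_empty_string(sys) || !grepl("^https?://", sys)) {
        ident[[i]][["system"]] <- paste0(MYHEALTHWAY_SOURCE, "/identifier")
        fixed <- TRUE
      }
    }
    .act(b, if (fixed) "defaulted_element" else "retained", "identifier",
         if (fixed) "identifier value kept; proper URL set as system"
         else "identifier preserved",
         value = ident)
  }

  code <- med[["code"]]
  if (!is.null(code)) {
    norm <- .normalize_concept(code, rs$code_policy$default_system)
    .act(b, if (norm$changed) "code_defaulted" else "retained", "code",
         if (norm$changed) "code system canonicalized/defaulted (ATC)"
         else "code preserved", value = norm$concept)
  }

  if (!is.null(med[["status"]])) {
    .act(b, "retained", "status", "status preserved", value = med[["status"]])
  }

  form <- med[["form"]]
  form_display <- form[["text"]] %||%
    (form[["coding"]] %||% list(list()))[[1]][["display"]]
  if (!is.null(form)) {
    normf <- .normalize_concept(form, ips_code_systems()[["snomed"]])
    f <- normf$concept
    if (is.null(f[["coding"]]) && non_empty_string(form_display) &&
        form_display %in% names(.DOSE_FORMS)) {
      f[["coding"]] <- list(list(system = ips_code_systems()[["snomed"]],
                                 code = unname(.DOSE_FORMS[[form_display]]),
                                 display = form_display))
      normf$changed <- TRUE
    }
    .act(b, if (normf$changed) "code_defaulted" else "retained", "form",
         if (normf$changed) "dose form coded with SNOMED CT"
         else "form preserved", value = f)
  }

  ing <- med[["ingredient"]]
  if (!is.null(ing)) {
    changed <- FALSE
    for (i in seq_along(ing)) {
      item <- ing[[i]][["itemCodeableConcept"]]
      if (is.null(item)) next
      has_code <- length(item[["coding"]] %||% list()) > 0L
      has_text <- non_empty_string(item[["text"]])
      if (!has_code && !has_text) {
        stop("invalid-input: ingredient lacks both code and text", call. = FALSE)
      }
      norm <- .normalize_concept(item, rs$code_policy$default_system)
      if (norm$changed) changed <- TRUE
      ing[[i]][["itemCodeableConcept"]] <- norm$concept
      den <- ing[[i]][["strength"]][["denominator"]]
      if (!is.null(den) && non_empty_string(form_display) &&
          !identical(den[["unit"]], form_display)) {
        ing[[i]][["strength"]][["denominator"]][["unit"]] <- form_display
        changed <- TRUE
        .warn(b, "ingredient strength denominator unit taken from dose-form display")
      }
    }
    .act(b, if (changed) "code_defaulted" else "retained", "ingredient",
         if (changed) "ingredient normalized (ATC system, denominator from dose form)"
         else "ingredient preserved", value = ing)
  }

  txt <- med[["text"]]
  div_ok <- non_empty_string(txt[["div"]]) &&
    !inherits(try(xml2::read_xml(txt[["div"]]), silent = TRUE), "try-error")
  if (div_ok) {
    .act(b, "retained", "text", "existing narrative preserved", value = txt)
  } else {
    div <- .medication_narrative(if (length(b$out)) b$out else med)
    .act(b, "narrative_generated", "text",
         "XHTML narrative generated (drug name and brief description)",
         value = list(status = "generated", div = div))
  }

  .log_removals(b, med, kept = names(b$out))
  if (identical(fhir_type(resource), "MedicationDispense")) {
    for (nm in setdiff(names(tree), c("contained", "resourceType"))) {
      .act(b, "removed", nm,
           sprintf("MedicationDispense envelope element '%s' discarded", nm))
    }
  }
  .finish(b)
}

# ---- MedicationRequest -----------------------------------------------------

#' Transform a MedicationRequest export into its IPS shape
#'
#' Preserves status, intent, authoredOn and the medicationCodeableConcept
#' verbatim (never converted to a medicationReference), stamps the IPS
#' MedicationRequest profile, flattens the subject reference to
#' `Patient/{id}`, keeps dosageInstruction entries reduced to text,
#' timing, route (existing SNOMED CT coding untouched) and doseAndRate,
#' and removes encounter, identifier, requester, reportedBoolean and all
#' contained resources.
#'
#' @inheritParams transform_immunization
#' @param resource A `fhir_resource` of type MedicationRequest.
#' @return A `transform_report`.
#' @export
transform_medication_request <- function(resource, ctx = transform_context()) {
  .check_type(resource, "MedicationRequest")
  tree <- unclass(resource)
  rs <- ctx$rulesets$medication_request
  b <- .new_builder(tree)

  .act(b, "retained", "resourceType", "resourceType preserved",
       value = "MedicationRequest")
  if (non_empty_string(tree[["id"]])) {
    .act(b, "retained", "id", "id preserved", value = tree[["id"]])
  }

  meta <- list(profile = list(rs$ips_profile_uri))
  src <- tree[["meta"]][["source"]]
  if (non_empty_string(src) && !startsWith(src, "#")) meta[["source"]] <- src
  .act(b, "profile_stamped", "meta",
       sprintf("meta.profile set to %s", rs$ips_profile_uri), value = meta)
  for (m in intersect(c("versionId", "lastUpdated"), names(tree[["meta"]] %||% list()))) {
    .act(b, "removed", paste0("meta.", m),
         sprintf("meta.%s removed (server-assigned)", m))
  }

  for (el in c("status", "intent", "authoredOn")) {
    if (!is.null(tree[[el]])) {
      .act(b, "retained", el, sprintf("'%s' preserved", el), value = tree[[el]])
    }
  }

  mcc <- tree[["medicationCodeableConcept"]]
  if (!is.null(mcc)) {
    .act(b, "retained", "medicationCodeableConcept",
         "medicationCodeableConcept preserved verbatim (not converted to reference)",
         value = mcc)
  } else if (identical(ctx$mode, "strict")) {
    stop("invalid-input: MedicationRequest has no medicationCodeableConcept",
         call. = FALSE)
  } else {
    .warn(b, "no medicationCodeableConcept in source MedicationRequest")
  }

  b <- .flatten_subject(b, tree, "subject", "Patient")

  dosage <- tree[["dosageInstruction"]]
  if (!is.null(dosage)) {
    keep <- unlist(rs$dosage_retain_members, use.names = FALSE)
    reduced <- lapply(dosage, function(d) d[intersect(keep, names(d))])
    .act(b, "retained", "dosageInstruction",
         "dosageInstruction preserved (text, timing, route, doseAndRate; SNOMED route untouched)",
         value = reduced)
  }

  .log_removals(b, tree, kept = names(b$out))
  .finish(b)
}

# ---- Procedure -------------------------------------------------------------

#' Transform a Procedure export into its IPS shape
#'
#' Retains resourceType, id, meta (reduced to versionId, lastUpdated,
#' source), status, code and subject. The code is reduced to `coding[0]`;
#' a missing or unusable system becomes `http://snomed.info/sct`; an EDI
#' code is replaced through the EDI to SNOMED CT concept map in `ctx`
#' (unmapped codes are an error in strict mode, a logged `code_unmapped`
#' action in lenient mode); `code.text` is set to the coding's
#' display/code. The subject reference is flattened to `Patient/{id}` and
#' a missing `performedDateTime` is backfilled from the source element or
#' the enclosing encounter's period start -- never fabricated.
#'
#' @inheritParams transform_immunization
#' @param resource A `fhir_resource` of type Procedure.
#' @return A `transform_report`.
#' @export
transform_procedure <- function(resource, ctx = transform_context()) {
  .check_type(resource, "Procedure")
  tree <- unclass(resource)
  rs <- ctx$rulesets$procedure
  b <- .new_builder(tree)

  .act(b, "retained", "resourceType", "resourceType preserved", value = "Procedure")
  if (non_empty_string(tree[["id"]])) {
    .act(b, "retained", "id", "id preserved", value = tree[["id"]])
  }

  m <- tree[["meta"]]
  if (!is.null(m)) {
    keep_names <- unlist(rs$meta_policy$keep_only, use.names = FALSE)
    kept <- m[intersect(keep_names, names(m))]
    if (length(kept)) {
      .act(b, "retained", "meta", "meta reduced to versionId/lastUpdated/source",
           value = kept)
    }
    for (nm in setdiff(names(m), keep_names)) {
      .act(b, "removed", paste0("meta.", nm),
           sprintf("meta.%s outside the keep-list", nm))
    }
  }

  if (!is.null(tree[["status"]])) {
    .act(b, "retained", "status", "status preserved", value = tree[["status"]])
  }

  codings <- tree[["code"]][["coding"]]
  if (is.null(codings) || !length(codings)) {
    stop("invalid-input: Procedure has no coding", call. = FALSE)
  }
  if (length(codings) > 1L) {
    .act(b, "removed", "code.coding.1",
         sprintf("use only coding[0]; %d extra coding(s) dropped",
                 length(codings) - 1L))
  }
  c0 <- codings[[1]]
  canon <- as.character(canonicalize_system(c0[["system"]]))
  kind <- "retained"
  detail <- "code preserved"
  if (identical(canon, IPS_UNKNOWN_SYSTEM)) {
    c0[["system"]] <- rs$code_policy$default_system
    kind <- "code_defaulted"
    detail <- "missing/unusable system set to http://snomed.info/sct"
  } else {
    c0[["system"]] <- canon
    if (identical(canon, ips_code_systems()[["edi"]]) && !is.null(ctx$concept_map)) {
      hit <- map_code(ctx$concept_map, canon, c0[["code"]])
      if (is_matched(hit)) {
        c0 <- list(system = hit$target_system, code = hit$target_code,
                   display = hit$target_display)
        kind <- "code_mapped"
        detail <- sprintf("EDI %s mapped to SNOMED CT %s via concept map",
                          hit$source_code, hit$target_code)
      } else {
        if (identical(ctx$mode, "strict")) {
          stop(sprintf("mapping error: EDI code '%s' has no entry in the concept map",
                       c0[["code"]]), call. = FALSE)
        }
        kind <- "code_unmapped"
        detail <- sprintf("EDI code '%s' not in concept map; left as-is", c0[["code"]])
        .warn(b, detail)
      }
    }
  }
  code_out <- list(coding = list(c0),
                   text = c0[["display"]] %||% c0[["code"]])
  .act(b, kind, "code", detail, value = code_out)

  b <- .flatten_subject(b, tree, "subject", "Patient")

  pd <- tree[["performedDateTime"]]
  if (non_empty_string(pd)) {
    .act(b, "retained", "performedDateTime", "performedDateTime preserved", value = pd)
  } else {
    enc <- tree[["encounter"]][["reference"]]
    enc_id <- if (non_empty_string(enc)) sub("^(Encounter/|#)", "", enc) else ""
    fill <- ctx$encounter_periods[[enc_id]] %||% ctx$default_performed_date
    if (non_empty_string(fill)) {
      .act(b, "defaulted_element", "performedDateTime",
           "performedDateTime backfilled from encounter period start", value = fill)
    } else if (identical(ctx$mode, "strict")) {
      stop("missing-element: performedDateTime absent and no encounter period available",
           call. = FALSE)
    } else {
      .warn(b, "performedDateTime missing and no encounter period available")
    }
  }

  .log_removals(b, tree, kept = names(b$out))
  .finish(b)
}

# ---- routing ---------------------------------------------------------------

.TRANSFORM_ROUTES <- c(
  Immunization = "immunization",
  MedicationDispense = "medication",
  Medication = "medication",
  MedicationRequest = "medication_request",
  Procedure = "procedure"
)

#' Apply all four rule-sets across a set of resources
#'
#' Routes each resource to its rule-set by resource type
#' (MedicationDispense is routed to the Medication rule-set); resources
#' with no rule-set (Patient, Organization, Encounter, ...) are skipped.
#' In lenient mode per-resource failures are collected; in strict mode
#' the first failure stops the run.
#'
#' @param resources List of `fhir_resource` (expand bundles first, e.g.
#'   with [bundle_entries()]).
#' @param ctx A [transform_context()].
#' @return List with `reports` (successful `transform_report`s),
#'   `skipped` (data.frame of resource type/id), and `failures`
#'   (list of error messages, lenient mode only).
#' @export
transform_all <- function(resources, ctx = transform_context()) {
  reports <- list()
  skipped_type <- character()
  skipped_id <- character()
  failures <- character()
  for (r in resources) {
    rt <- fhir_type(r)
    route <- if (rt %in% names(.TRANSFORM_ROUTES)) .TRANSFORM_ROUTES[[rt]] else NA_character_
    if (is.na(route)) {
      skipped_type <- c(skipped_type, rt)
      skipped_id <- c(skipped_id, fhir_id(r) %||% "")
      next
    }
    f <- switch(route,
      immunization = transform_immunization,
      medication = transform_medication,
      medication_request = transform_medication_request,
      procedure = transform_procedure
    )
    if (identical(ctx$mode, "strict")) {
      reports[[length(reports) + 1L]] <- f(r, ctx)
    } else {
      res <- tryCatch(f(r, ctx), error = function(e) conditionMessage(e))
      if (inherits(res, "transform_report")) {
        reports[[length(reports) + 1L]] <- res
      } else {
        failures <- c(failures, sprintf("%s/%s: %s", rt, fhir_id(r) %||% "", res))
      }
    }
  }
  list(reports = reports,
       skipped = data.frame(resource_type = skipped_type, id = skipped_id,
                            stringsAsFactors = FALSE),
       failures = failures)
}
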