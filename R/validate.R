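# Two-tier local validator: tier "syntax" checks conformity to the FHIR R4
# base structure (required elements, status value sets, date/time lexical
# forms, reference well-formedness); tier "profile" applies the IPS-level
# semantic rules for the four transformed profiles. Referential-integrity
# checks (unresolved targets in an external store) are deliberately out of
# scope, matching create-time server behaviour where ids are reassigned.

.FHIR_DATE_RE <- "^\\d{4}(-\\d{2}(-\\d{2})?)?$"
.FHIR_DATETIME_RE <- paste0(
  "^\\d{4}(-\\d{2}(-\\d{2}(T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?",
  "(Z|[+-]\\d{2}:\\d{2}))?)?)?$")
.FHIR_INSTANT_RE <-
  "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?(Z|[+-]\\d{2}:\\d{2})$"

.STATUS_VALUE_SETS <- list(
  Immunization = c("completed", "entered-in-error", "not-done"),
  Procedure = c("preparation", "in-progress", "not-done", "on-hold", "stopped",
                "completed", "entered-in-error", "unknown"),
  MedicationRequest = c("active", "on-hold", "cancelled", "completed",
                        "entered-in-error", "stopped", "draft", "unknown"),
  MedicationDispense = c("preparation", "in-progress", "cancelled", "on-hold",
                         "completed", "entered-in-error", "stopped", "declined",
                         "unknown"),
  Medication = c("active", "inactive", "entered-in-error"),
  Encounter = c("planned", "arrived", "triaged", "in-progress", "onleave",
                "finished", "cancelled", "entered-in-error", "unknown")
)

.REQUIRED_ELEMENTS <- list(
  Immunization = c("status", "vaccineCode", "patient"),
  Procedure = c("status", "subject"),
  MedicationRequest = c("status", "intent", "subject"),
  MedicationDispense = "status",
  Encounter = c("status", "class"),
  Bundle = "type"
)

# Elements whose string value must be a date / dateTime / instant.
.DATE_ELEMENTS <- list(
  date = c("birthDate", "expirationDate"),
  dateTime = c("occurrenceDateTime", "performedDateTime", "authoredOn",
               "whenHandedOver", "whenPrepared", "onsetDateTime",
               "recordedDate", "effectiveDateTime", "recorded", "start",
               "end", "deceasedDateTime"),
  instant = c("lastUpdated", "timestamp", "issued")
)

# IPS canonical profile URIs expected in meta.profile of transformed output.
.EXPECTED_PROFILE <- c(
  Immunization = "http://hl7.org/fhir/uv/ips/StructureDefinition/Immunization-uv-ips",
  MedicationRequest = "http://hl7.org/fhir/uv/ips/StructureDefinition/MedicationRequest-uv-ips"
)

# Elements an IPS-shaped output is expected to carry; anything else is an
# extra-element warning at the profile tier.
.PROFILE_ALLOWED <- list(
  Immunization = c("resourceType", "id", "meta", "text", "status", "vaccineCode",
                   "patient", "occurrenceDateTime", "lotNumber", "primarySource",
                   "performer", "protocolApplied"),
  Medication = c("resourceType", "id", "meta", "text", "identifier", "code",
                 "status", "form", "amount", "ingredient", "batch"),
  MedicationRequest = c("resourceType", "id", "meta", "text", "status", "intent",
                        "medicationCodeableConcept", "subject", "authoredOn",
                        "dosageInstruction"),
  Procedure = c("resourceType", "id", "meta", "text", "status", "code",
                "subject", "performedDateTime")
)

#' The validator rule catalogue
#'
#' One row per rule the two-tier validator can emit. `origin` marks rules
#' grounded directly in the IPS transformation requirements
#' (`"ips-requirement"`) versus conformance checks added by this toolkit
#' (`"toolkit"`).
#'
#' @return data.frame with columns `rule_id`, `tier`, `severity`,
#'   `origin`, `description`.
#' @export
ips_rule_catalogue <- function() {
  read_row <- function(...) list(...)
  rows <- list(
    read_row("SYN-TYPE", "syntax", "error", "toolkit",
             "resourceType must be a registered FHIR R4 type"),
    read_row("SYN-REQ", "syntax", "error", "toolkit",
             "required base element missing for this resource type"),
    read_row("SYN-STATUS", "syntax", "error", "toolkit",
             "status outside the R4 value set for this resource type"),
    read_row("SYN-DATE", "syntax", "error", "toolkit",
             "date/dateTime/instant string does not match the FHIR lexical form"),
    read_row("SYN-REF", "syntax", "error", "toolkit",
             "reference string is not '#id', 'Type/id' or an absolute URL"),
    read_row("REF-INLINE", "syntax", "error", "ips-requirement",
             "reference element embeds an inline resource object (redundant nested resource)"),
    read_row("IPS-PROFILE-URI", "profile", "error", "ips-requirement",
             "meta.profile must carry the expected IPS canonical URI"),
    read_row("IPS-CONTAINED", "profile", "error", "ips-requirement",
             "contained must be empty after flattening"),
    read_row("SYS-UNKNOWN", "profile", "error", "ips-requirement",
             "coding system is 'undefined' or otherwise unrecognized"),
    read_row("SYS-MISSING", "profile", "warning", "toolkit",
             "coding has no system"),
    read_row("PROC-SNOMED", "profile", "error", "ips-requirement",
             "Procedure code.coding[0].system must be SNOMED CT"),
    read_row("PROC-CODING1", "profile", "warning", "ips-requirement",
             "Procedure code should carry a single coding (coding[0] only)"),
    read_row("PROC-DATE", "profile", "error", "ips-requirement",
             "Procedure must carry a valid performedDateTime"),
    read_row("MR-CODEABLE", "profile", "error", "ips-requirement",
             "MedicationRequest must use medicationCodeableConcept, not medicationReference"),
    read_row("MED-NARRATIVE", "profile", "error", "ips-requirement",
             "Medication text.div must be present, well-formed XHTML"),
    read_row("IMM-META", "profile", "error", "ips-requirement",
             "Immunization meta must drop versionId/lastUpdated and carry a proper source URI"),
    read_row("TERM-UNMAPPED", "profile", "warning", "ips-requirement",
             "local (EDI) code has no entry in the supplied concept map"),
    read_row("IPS-EXTRA", "profile", "warning", "toolkit",
             "element outside the profile's expected element set")
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(rule_id = r[[1]], tier = r[[2]], severity = r[[3]],
               origin = r[[4]], description = r[[5]], stringsAsFactors = FALSE)
  }))
}

.issue <- function(severity, tier, path, rule_id, message) {
  data.frame(severity = severity, tier = tier, path = path, rule_id = rule_id,
             message = message, stringsAsFactors = FALSE)
}

.no_issues <- function() {
  data.frame(severity = character(), tier = character(), path = character(),
             rule_id = character(), message = character(), stringsAsFactors = FALSE)
}

.make_report <- function(resource, issues) {
  structure(list(
    resource_type = fhir_type(resource),
    resource_id = fhir_id(resource) %||% "",
    issues = issues,
    valid = !any(issues$severity == "error")
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s/%s: %s (%d error, %d warning)\n",
              x$resource_type, x$resource_id,
              if (x$valid) "valid" else "INVALID",
              sum(x$issues$severity == "error"),
              sum(x$issues$severity == "warning")))
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues))) {
      r <- x$issues[i, ]
      cat(sprintf("  [%s/%s] %s @ %s: %s\n", r$tier, r$severity, r$rule_id,
                  r$path, r$message))
    }
  }
  invisible(x)
}

# Recursive walks -------------------------------------------------------------

.walk_named <- function(node, path, fn, acc) {
  if (!is.list(node)) return(acc)
  nms <- names(node)
  for (i in seq_along(node)) {
    child <- node[[i]]
    nm <- if (!is.null(nms) && nzchar(nms[[i]])) nms[[i]] else as.character(i - 1L)
    p <- if (nzchar(path)) paste(path, nm, sep = ".") else nm
    acc <- fn(nm, child, p, acc)
    acc <- .walk_named(child, p, fn, acc)
  }
  acc
}

.check_dates <- function(tree) {
  .walk_named(tree, "", function(nm, val, p, acc) {
    if (!is_string(val)) return(acc)
    re <- if (nm %in% .DATE_ELEMENTS$date) .FHIR_DATE_RE
      else if (nm %in% .DATE_ELEMENTS$dateTime) .FHIR_DATETIME_RE
      else if (nm %in% .DATE_ELEMENTS$instant) .FHIR_INSTANT_RE
      else return(acc)
    if (!grepl(re, val)) {
      acc <- rbind(acc, .issue("error", "syntax", p, "SYN-DATE",
        sprintf("'%s' is not a valid FHIR %s value", val, nm)))
    }
    acc
  }, .no_issues())
}

.check_references <- function(tree) {
  .walk_named(tree, "", function(nm, val, p, acc) {
    if (!is.list(val) || is.null(names(val)) || !"reference" %in% names(val)) {
      return(acc)
    }
    ref <- val[["reference"]]
    if (!is_string(ref) ||
        !(grepl("^#[A-Za-z0-9.\\-]+$", ref) ||
          grepl("^[A-Za-z]+/[A-Za-z0-9.\\-]{1,64}$", ref) ||
          reference_kind(ref) == "absolute")) {
      acc <- rbind(acc, .issue("error", "syntax", paste0(p, ".reference"),
        "SYN-REF", "reference string is not '#id', 'Type/id' or an absolute URL"))
    }
    for (sub in val) {
      if (is.list(sub) && !is.null(sub[["resourceType"]])) {
        acc <- rbind(acc, .issue("error", "syntax", p, "REF-INLINE",
          sprintf("inline %s resource embedded in reference element",
                  sub[["resourceType"]])))
      }
    }
    acc
  }, .no_issues())
}

#' Tier-1 syntactic validation against the FHIR R4 base structure
#'
#' Checks the registered resource type, required base elements, status
#' value sets, date/dateTime/instant lexical forms and reference
#' well-formedness. Unresolved reference *targets* are explicitly not
#' checked. Issues are returned, never raised.
#'
#' @param resource A `fhir_resource`.
#' @return A `validation_report` (fields `resource_type`, `resource_id`,
#'   `issues`, `valid`).
#' @export
validate_syntax <- function(resource) {
  stopifnot(is_fhir_resource(resource))
  tree <- unclass(resource)
  rt <- fhir_type(resource)
  issues <- .no_issues()

  if (!rt %in% FHIR_RESOURCE_TYPES) {
    issues <- rbind(issues, .issue("error", "syntax", "resourceType", "SYN-TYPE",
      sprintf("'%s' is not a registered resource type", rt)))
  }
  for (el in .REQUIRED_ELEMENTS[[rt]] %||% character()) {
    if (is.null(tree[[el]])) {
      issues <- rbind(issues, .issue("error", "syntax", el, "SYN-REQ",
        sprintf("%s.%s is required", rt, el)))
    }
  }
  if (identical(rt, "MedicationRequest") &&
      is.null(tree[["medicationCodeableConcept"]]) &&
      is.null(tree[["medicationReference"]])) {
    issues <- rbind(issues, .issue("error", "syntax", "medication[x]", "SYN-REQ",
      "MedicationRequest.medication[x] is required"))
  }
  vs <- .STATUS_VALUE_SETS[[rt]]
  if (!is.null(vs) && is_string(tree[["status"]]) && !tree[["status"]] %in% vs) {
    issues <- rbind(issues, .issue("error", "syntax", "status", "SYN-STATUS",
      sprintf("status '%s' is not in the R4 %s value set", tree[["status"]], rt)))
  }
  issues <- rbind(issues, .check_dates(tree), .check_references(tree))
  .make_report(resource, issues)
}

# Collect (path, coding) pairs across the tree.
.collect_codings <- function(tree) {
  out <- list()
  .walk_named(tree, "", function(nm, val, p, acc) {
    if (identical(nm, "coding") && is.list(val) && is.null(names(val))) {
      for (i in seq_along(val)) {
        out[[length(out) + 1L]] <<- list(path = paste(p, i - 1L, sep = "."),
                                         coding = val[[i]])
      }
    }
    acc
  }, NULL)
  out
}

#' Tier-2 IPS profile validation for the four transformed profiles
#'
#' Codifies the semantic conformance checks applied to transformed
#' output: expected IPS profile URI (Immunization, MedicationRequest),
#' empty `contained`, no undefined/unrecognized coding systems, SNOMED CT
#' procedure coding with a single entry and a populated
#' `performedDateTime`, `medicationCodeableConcept` (never a reference)
#' on MedicationRequest, well-formed XHTML narrative on Medication, and
#' the Immunization meta policy. When `concept_map` is supplied, EDI
#' codes absent from it are flagged `TERM-UNMAPPED`.
#'
#' @param resource A `fhir_resource` of type Medication,
#'   MedicationRequest, Immunization or Procedure.
#' @param concept_map Optional `concept_map` for unmapped-code checks.
#' @return A `validation_report`.
#' @export
validate_ips_profile <- function(resource, concept_map = NULL) {
  stopifnot(is_fhir_resource(resource))
  rt <- fhir_type(resource)
  if (!rt %in% names(.PROFILE_ALLOWED)) {
    stop(sprintf("type error: no IPS profile rules for resource type '%s'", rt),
         call. = FALSE)
  }
  tree <- unclass(resource)
  issues <- .no_issues()
  systems <- ips_code_systems()

  expected <- if (rt %in% names(.EXPECTED_PROFILE)) .EXPECTED_PROFILE[[rt]] else NULL
  if (!is.null(expected)) {
    profs <- unlist(tree[["meta"]][["profile"]] %||% list(), use.names = FALSE)
    if (!expected %in% profs) {
      issues <- rbind(issues, .issue("error", "profile", "meta.profile",
        "IPS-PROFILE-URI", sprintf("expected profile %s", expected)))
    }
  }

  if (length(tree[["contained"]] %||% list())) {
    issues <- rbind(issues, .issue("error", "profile", "contained",
      "IPS-CONTAINED", "contained resources must be flattened away"))
  }

  for (pc in .collect_codings(tree)) {
    sys <- pc$coding[["system"]]
    if (is.null(sys)) {
      issues <- rbind(issues, .issue("warning", "profile",
        paste0(pc$path, ".system"), "SYS-MISSING", "coding has no system"))
      next
    }
    canon <- as.character(canonicalize_system(sys))
    if (identical(canon, IPS_UNKNOWN_SYSTEM)) {
      issues <- rbind(issues, .issue("error", "profile",
        paste0(pc$path, ".system"), "SYS-UNKNOWN",
        sprintf("coding system '%s' is undefined/unrecognized", sys)))
    } else if (!is.null(concept_map) && identical(canon, systems[["edi"]])) {
      if (!is_matched(map_code(concept_map, canon, pc$coding[["code"]] %||% ""))) {
        issues <- rbind(issues, .issue("warning", "profile", pc$path,
          "TERM-UNMAPPED",
          sprintf("EDI code '%s' has no entry in the concept map",
                  pc$coding[["code"]] %||% "")))
      }
    }
  }

  if (identical(rt, "Procedure")) {
    codings <- tree[["code"]][["coding"]] %||% list()
    if (length(codings) > 1L) {
      issues <- rbind(issues, .issue("warning", "profile", "code.coding",
        "PROC-CODING1", sprintf("%d codings present; expected one", length(codings))))
    }
    sys0 <- if (length(codings)) codings[[1]][["system"]] else NULL
    if (!identical(as.character(canonicalize_system(sys0)), systems[["snomed"]])) {
      issues <- rbind(issues, .issue("error", "profile", "code.coding.0.system",
        "PROC-SNOMED", "Procedure coding[0] must use http://snomed.info/sct"))
    }
    pd <- tree[["performedDateTime"]]
    if (!is_string(pd) || !grepl(.FHIR_DATETIME_RE, pd)) {
      issues <- rbind(issues, .issue("error", "profile", "performedDateTime",
        "PROC-DATE", "performedDateTime must be present and valid"))
    }
  }

  if (identical(rt, "MedicationRequest")) {
    if (!is.null(tree[["medicationReference"]])) {
      issues <- rbind(issues, .issue("error", "profile", "medicationReference",
        "MR-CODEABLE", "medicationReference must not be used"))
    }
    if (is.null(tree[["medicationCodeableConcept"]])) {
      issues <- rbind(issues, .issue("error", "profile",
        "medicationCodeableConcept", "MR-CODEABLE",
        "medicationCodeableConcept is required"))
    }
  }

  if (identical(rt, "Medication")) {
    div <- tree[["text"]][["div"]]
    ok <- non_empty_string(div) &&
      !inherits(try(xml2::read_xml(div), silent = TRUE), "try-error")
    if (!ok) {
      issues <- rbind(issues, .issue("error", "profile", "text.div",
        "MED-NARRATIVE", "text.div missing or not well-formed XHTML"))
    }
  }

  if (identical(rt, "Immunization")) {
    m <- tree[["meta"]] %||% list()
    if (!is.null(m[["versionId"]]) || !is.null(m[["lastUpdated"]])) {
      issues <- rbind(issues, .issue("error", "profile", "meta", "IMM-META",
        "meta must not carry versionId/lastUpdated"))
    }
    src <- m[["source"]]
    if (!non_empty_string(src) || startsWith(src, "#")) {
      issues <- rbind(issues, .issue("error", "profile", "meta.source",
        "IMM-META", "meta.source must be a proper URI (no tag-like strings)"))
    }
  }

  allowed <- .PROFILE_ALLOWED[[rt]]
  for (nm in setdiff(names(tree), allowed)) {
    issues <- rbind(issues, .issue("warning", "profile", nm, "IPS-EXTRA",
      sprintf("element '%s' is outside the %s IPS element set", nm, rt)))
  }

  .make_report(resource, issues)
}

#' Validate a resource across both tiers
#'
#' Runs [validate_syntax()] always and [validate_ips_profile()] when the
#' resource type has profile rules.
#'
#' @inheritParams validate_ips_profile
#' @param tiers Subset of `c("syntax", "profile")`.
#' @return A `validation_report` with the combined issue list.
#' @export
validate_resource <- function(resource, tiers = c("syntax", "profile"),
                              concept_map = NULL) {
  issues <- .no_issues()
  if ("syntax" %in% tiers) {
    issues <- rbind(issues, validate_syntax(resource)$issues)
  }
  if ("profile" %in% tiers && fhir_type(resource) %in% names(.PROFILE_ALLOWED)) {
    issues <- rbind(issues, validate_ips_profile(resource, concept_map)$issues)
  }
  .make_report(resource, issues)
}

#' Validate a set of resources with aggregate totals
#'
#' @param resources List of `fhir_resource`.
#' @inheritParams validate_resource
#' @return Object of class `validation_set`: `reports` (in input order),
#'   `n_resources`, `n_valid`, `n_error`, `n_warning`.
#' @export
validate_set <- function(resources, tiers = c("syntax", "profile"),
                         concept_map = NULL) {
  reports <- lapply(resources, validate_resource, tiers = tiers,
                    concept_map = concept_map)
  n_err <- sum(vapply(reports, function(r) sum(r$issues$severity == "error"),
                      integer(1)))
  n_warn <- sum(vapply(reports, function(r) sum(r$issues$severity == "warning"),
                       integer(1)))
  structure(list(
    reports = reports,
    n_resources = length(reports),
    n_valid = sum(vapply(reports, function(r) isTRUE(r$valid), logical(1))),
    n_error = n_err,
    n_warning = n_warn
  ), class = "validation_set")
}

#' @export
print.validation_set <- function(x, ...) {
  cat(sprintf("<validation_set> %d resources: %d valid, %d error issue(s), %d warning(s)\n",
              x$n_resources, x$n_valid, x$n_error, x$n_warning))
  invisible(x)
}

#' Export a validation report as OperationOutcome-shaped JSON
#'
#' @param report A `validation_report`.
#' @return A list mirroring a FHIR OperationOutcome (issue severity,
#'   code, diagnostics, expression), suitable for
#'   `jsonlite::write_json()`.
#' @export
as_operation_outcome <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  issues <- report$issues
  entries <- if (nrow(issues) == 0L) {
    list(list(severity = "information", code = "informational",
              diagnostics = "no issues"))
  } else {
    lapply(seq_len(nrow(issues)), function(i) {
      list(severity = issues$severity[[i]],
           code = if (issues$tier[[i]] == "syntax") "structure" else "invariant",
           diagnostics = sprintf("[%s] %s", issues$rule_id[[i]], issues$message[[i]]),
           expression = list(issues$path[[i]]))
    })
  }
  list(resourceType = "OperationOutcome", issue = entries)
}
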