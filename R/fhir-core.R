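# Minimal FHIR R4 data model: JSON parsing/serialization with deterministic
# element ordering, contained-resource access and reference utilities.
#
# Resources are held as plain R lists mirroring the JSON tree (named lists
# for objects, unnamed lists for arrays) with class "fhir_resource".
# Unknown elements are preserved verbatim at parse time; only explicit
# transform rules remove anything.

# Resource types the toolkit recognises. Substance and Practitioner are
# included because source exports carry them inside `contained` and in
# performer references, even though no transformation targets them.
FHIR_RESOURCE_TYPES <- c(
  "Patient", "Organization", "Encounter", "Medication", "MedicationDispense",
  "MedicationRequest", "Immunization", "Procedure", "Condition",
  "AllergyIntolerance", "DiagnosticReport", "Bundle",
  "Substance", "Practitioner"
)

# R4 definition order of top-level elements, used for deterministic output.
# Elements not listed here are appended in input order.
.FHIR_COMMON_PREFIX <- c(
  "resourceType", "id", "meta", "implicitRules", "language", "text",
  "contained", "extension", "modifierExtension"
)

.FHIR_ELEMENT_ORDER <- list(
  Patient = c("identifier", "active", "name", "telecom", "gender", "birthDate",
    "deceasedBoolean", "deceasedDateTime", "address", "maritalStatus",
    "contact", "communication", "generalPractitioner", "managingOrganization"),
  Organization = c("identifier", "active", "type", "name", "alias", "telecom",
    "address", "partOf", "contact", "endpoint"),
  Encounter = c("identifier", "status", "statusHistory", "class", "classHistory",
    "type", "serviceType", "priority", "subject", "episodeOfCare", "basedOn",
    "participant", "appointment", "period", "length", "reasonCode",
    "reasonReference", "diagnosis", "account", "hospitalization", "location",
    "serviceProvider", "partOf"),
  Medication = c("identifier", "code", "status", "manufacturer", "form",
    "amount", "ingredient", "batch"),
  MedicationDispense = c("identifier", "partOf", "status",
    "statusReasonCodeableConcept", "statusReasonReference", "category",
    "medicationCodeableConcept", "medicationReference", "subject", "context",
    "supportingInformation", "performer", "location", "authorizingPrescription",
    "type", "quantity", "daysSupply", "whenPrepared", "whenHandedOver",
    "destination", "receiver", "note", "dosageInstruction", "substitution",
    "detectedIssue", "eventHistory"),
  MedicationRequest = c("identifier", "status", "statusReason", "intent",
    "category", "priority", "doNotPerform", "reportedBoolean",
    "reportedReference", "medicationCodeableConcept", "medicationReference",
    "subject", "encounter", "supportingInformation", "authoredOn", "requester",
    "performer", "performerType", "recorder", "reasonCode", "reasonReference",
    "instantiatesCanonical", "instantiatesUri", "basedOn", "groupIdentifier",
    "courseOfTherapyType", "insurance", "note", "dosageInstruction",
    "dispenseRequest", "substitution", "priorPrescription", "detectedIssue",
    "eventHistory"),
  Immunization = c("identifier", "status", "statusReason", "vaccineCode",
    "patient", "encounter", "occurrenceDateTime", "occurrenceString",
    "recorded", "primarySource", "reportOrigin", "location", "manufacturer",
    "lotNumber", "expirationDate", "site", "route", "doseQuantity",
    "performer", "note", "reasonCode", "reasonReference", "isSubpotent",
    "subpotentReason", "education", "programEligibility", "fundingSource",
    "reaction", "protocolApplied"),
  Procedure = c("identifier", "instantiatesCanonical", "instantiatesUri",
    "basedOn", "partOf", "status", "statusReason", "category", "code",
    "subject", "encounter", "performedDateTime", "performedPeriod",
    "performedString", "performedAge", "performedRange", "recorder",
    "asserter", "performer", "location", "reasonCode", "reasonReference",
    "bodySite", "outcome", "report", "complication", "complicationDetail",
    "followUp", "note", "focalDevice", "usedReference", "usedCode"),
  Condition = c("identifier", "clinicalStatus", "verificationStatus",
    "category", "severity", "code", "bodySite", "subject", "encounter",
    "onsetDateTime", "recordedDate", "note"),
  AllergyIntolerance = c("identifier", "clinicalStatus", "verificationStatus",
    "type", "category", "criticality", "code", "patient", "encounter",
    "onsetDateTime", "recordedDate", "note", "reaction"),
  DiagnosticReport = c("identifier", "basedOn", "status", "category", "code",
    "subject", "encounter", "effectiveDateTime", "effectivePeriod", "issued",
    "performer", "resultsInterpreter", "specimen", "result", "imagingStudy",
    "media", "conclusion", "conclusionCode", "presentedForm"),
  Bundle = c("identifier", "type", "timestamp", "total", "link", "entry",
    "signature"),
  Substance = c("identifier", "status", "category", "code", "description",
    "instance", "ingredient"),
  Practitioner = c("identifier", "active", "name", "telecom", "address",
    "gender", "birthDate", "qualification", "communication")
)

#' Construct a FHIR resource from an R list tree
#'
#' Wraps a parsed JSON tree (named lists for objects, unnamed lists for
#' arrays) as a `fhir_resource`, checking the structural invariants the
#' toolkit relies on: a registered `resourceType` and, when a `contained`
#' list is present, that every contained entry is itself a resource with
#' an `id`.
#'
#' @param tree A named list with at least a `resourceType` element.
#' @return An object of class `fhir_resource`.
#' @export
fhir_resource <- function(tree) {
  if (!is.list(tree) || is.null(names(tree))) {
    stop("fhir_resource: tree must be a named list", call. = FALSE)
  }
  rt <- tree[["resourceType"]]
  if (!non_empty_string(rt)) {
    stop("unsupported-resource: missing resourceType", call. = FALSE)
  }
  if (!rt %in% FHIR_RESOURCE_TYPES) {
    stop(sprintf("unsupported-resource: resourceType '%s' is not registered", rt),
         call. = FALSE)
  }
  contained <- tree[["contained"]]
  if (!is.null(contained)) {
    for (k in seq_along(contained)) {
      entry <- contained[[k]]
      ct <- if (is.list(entry)) entry[["resourceType"]] else NULL
      if (!non_empty_string(ct) || !ct %in% FHIR_RESOURCE_TYPES) {
        stop(sprintf("unsupported-resource: contained[%d] has no registered resourceType",
                     k - 1L), call. = FALSE)
      }
      if (!non_empty_string(entry[["id"]])) {
        stop(sprintf("invalid-contained: contained[%d] (%s) has no id", k - 1L, ct),
             call. = FALSE)
      }
    }
  }
  structure(tree, class = "fhir_resource")
}

#' @export
print.fhir_resource <- function(x, ...) {
  cat(sprintf("<fhir_resource> %s", x[["resourceType"]]))
  if (non_empty_string(x[["id"]])) cat(sprintf("/%s", x[["id"]]))
  cat(sprintf("  (%d top-level elements, %d contained)\n",
              length(x), length(x[["contained"]])))
  invisible(x)
}

#' @rdname fhir_resource
#' @param x An object.
#' @export
is_fhir_resource <- function(x) inherits(x, "fhir_resource")

#' Resource type and id accessors
#'
#' @param resource A `fhir_resource`.
#' @return `fhir_type()` the resourceType string; `fhir_id()` the id string
#'   or `NULL`.
#' @export
fhir_type <- function(resource) resource[["resourceType"]]

#' @rdname fhir_type
#' @export
fhir_id <- function(resource) resource[["id"]]

# Locate the byte offset of a JSON syntax error by re-validating prefixes
# (bisection); only runs on the error path.
.json_error_offset <- function(txt) {
  raw <- charToRaw(enc2utf8(txt))
  lo <- 0L; hi <- length(raw)
  # find smallest prefix length at which the prefix can no longer be
  # extended to valid JSON: approximate via validity of prefix + plausible
  # closers is overkill; report the first position where validation of the
  # full text fails by scanning from the yajl message is fragile, so use
  # a linear scan capped at 4096 checks for small inputs, else bisect on
  # "prefix parses as a JSON prefix" via incremental brace balance.
  depth <- 0L; in_str <- FALSE; esc <- FALSE
  for (i in seq_along(raw)) {
    ch <- rawToChar(raw[i])
    if (in_str) {
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == "\"") in_str <- FALSE
      next
    }
    if (ch == "\"") in_str <- TRUE
    else if (ch %in% c("{", "[")) depth <- depth + 1L
    else if (ch %in% c("}", "]")) {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  length(raw)
}

#' Parse a FHIR R4 resource from JSON text
#'
#' @param json_text A single UTF-8 string of JSON with a top-level
#'   `resourceType` member.
#' @return A `fhir_resource`. Unknown elements are preserved verbatim.
#' @examples
#' r <- parse_resource('{"resourceType":"Immunization","status":"completed"}')
#' fhir_type(r)
#' @export
parse_resource <- function(json_text) {
  stopifnot(is_string(json_text))
  if (!jsonlite::validate(json_text)) {
    stop(sprintf("parse error: malformed JSON near byte offset %d",
                 .json_error_offset(json_text)), call. = FALSE)
  }
  tree <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  fhir_resource(tree)
}

# Reorder a resource tree: common prefix, then the type's R4 element order,
# then unknown elements in input order. Applied recursively to contained
# resources and Bundle entries.
.order_resource_tree <- function(tree) {
  rt <- tree[["resourceType"]]
  order_vec <- c(.FHIR_COMMON_PREFIX, .FHIR_ELEMENT_ORDER[[rt]] %||% character())
  nms <- names(tree)
  known <- order_vec[order_vec %in% nms]
  unknown <- nms[!nms %in% order_vec]
  tree <- tree[c(known, unknown)]
  if (!is.null(tree[["contained"]])) {
    tree[["contained"]] <- lapply(tree[["contained"]], .order_resource_tree)
  }
  if (identical(rt, "Bundle") && !is.null(tree[["entry"]])) {
    tree[["entry"]] <- lapply(tree[["entry"]], function(e) {
      if (is.list(e[["resource"]]) && non_empty_string(e[["resource"]][["resourceType"]])) {
        e[["resource"]] <- .order_resource_tree(e[["resource"]])
      }
      e
    })
  }
  tree
}

#' Serialize a FHIR resource to deterministic JSON
#'
#' Output ordering is fixed: R4 definition order for known top-level
#' elements, then unknown elements in input order; byte-identical across
#' runs for the same tree, and `parse_resource(serialize_resource(r))`
#' reproduces `r` up to that canonical ordering.
#'
#' @param resource A `fhir_resource`.
#' @param pretty Indent the output (2 spaces) for on-disk files.
#' @return A single JSON string.
#' @export
serialize_resource <- function(resource, pretty = FALSE) {
  stopifnot(is_fhir_resource(resource))
  tree <- .order_resource_tree(unclass(resource))
  as.character(jsonlite::toJSON(
    tree, auto_unbox = TRUE, digits = NA, null = "null",
    pretty = if (isTRUE(pretty)) 2L else FALSE
  ))
}

#' List the contained resources of a resource
#'
#' @param resource A `fhir_resource`.
#' @return A list of `fhir_resource` (empty when nothing is contained).
#' @export
list_contained <- function(resource) {
  contained <- resource[["contained"]]
  if (is.null(contained)) return(list())
  lapply(contained, fhir_resource)
}

#' Classify a FHIR reference string
#'
#' @param reference_string A reference value such as `"Patient/p1"`,
#'   `"#med1"` or an absolute URL.
#' @return One of `"local"` (`#`-prefixed), `"absolute"` (has a URI
#'   scheme), or `"relative"`.
#' @export
reference_kind <- function(reference_string) {
  stopifnot(is_string(reference_string))
  if (startsWith(reference_string, "#")) return("local")
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", reference_string) ||
      grepl("^urn:", reference_string)) return("absolute")
  "relative"
}

#' Flatten a reference element to "Type/id" form
#'
#' Replaces the element at `element_path` with the single-member object
#' `{"reference": "<target_type>/<target_id>"}`; any inline resource
#' object or extra members at that path are removed entirely. Idempotent.
#'
#' @param resource A `fhir_resource`.
#' @param element_path Dotted path of the reference-bearing element
#'   (list entries by zero-based index, e.g. `"performer.0.actor"`).
#' @param target_type Resource type for the flat reference.
#' @param target_id Non-empty id for the flat reference.
#' @return The modified `fhir_resource`.
#' @export
rewrite_reference <- function(resource, element_path, target_type, target_id) {
  stopifnot(is_fhir_resource(resource))
  if (!non_empty_string(target_id)) {
    stop("invalid-argument: target_id must be a non-empty string", call. = FALSE)
  }
  if (!non_empty_string(target_type)) {
    stop("invalid-argument: target_type must be a non-empty string", call. = FALSE)
  }
  tree <- unclass(resource)
  if (!path_exists(tree, element_path)) {
    stop(sprintf("path-not-found: '%s' is not present", element_path), call. = FALSE)
  }
  tree <- path_set(tree, element_path,
                   list(reference = paste0(target_type, "/", target_id)))
  fhir_resource(tree)
}

# ---- files and bundles -----------------------------------------------------

#' Read and write FHIR resources as JSON files
#'
#' @param path File path.
#' @return `read_resource()` a `fhir_resource`; writers return `path`
#'   invisibly.
#' @export
read_resource <- function(path) {
  parse_resource(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n"))
}

#' @rdname read_resource
#' @param resource A `fhir_resource`.
#' @param pretty Indent output.
#' @export
write_resource <- function(resource, path, pretty = TRUE) {
  txt <- serialize_resource(resource, pretty = pretty)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(enc2utf8(paste0(txt, "\n"))), con)
  invisible(path)
}

#' Build a Bundle resource from a list of resources
#'
#' @param entries List of `fhir_resource`.
#' @param type Bundle type token (default `"collection"`).
#' @param id Optional bundle id.
#' @return A `fhir_resource` of type Bundle; entry order is preserved.
#' @export
make_bundle <- function(entries, type = "collection", id = NULL) {
  stopifnot(is.list(entries))
  tree <- list(resourceType = "Bundle")
  if (!is.null(id)) tree[["id"]] <- id
  tree[["type"]] <- type
  tree[["entry"]] <- lapply(entries, function(r) {
    stopifnot(is_fhir_resource(r))
    list(resource = unclass(r))
  })
  fhir_resource(tree)
}

#' Extract the entry resources of a Bundle
#'
#' @param bundle A `fhir_resource` of type Bundle.
#' @return List of `fhir_resource` in entry order.
#' @export
bundle_entries <- function(bundle) {
  stopifnot(is_fhir_resource(bundle), identical(fhir_type(bundle), "Bundle"))
  lapply(bundle[["entry"]] %||% list(), function(e) fhir_resource(e[["resource"]]))
}

#' Read and write NDJSON resource stores
#'
#' One resource per line, the standard FHIR bulk-data layout.
#'
#' @param resources List of `fhir_resource`.
#' @param path File path.
#' @return `read_ndjson()` a list of `fhir_resource`; `write_ndjson()`
#'   returns `path` invisibly.
#' @export
write_ndjson <- function(resources, path) {
  lines <- vapply(resources, serialize_resource, character(1), pretty = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  if (length(lines)) {
    writeBin(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"), "\n"))), con)
  }
  invisible(path)
}

#' @rdname write_ndjson
#' @export
read_ndjson <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_resource)
}
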