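# Code-system canonicalization and local->international concept mapping.
#
# Korean source exports mix canonical URIs, short names ("EDI", "SNOMED"),
# and the literal strings "undefined" / "resource identifier (undefined)".
# canonicalize_system() reduces all of these to a fixed URI or the UNKNOWN
# marker; map_code() is a strict exact lookup against a ConceptMap-style
# table -- codes are never inferred, only taken from the mapping table.

#' Canonical code-system URIs
#'
#' Fixed canonical identifiers used throughout the toolkit. The EDI URI is
#' a documented placeholder chosen by this package (HIRA publishes no
#' canonical URI for EDI claim codes).
#'
#' @return Named character vector with entries `snomed`, `loinc`, `atc`,
#'   `kcd`, `edi`.
#' @export
ips_code_systems <- function() {
  c(snomed = "http://snomed.info/sct",
    loinc  = "http://loinc.org",
    atc    = "http://www.whocc.no/atc",
    kcd    = "http://hl7.org/fhir/sid/icd-10-kr",
    edi    = "https://hira.or.kr/CodeSystem/edi")
}

#' @rdname ips_code_systems
#' @export
IPS_UNKNOWN_SYSTEM <- "UNKNOWN"

.pkg_extdata <- function(...) {
  system.file("extdata", ..., package = "ipspipe", mustWork = TRUE)
}

#' Load a code-system alias table
#'
#' CSV with columns `raw`, `canonical`; `canonical` is either a canonical
#' URI or the literal `UNKNOWN`.
#'
#' @param path CSV path; default is the packaged alias table.
#' @return data.frame with columns `raw`, `canonical`.
#' @export
load_system_aliases <- function(path = .pkg_extdata("terminology", "system_aliases.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  need <- c("raw", "canonical")
  if (!all(need %in% names(df))) {
    stop("schema error: alias table needs columns raw, canonical", call. = FALSE)
  }
  df
}

.alias_cache <- new.env(parent = emptyenv())

.default_aliases <- function() {
  if (is.null(.alias_cache$tbl)) .alias_cache$tbl <- load_system_aliases()
  .alias_cache$tbl
}

#' Canonicalize a code-system identifier
#'
#' Total function: every input yields a canonical URI or the `UNKNOWN`
#' marker, never an error. Matching against the alias table is
#' case-insensitive; `NULL`, `NA`, empty strings, `"undefined"` and
#' `"resource identifier (undefined)"` all map to `UNKNOWN`. An
#' unrecognized non-empty string maps to `UNKNOWN` with attribute
#' `unrecognized = TRUE`.
#'
#' @param raw System string as found in source data (or `NULL`).
#' @param aliases Alias table (see [load_system_aliases()]).
#' @return Canonical URI string, or `IPS_UNKNOWN_SYSTEM`.
#' @examples
#' canonicalize_system("EDI")
#' canonicalize_system("undefined")
#' @export
canonicalize_system <- function(raw, aliases = .default_aliases()) {
  if (is.null(raw) || !is_string(raw) || !nzchar(trimws(raw))) {
    return(IPS_UNKNOWN_SYSTEM)
  }
  key <- tolower(trimws(raw))
  hit <- match(key, tolower(aliases$raw))
  if (!is.na(hit)) return(aliases$canonical[[hit]])
  structure(IPS_UNKNOWN_SYSTEM, unrecognized = TRUE)
}

# ---- concept maps ----------------------------------------------------------

.CONCEPT_MAP_COLS <- c("source_system", "source_code", "target_system",
                       "target_code", "target_display", "equivalence")
.EQUIVALENCE_LEVELS <- c("equal", "wider", "narrower", "unmatched")

#' Load a ConceptMap-style lookup table from CSV
#'
#' Columns: `source_system`, `source_code`, `target_system`, `target_code`,
#' `target_display`, `equivalence` (one of equal/wider/narrower/unmatched).
#' Duplicate (source_system, source_code) keys are rejected.
#'
#' @param path CSV path.
#' @return An object of class `concept_map`.
#' @export
load_concept_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  missing_cols <- setdiff(.CONCEPT_MAP_COLS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: concept map is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_eq <- setdiff(unique(df$equivalence), .EQUIVALENCE_LEVELS)
  if (length(bad_eq)) {
    stop(sprintf("schema error: unknown equivalence value(s): %s",
                 paste(bad_eq, collapse = ", ")), call. = FALSE)
  }
  keys <- paste(df$source_system, df$source_code, sep = "|")
  dup <- keys[duplicated(keys)]
  if (length(dup)) {
    stop(sprintf("load error: duplicate concept-map key(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  incomplete <- df$equivalence != "unmatched" &
    (!nzchar(df$target_system) | !nzchar(df$target_code))
  if (any(incomplete)) {
    stop(sprintf("load error: entry with empty target but equivalence != unmatched: %s",
                 paste(keys[incomplete], collapse = ", ")), call. = FALSE)
  }
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(df))) assign(keys[[i]], i, envir = idx)
  structure(list(entries = df, index = idx, path = path), class = "concept_map")
}

#' @export
print.concept_map <- function(x, ...) {
  cat(sprintf("<concept_map> %d entries (%s -> %s)\n", nrow(x$entries),
              paste(unique(x$entries$source_system), collapse = ", "),
              paste(unique(x$entries$target_system), collapse = ", ")))
  invisible(x)
}

#' Packaged concept-map excerpts
#'
#' Small excerpts modeled on the published HIRA EDI to SNOMED CT and HINS
#' KCD to SNOMED CT mapping tables. The codes are synthetic stand-ins
#' chosen by this package (no real mapping rows are redistributed); the
#' EDI excerpt includes one entry targeting SNOMED CT 11466000
#' (cesarean section) used by the worked example.
#'
#' @return A `concept_map`.
#' @export
default_edi_snomed_map <- function() {
  load_concept_map(.pkg_extdata("terminology", "edi_snomed_excerpt.csv"))
}

#' @rdname default_edi_snomed_map
#' @export
default_kcd_snomed_map <- function() {
  load_concept_map(.pkg_extdata("terminology", "kcd_snomed_excerpt.csv"))
}

#' Look up a code in a concept map
#'
#' Exact-key lookup; no fuzzy matching or inference. A miss returns an
#' unmatched marker carrying the queried key.
#'
#' @param table A `concept_map`.
#' @param system Canonical source-system URI.
#' @param code Source code.
#' @return A list of class `concept_map_entry` on a hit (fields
#'   `source_system`, `source_code`, `target_system`, `target_code`,
#'   `target_display`, `equivalence`) or class `concept_map_unmatched` on
#'   a miss. Test with [is_matched()].
#' @export
map_code <- function(table, system, code) {
  stopifnot(inherits(table, "concept_map"), is_string(system), is_string(code))
  key <- paste(system, code, sep = "|")
  i <- if (exists(key, envir = table$index, inherits = FALSE)) {
    get(key, envir = table$index, inherits = FALSE)
  } else NA_integer_
  if (is.na(i)) {
    return(structure(list(source_system = system, source_code = code),
                     class = "concept_map_unmatched"))
  }
  row <- table$entries[i, , drop = FALSE]
  structure(as.list(row), class = "concept_map_entry")
}

#' @rdname map_code
#' @param entry Result of [map_code()].
#' @export
is_matched <- function(entry) inherits(entry, "concept_map_entry")
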