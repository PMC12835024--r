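# Machine-readable encoding of the IPS component/profile inventory and its
# mapping onto the KR Core profile set, with coverage statistics and the
# per-profile code-system discrepancies.
#
# The registry is data, not code: three CSVs (components, mappings, deltas)
# packaged under extdata/registry and schema-checked at load, so the
# mapping can be extended without touching the package.

#' Load an IPS/KR Core gap registry
#'
#' @param components_path CSV with columns `component`, `tier`
#'   (required/recommended), `ips_profile` -- one row per component-profile
#'   pair.
#' @param mappings_path CSV with columns `ips_profile`, `kr_profile` -- one
#'   row per IPS-profile/KR-profile pair; an empty `kr_profile` cell means
#'   NO MATCH.
#' @param deltas_path CSV with columns `ips_profile`, `ips_system`,
#'   `kr_system` (canonical URIs); agreement is derived, not stored.
#' @return Object of class `ips_gap_registry` with data.frames
#'   `components`, `mappings`, `deltas`.
#' @export
load_gap_registry <- function(components_path, mappings_path, deltas_path) {
  comp <- utils::read.csv(components_path, stringsAsFactors = FALSE,
                          comment.char = "#", colClasses = "character")
  maps <- utils::read.csv(mappings_path, stringsAsFactors = FALSE,
                          comment.char = "#", colClasses = "character")
  deltas <- utils::read.csv(deltas_path, stringsAsFactors = FALSE,
                            comment.char = "#", colClasses = "character")

  if (!all(c("component", "tier", "ips_profile") %in% names(comp))) {
    stop("load error: components file needs columns component, tier, ips_profile",
         call. = FALSE)
  }
  if (!all(c("ips_profile", "kr_profile") %in% names(maps))) {
    stop("load error: mappings file needs columns ips_profile, kr_profile",
         call. = FALSE)
  }
  if (!all(c("ips_profile", "ips_system", "kr_system") %in% names(deltas))) {
    stop("load error: deltas file needs columns ips_profile, ips_system, kr_system",
         call. = FALSE)
  }
  bad_tier <- setdiff(unique(comp$tier), c("required", "recommended"))
  if (length(bad_tier)) {
    stop(sprintf("load error: unknown tier value(s): %s",
                 paste(bad_tier, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(comp$ips_profile)) {
    stop("load error: an ips_profile appears under more than one component",
         call. = FALSE)
  }
  unknown <- setdiff(unique(maps$ips_profile), comp$ips_profile)
  if (length(unknown)) {
    stop(sprintf("load error: mapping references unknown IPS profile(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  deltas$agrees <- deltas$ips_system == deltas$kr_system
  structure(list(components = comp, mappings = maps, deltas = deltas),
            class = "ips_gap_registry")
}

#' @rdname load_gap_registry
#' @export
load_default_registry <- function() {
  load_gap_registry(
    .pkg_extdata("registry", "ips_components.csv"),
    .pkg_extdata("registry", "kr_core_mappings.csv"),
    .pkg_extdata("registry", "code_system_deltas.csv")
  )
}

#' @export
print.ips_gap_registry <- function(x, ...) {
  cat(sprintf("<ips_gap_registry> %d components, %d IPS profiles, %d mapping rows, %d code-system deltas\n",
              length(unique(x$components$component)),
              length(unique(x$components$ips_profile)),
              nrow(x$mappings), nrow(x$deltas)))
  invisible(x)
}

# Derived mapping cardinality per IPS profile: 0 KR profiles -> unmapped,
# 1 -> one_to_one, >1 -> one_to_many.
profile_cardinality <- function(registry) {
  profs <- unique(registry$components$ips_profile)
  kr_count <- vapply(profs, function(p) {
    kr <- registry$mappings$kr_profile[registry$mappings$ips_profile == p]
    sum(nzchar(kr))
  }, integer(1))
  data.frame(
    ips_profile = profs,
    n_kr = unname(kr_count),
    cardinality = ifelse(kr_count == 0L, "unmapped",
                         ifelse(kr_count == 1L, "one_to_one", "one_to_many")),
    stringsAsFactors = FALSE
  )
}

#' Compute the gap report for a registry
#'
#' A component counts as mapped iff at least one of its IPS profiles has
#' at least one KR Core mapping. Coverage is the mapped fraction as a
#' percentage, rounded half away from zero to the nearest integer.
#'
#' @param registry An `ips_gap_registry`.
#' @return Object of class `ips_gap_report` with fields `n_components`,
#'   `n_components_mapped`, `component_coverage_pct`,
#'   `n_ips_profiles_mapped`, `unmapped_ips_profiles`,
#'   `kr_profiles_referenced`, `deltas`.
#' @examples
#' compute_gap_report(load_default_registry())
#' @export
compute_gap_report <- function(registry) {
  stopifnot(inherits(registry, "ips_gap_registry"))
  comp <- registry$components
  components <- unique(comp$component)
  if (length(components) == 0L) {
    stop("undefined-coverage: registry has no components", call. = FALSE)
  }
  card <- profile_cardinality(registry)
  mapped_profiles <- card$ips_profile[card$cardinality != "unmapped"]
  comp_mapped <- vapply(components, function(cm) {
    any(comp$ips_profile[comp$component == cm] %in% mapped_profiles)
  }, logical(1))
  kr_ref <- registry$mappings$kr_profile[nzchar(registry$mappings$kr_profile)]
  structure(list(
    n_components = length(components),
    n_components_mapped = sum(comp_mapped),
    component_coverage_pct = as.integer(round_half_up(
      100 * sum(comp_mapped) / length(components))),
    n_ips_profiles_mapped = length(mapped_profiles),
    unmapped_ips_profiles = card$ips_profile[card$cardinality == "unmapped"],
    kr_profiles_referenced = unique(kr_ref),
    cardinality = card,
    deltas = registry$deltas
  ), class = "ips_gap_report")
}

#' @export
print.ips_gap_report <- function(x, ...) {
  cat("IPS / KR Core gap report\n")
  cat(sprintf("  components mapped : %d of %d (%d%%)\n",
              x$n_components_mapped, x$n_components, x$component_coverage_pct))
  cat(sprintf("  IPS profiles mapped: %d\n", x$n_ips_profiles_mapped))
  cat(sprintf("  KR Core profiles referenced: %d\n",
              length(x$kr_profiles_referenced)))
  if (length(x$unmapped_ips_profiles)) {
    cat("  NO MATCH:\n")
    for (p in x$unmapped_ips_profiles) cat(sprintf("    - %s\n", p))
  }
  if (nrow(x$deltas)) {
    cat("  code-system deltas:\n")
    for (i in seq_len(nrow(x$deltas))) {
      d <- x$deltas[i, ]
      cat(sprintf("    - %-28s %s vs %s (%s)\n", d$ips_profile, d$ips_system,
                  d$kr_system, if (d$agrees) "agrees" else "differs"))
    }
  }
  invisible(x)
}

#' Export a gap report as JSON
#'
#' @param report An `ips_gap_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(report, path) {
  stopifnot(inherits(report, "ips_gap_report"))
  out <- unclass(report)
  out$cardinality <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Code-system deltas recorded for an IPS profile
#'
#' @param registry An `ips_gap_registry`.
#' @param ips_profile Profile name as listed in the registry.
#' @return data.frame of deltas (zero rows when none are recorded).
#' @export
code_system_delta <- function(registry, ips_profile) {
  stopifnot(inherits(registry, "ips_gap_registry"))
  if (!ips_profile %in% registry$components$ips_profile) {
    stop(sprintf("not-found: IPS profile '%s' is not in the registry", ips_profile),
         call. = FALSE)
  }
  registry$deltas[registry$deltas$ips_profile == ips_profile, , drop = FALSE]
}
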