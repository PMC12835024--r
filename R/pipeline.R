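# ETL orchestration: extract (read loose resource files and bundles) ->
# transform (four rule-sets) -> validate (two tiers) -> load (per-type
# NDJSON store with manifests and validation reports). Re-running with
# identical inputs and configuration reproduces an identical store.

#' Pipeline configuration
#'
#' @param input_paths Character vector of FHIR JSON files (single
#'   resources or Bundles).
#' @param output_dir Directory for the output store.
#' @param mode `"lenient"` (collect errors, summary decides the exit
#'   status) or `"strict"` (abort on the first error).
#' @param concept_map A `concept_map`, a CSV path, or `NULL` to disable
#'   EDI mapping. Defaults to the packaged EDI to SNOMED CT excerpt.
#' @param dedup Drop exact duplicates (same type, id and content hash)
#'   across input files; first occurrence wins.
#' @param gap_report Also write the IPS/KR Core gap report into the
#'   store.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_paths, output_dir,
                            mode = c("lenient", "strict"),
                            concept_map = default_edi_snomed_map(),
                            dedup = TRUE, gap_report = FALSE) {
  mode <- match.arg(mode)
  if (is.character(concept_map)) concept_map <- load_concept_map(concept_map)
  structure(list(input_paths = input_paths, output_dir = output_dir,
                 mode = mode, concept_map = concept_map, dedup = isTRUE(dedup),
                 gap_report = isTRUE(gap_report)),
            class = "pipeline_config")
}

# Extract stage: read every input; expand bundles; collect encounter
# periods (id -> period.start) for performedDateTime backfill.
.extract_stage <- function(input_paths) {
  resources <- list()
  encounter_periods <- list()
  for (path in input_paths) {
    r <- read_resource(path)
    batch <- if (identical(fhir_type(r), "Bundle")) bundle_entries(r) else list(r)
    for (entry in batch) {
      if (identical(fhir_type(entry), "Encounter")) {
        eid <- fhir_id(entry)
        start <- entry[["period"]][["start"]]
        if (non_empty_string(eid) && non_empty_string(start)) {
          encounter_periods[[eid]] <- start
        }
      }
      resources[[length(resources) + 1L]] <- entry
    }
  }
  list(resources = resources, encounter_periods = encounter_periods,
       n_files = length(input_paths))
}

.dedup_stage <- function(resources) {
  seen <- character()
  kept <- list()
  removed <- 0L
  for (r in resources) {
    key <- paste(fhir_type(r), fhir_id(r) %||% "",
                 md5_string(serialize_resource(r)), sep = "|")
    if (key %in% seen) {
      removed <- removed + 1L
      next
    }
    seen <- c(seen, key)
    kept[[length(kept) + 1L]] <- r
  }
  list(resources = kept, n_removed = removed)
}

#' Run the full extract-transform-validate-load pipeline
#'
#' Stage order is fixed. The load stage writes one NDJSON file per output
#' resource type plus `run-manifest.json`, `validation.json`
#' (OperationOutcome-shaped reports) and `transform-log.json`; a failed
#' run leaves a manifest with `"status": "FAILED"` rather than an
#' unlabelled partial store.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `etl_summary` with input/transform/validation
#'   counts and the written-file manifest.
#' @export
run_etl <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("I/O error: cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  manifest_path <- file.path(out_dir, "run-manifest.json")
  summary <- tryCatch(
    .run_etl_stages(config, out_dir),
    error = function(e) {
      jsonlite::write_json(
        list(status = "FAILED", error = conditionMessage(e)),
        manifest_path, auto_unbox = TRUE)
      stop(e)
    }
  )
  summary
}

.run_etl_stages <- function(config, out_dir) {
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  ex <- .extract_stage(config$input_paths)
  timings["extract"] <- toc(t0)

  n_dedup_removed <- 0L
  resources <- ex$resources
  if (config$dedup) {
    dd <- .dedup_stage(resources)
    resources <- dd$resources
    n_dedup_removed <- dd$n_removed
  }

  t0 <- tic()
  ctx <- transform_context(concept_map = config$concept_map, mode = config$mode,
                           encounter_periods = ex$encounter_periods)
  tr <- transform_all(resources, ctx)
  timings["transform"] <- toc(t0)
  if (identical(config$mode, "strict") && length(tr$failures)) {
    stop(sprintf("transform error(s): %s", paste(tr$failures, collapse = "; ")),
         call. = FALSE)
  }

  outputs <- lapply(tr$reports, function(r) r$output)
  t0 <- tic()
  vs <- validate_set(outputs, concept_map = config$concept_map)
  timings["validate"] <- toc(t0)
  if (identical(config$mode, "strict") && vs$n_error > 0L) {
    bad <- Filter(function(r) !r$valid, vs$reports)
    stop(sprintf("validation error(s) in %d resource(s), first: %s/%s",
                 length(bad), bad[[1]]$resource_type, bad[[1]]$resource_id),
         call. = FALSE)
  }

  t0 <- tic()
  types <- vapply(outputs, fhir_type, character(1))
  written <- character()
  for (tp in sort(unique(types))) {
    path <- file.path(out_dir, paste0(tp, ".ndjson"))
    write_ndjson(outputs[types == tp], path)
    written <- c(written, basename(path))
  }
  jsonlite::write_json(
    lapply(vs$reports, as_operation_outcome),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  written <- c(written, "validation.json")
  log_entries <- lapply(tr$reports, function(r) {
    list(input_id = r$input_id, input_type = r$input_type,
         output_type = fhir_type(r$output), output_id = fhir_id(r$output),
         warnings = r$warnings,
         actions = lapply(r$actions, function(a) {
           a[c("kind", "path", "detail")]
         }))
  })
  jsonlite::write_json(log_entries, file.path(out_dir, "transform-log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, "transform-log.json")
  if (config$gap_report) {
    write_gap_report(compute_gap_report(load_default_registry()),
                     file.path(out_dir, "gap-report.json"))
    written <- c(written, "gap-report.json")
  }
  timings["load"] <- toc(t0)

  n_by_type <- table(factor(types, levels = sort(unique(types))))
  file_manifest <- data.frame(
    file = written,
    md5 = vapply(written, function(f) md5_file(file.path(out_dir, f)),
                 character(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  summary <- structure(list(
    status = "OK",
    n_input_files = ex$n_files,
    n_resources = length(ex$resources),
    n_dedup_removed = n_dedup_removed,
    n_transformed = as.list(n_by_type),
    n_skipped = nrow(tr$skipped),
    n_transform_failures = length(tr$failures),
    transform_failures = tr$failures,
    n_valid = vs$n_valid,
    n_error = vs$n_error,
    n_warning = vs$n_warning,
    timings_sec = as.list(round(timings, 3)),
    files = file_manifest,
    output_dir = out_dir
  ), class = "etl_summary")

  jsonlite::write_json(
    c(unclass(summary)[c("status", "n_input_files", "n_resources",
                         "n_dedup_removed", "n_transformed", "n_skipped",
                         "n_transform_failures", "n_valid", "n_error",
                         "n_warning")],
      list(files = file_manifest)),
    file.path(out_dir, "run-manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows")
  summary
}

#' @export
print.etl_summary <- function(x, ...) {
  cat("ETL run summary\n")
  cat(sprintf("  status      : %s\n", x$status))
  cat(sprintf("  input files : %d (%d resources, %d duplicate(s) removed)\n",
              x$n_input_files, x$n_resources, x$n_dedup_removed))
  tr <- paste(sprintf("%s=%d", names(x$n_transformed),
                      unlist(x$n_transformed)), collapse = ", ")
  cat(sprintf("  transformed : %s (%d skipped, %d failure(s))\n",
              if (nzchar(tr)) tr else "none", x$n_skipped,
              x$n_transform_failures))
  cat(sprintf("  validation  : %d valid, %d error issue(s), %d warning(s)\n",
              x$n_valid, x$n_error, x$n_warning))
  cat(sprintf("  store       : %s\n", x$output_dir))
  invisible(x)
}

#' Suggested process exit code for an ETL summary
#'
#' 0 = success; 2 = validation errors survived a lenient run; 3 =
#' transform failures.
#'
#' @param summary An `etl_summary`.
#' @return Integer exit code.
#' @export
etl_exit_code <- function(summary) {
  if (summary$n_transform_failures > 0L) return(3L)
  if (summary$n_error > 0L) return(2L)
  0L
}
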