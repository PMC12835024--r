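# ipspipe

Korean personal health records are exported from the national "My Health
Record" platform as FHIR R4 JSON shaped by the KR Core profile set. The
International Patient Summary (IPS) — the minimal, border-crossing patient
summary standard — expects the same resources in a different shape:
flattened references instead of `contained` nesting, IPS canonical
profiles in `meta.profile`, and international terminology (SNOMED CT,
LOINC, ATC) where Korean exports carry domestic EDI claim codes, KCD
diagnosis codes, or systems literally labelled `"undefined"`.

`ipspipe` is a deterministic toolkit for that conversion, aimed at health
informatics engineers working with Korean FHIR data:

* **Gap registry** — a machine-readable encoding of the IPS component /
  profile inventory (3 required + 4 recommended components) and its
  mapping onto the KR Core profile set, with coverage statistics: a
  component counts as mapped iff at least one of its IPS profiles has a
  KR Core counterpart, and coverage is
  `round(100 * n_mapped / n_components)`.
* **Terminology** — canonicalization of code-system identifiers and strict
  ConceptMap-style lookup of EDI → SNOMED CT and KCD → SNOMED CT mappings
  (packaged as small synthetic excerpts modeled on the published HIRA and
  HINS tables). Codes are never inferred: a miss is surfaced, not guessed.
* **Transform engine** — four declarative rule-sets (Immunization,
  Medication, MedicationRequest, Procedure) that retain the IPS element
  set, flatten `contained` resources into `Type/id` references, stamp IPS
  profile URIs, default or map code systems, and generate XHTML
  narratives. Every transformer is a projection (`f(f(x)) == f(x)`) and
  logs every element it places, so the action log replays to the exact
  output.
* **Two-tier validator** — tier 1 checks FHIR R4 base structure (required
  elements, status value sets, date and reference lexical forms); tier 2
  checks IPS profile rules (profile URIs, empty `contained`, SNOMED-coded
  procedures with a populated `performedDateTime`, well-formed Medication
  narrative, ...). Referential-integrity checks are deliberately out of
  scope.
* **Synthetic generator** — a seedable source of messy exports reproducing
  the documented pathologies (`undefined` systems, redundant nested
  resources, missing performed dates, unmappable EDI codes), so the whole
  pipeline is testable without any real personal health data.
* **ETL pipeline** — extract → transform → validate → load into a per-type
  NDJSON store with manifests, exposed both as R functions and as a thin
  CLI (`inst/cli/ipspipe.R`).

## Worked example

An EDI-coded procedure with a nested patient is transformed through the
packaged mapping excerpt; the missing `performedDateTime` is backfilled
from the encounter period supplied in context:

```r
library(ipspipe)

proc <- fhir_resource(list(
  resourceType = "Procedure", id = "proc-1", status = "completed",
  code = list(coding = list(list(system = "EDI", code = "R4519",
                                 display = "Cesarean section"))),
  subject = list(reference = "#p1"),
  contained = list(list(resourceType = "Patient", id = "p1")),
  encounter = list(reference = "Encounter/enc-1")
))
ctx <- transform_context(
  encounter_periods = list("enc-1" = "2024-02-10T08:30:00+09:00"))
rep <- transform_procedure(proc, ctx)
cat(serialize_resource(rep$output, pretty = TRUE))
#> {
#>   "resourceType": "Procedure",
#>   "id": "proc-1",
#>   "status": "completed",
#>   "code": {
#>     "coding": [
#>       {
#>         "system": "http://snomed.info/sct",
#>         "code": "11466000",
#>         "display": "Cesarean section"
#>       }
#>     ],
#>     "text": "Cesarean section"
#>   },
#>   "subject": {
#>     "reference": "Patient/p1"
#>   },
#>   "performedDateTime": "2024-02-10T08:30:00+09:00"
#> }
validate_resource(rep$output)
#> <validation_report> Procedure/proc-1: valid (0 error, 0 warning)
```

The EDI claim code `R4519` was replaced by SNOMED CT `11466000` (cesarean
section) via exact lookup in the packaged excerpt, the nested patient was
flattened to `Patient/p1`, and the result passes both validation tiers.

The gap report prints the coverage statistics:

```r
compute_gap_report(load_default_registry())
#> IPS / KR Core gap report
#>   components mapped : 6 of 7 (86%)
#>   IPS profiles mapped: 7
#>   KR Core profiles referenced: 11
#>   NO MATCH:
#>     - MedicationStatement (IPS)
#>     - Device (IPS)
#>     - Device - performer or observer (IPS)
#>     - DeviceUseStatement (IPS)
#>   ...
```

A full synthetic run:

```r
src <- tempfile(); out <- tempfile()
m <- generate_cohort(clean_config(cohort_config(seed = 7)), src)
run_etl(pipeline_config(file.path(src, m$files$file), out))
#> ETL run summary
#>   status      : OK
#>   input files : 7 (12 resources, 0 duplicate(s) removed)
#>   transformed : Immunization=3, Medication=3, MedicationRequest=1, Procedure=2 (3 skipped, 0 failure(s))
#>   validation  : 9 valid, 0 error issue(s), 0 warning(s)
```

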