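---
title: "Transforming Korean PHR exports into the International Patient Summary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transforming Korean PHR exports into the International Patient Summary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipspipe)
```

## The problem

The Korean "My Health Record" ecosystem exports personal health data as
FHIR R4 JSON shaped by the KR Core national profiles. The International
Patient Summary (IPS) defines a minimal cross-border patient summary on
the same FHIR base, but its implementation guide constrains the
resources differently: references must be flat (`Patient/{id}`), not
nested `contained` structures; `meta.profile` must carry IPS canonical
URIs; and coding must use international terminologies — SNOMED CT for
procedures, LOINC for laboratory reports, ATC for drugs — where Korean
exports carry domestic EDI claim codes, KCD diagnosis codes, or code
systems labelled literally `"undefined"`.

`ipspipe` treats this as a deterministic data-engineering problem in
four parts: a **gap registry** quantifying how much of the IPS inventory
the KR Core can express, a **terminology** module for code-system
canonicalization and strict concept-map lookup, a **transform engine**
applying four declarative rule-sets, and a **two-tier validator**. A
**synthetic generator** supplies realistic messy inputs so every stage
is testable without personal health data.

## The gap registry and its coverage statistic

The registry is data, not code: three CSVs under
`extdata/registry/` list (1) the seven IPS components — three required
(Allergies and Intolerances; Medication Summary; Problems) and four
recommended (Results; History of Procedures; Immunizations; Medical
Devices) — with their eleven IPS profiles, (2) one row per IPS-profile /
KR-profile pair (an empty KR cell meaning NO MATCH), and (3) the
per-profile code-system deltas. Mapping cardinality is derived, never
stored: 0 KR profiles → `unmapped`, 1 → `one_to_one`, more →
`one_to_many`.

A component counts as *mapped* iff at least one of its profiles has at
least one KR Core mapping; coverage is

```
coverage_pct = round_half_away_from_zero(100 * n_components_mapped / n_components)
```

Half-away-from-zero rounding (not banker's rounding) is used so 6/7
prints as 86%. With the packaged registry, the Medication Summary
component counts as mapped through Medication and MedicationRequest even
though MedicationStatement has no KR counterpart; the Medical Devices
component is the one unmapped component. The registry encodes the
*eleven* KR Core profile names that the mapping enumeration actually
lists (two Condition profiles, four DiagnosticReport profiles, and one
each for AllergyIntolerance, Medication, MedicationRequest, Procedure,
Immunization); the report exposes every count as computed from the data
rather than as a constant, so an edited registry yields honestly
recomputed statistics.

```{r}
compute_gap_report(load_default_registry())
```

## Terminology

`canonicalize_system()` is a total function over a packaged alias table:
every raw string maps to a canonical URI or to the `UNKNOWN` marker
(never an error), with `"undefined"`, `"resource identifier
(undefined)"`, empty and absent values all collapsing to `UNKNOWN`.
Canonical URIs are fixed as `http://snomed.info/sct`,
`http://loinc.org`, `http://www.whocc.no/atc`,
`http://hl7.org/fhir/sid/icd-10-kr` for KCD, and —
because HIRA publishes no canonical URI for EDI claim codes —
the package-chosen placeholder `https://hira.or.kr/CodeSystem/edi`,
overridable through the alias table.

`map_code()` is a strict exact lookup on (source system, source code).
There is no fuzzy matching and no inference: a code either comes from
the official-style mapping table or is surfaced as unmatched. The
packaged EDI → SNOMED CT and KCD → SNOMED CT tables are small *synthetic
excerpts*: their EDI/KCD source codes are artifact-chosen placeholders
(no rows of the real 10,990-item HIRA or 14,402-item HINS tables are
redistributed), while the SNOMED CT targets are genuine concepts. One
excerpt row targets SNOMED CT 11466000 (cesarean section) and anchors
the worked example used throughout the tests; its EDI source code
`R4519` is likewise a documented placeholder.

## The transform rule-sets

The declarative part of each rule-set — retain/remove lists, profile
URIs, meta and code policies — ships as JSON under `extdata/rulesets/`;
the mechanics live in one function per rule-set. Common behaviour:

* outputs are built from scratch, so `contained` is always empty and
  nothing survives by accident;
* every element placed in the output is logged as one action carrying
  the placed value, so `replay_transform()` rebuilds the output from the
  log alone (tested as an invariant);
* each transformer is a projection: run on its own output it changes
  nothing, which is what makes re-running a pipeline safe.

Per rule-set:

* **Immunization** keeps status, vaccineCode, occurrenceDateTime,
  lotNumber, primarySource and protocolApplied (with targetDisease),
  stamps the IPS Immunization profile, drops versionId/lastUpdated, sets
  `meta.source` to `https://myhealthway.go.kr` (never a tag-like
  `#SystemGenerated` string), flattens patient and performer references,
  and removes encounter, location and note.
* **Medication** accepts a bare Medication or a MedicationDispense whose
  `contained` carries the Medication; Substance resources are removed
  from `contained`, identifiers keep their value but get a proper URL
  system, the drug code and ingredient systems are canonicalized to ATC,
  the dose form is SNOMED-coded, and a well-formed XHTML narrative with
  the drug name is generated when absent.
* **MedicationRequest** keeps status, intent, authoredOn and the
  medicationCodeableConcept verbatim (never converted to a
  medicationReference), stamps the IPS MedicationRequest profile,
  flattens the subject, reduces each dosageInstruction to text, timing,
  route (existing SNOMED CT coding untouched) and doseAndRate, and
  removes encounter, identifier, requester and reportedBoolean.
* **Procedure** retains resourceType, id, meta (reduced to versionId,
  lastUpdated, source), status, code and subject; the code is reduced to
  `coding[0]` (the literal first list element, no re-ranking), a missing
  or unusable system becomes SNOMED CT, an EDI code is replaced through
  the concept map, and `code.text` is set to the coding's display (or
  code when no display exists).

### Design choices where the rules were open

* **Undefined code systems.** The cleanup objective implies `"undefined"`
  systems must not survive transformation, but no rule says what to put
  there. Policy: each rule-set declares a `default_system` (ATC for drug
  and vaccine codes, SNOMED CT for dose forms and procedure codes) used
  only when the source system canonicalizes to `UNKNOWN`. The *code
  value* is never changed by this defaulting — codes change only through
  the concept map — so the no-invention property (every output code
  appears in the input or in the mapping table) holds by construction
  and is property-tested.
* **`performedDateTime` backfill.** Mandatory elements must be populated,
  but no source is named. Policy: use the procedure's own element if
  present, else the period start of the encounter it references (the
  pipeline collects encounter periods per input bundle), else fail in
  strict mode / flag in lenient mode. A date is never fabricated.
* **Strength "denominator as form".** The Medication rule's phrase is
  ambiguous between the denominator unit and the dose-form element.
  Implemented as: the denominator *unit string* is set from the
  dose-form display, and the change is flagged in the report warnings.
* **Extracted Medication id.** The contained id (stripped of `#`) is
  reused when present; otherwise a deterministic content-hash id
  (`med-` + truncated MD5 of the canonical JSON) keeps outputs
  reproducible.
* **`meta.source`.** Only the Immunization rule-set sets a fixed source
  URI; Procedure keeps the input's source via its meta keep-list, and
  MedicationRequest keeps a non-tag-like input source alongside the
  stamped profile. Each rule-set is followed literally rather than
  harmonized.
* **Duplicates.** Redundant copies of the same resource across input
  files are removed at the pipeline level by (type, id, content hash);
  the first occurrence wins and removals are counted in the summary.

## The two-tier validator

Tier 1 (`validate_syntax`) checks the FHIR R4 base structure: registered
resource type, required base elements per type, status value sets,
date/dateTime/instant lexical forms, and reference well-formedness,
including the `REF-INLINE` rule that flags a resource object embedded
inside a reference element (the "redundant nested resource" pathology).
Checks that a referenced target exists in some store are deliberately
excluded: a create-time server reassigns ids, so referential integrity
is not a property of the artifact being validated.

Tier 2 (`validate_ips_profile`) applies the IPS-level rules for the four
output profiles. The full catalogue, with each rule's tier, severity and
origin, is `ips_rule_catalogue()`; rules grounded directly in the IPS
transformation requirements are marked `ips-requirement`, conformance
checks added by this package `toolkit`. Severity policy: base-structure
violations and IPS must-have absences are errors; extra elements outside
a profile's expected set are warnings.

One scoping decision: the expected-profile-URI rule applies to
Immunization and MedicationRequest only. The Procedure rule-set's meta
keep-list (versionId, lastUpdated, source) stamps no profile URI, so
requiring one there would make the validator reject the very transform
it validates; Procedure conformance is checked through its SNOMED
coding, single-coding shape and `performedDateTime` instead, and
Medication through narrative and structural checks.

## The synthetic cohort

The generator emulates the study setting the toolkit is built for:
**three subjects**, each contributing one medication-record file
(MedicationDispense with contained Patient / Organization / Medication /
Substance) and one immunization file — six app-export files — plus **one
hospital "Medical MyData" bundle** (MedicationRequest, Procedure,
Patient, Organization, Encounter; EDI-coded procedures) for a single
designated subject, since only one study participant had retrievable
hospital records. App exports are written as loose resource files and
the hospital extract as a Bundle; the pipeline accepts both, since the
real export envelope is not fixed.

Four messiness knobs reproduce the documented pathologies, with defaults
`p_undefined_system = 1`, `p_redundant_nested = 1`,
`p_missing_performed_date = 0.5`, `p_unmapped_edi = 0`: the first two
pathologies were observed throughout the real exports, missing performed
dates occurred sporadically (0.5 makes both branches of the backfill
logic exercise under any seed), and unmappable codes are opt-in because
the packaged excerpt covers the generator's EDI pool by construction.
Each knob, enabled alone, flips exactly one documented validator rule
from pass to fail on raw data (`SYS-UNKNOWN`, `REF-INLINE`, `PROC-DATE`,
`TERM-UNMAPPED`), and transformation clears the issue — except unmapped
codes, which survive by design and keep the store honestly red. This
pathology-to-rule traceability is itself a test.

Determinism: each subject draws from its own seeded substream
(`seed * 1009 + k * 7919 mod 2^31 - 1`), so adding a subject never
perturbs earlier subjects' files, and identical configurations produce
byte-identical files — the ETL store is likewise byte-deterministic,
which the suite checks with file hashes.

What the cohort does *not* emulate: statistical realism of Korean
prescribing or immunization patterns, Korean-language text, volume (a
handful of resources, not an institutional export), AllergyIntolerance /
Condition / DiagnosticReport payloads (no transformation rule-sets exist
for them), or the full breadth of the real mapping tables. Green tests
on this cohort therefore demonstrate the mechanics of flattening,
mapping and validation — not that any particular real-world export will
map completely.

## Numerical and representational choices

* **Serialization** is deterministic: R4 definition order for known
  top-level elements, unknown elements appended in input order, fixed
  two-space indentation for files, one-line JSON for NDJSON stores.
  Unknown elements are preserved at parse time and removed only by
  explicit transform rules.
* **Dotted paths** address list entries by zero-based index
  (`code.coding.0.system`), matching the `coding[0]` convention in the
  rules.
* **Numbers** round-trip through R doubles; JSON is emitted with full
  precision (`digits = NA`). Insignificant decimal spellings (`1.50` vs
  `1.5`) are not preserved.
* **Degenerate inputs**: an empty registry is an explicit
  undefined-coverage error; an empty concept map loads and answers every
  lookup unmatched; an empty pipeline input set yields an all-zero
  summary and exit code 0; a failed run writes a `FAILED` marker into
  the store manifest rather than leaving it unlabelled.
* **Problem sizes** in the test suite are small by design — cohorts of
  one to four subjects, registries of a few components, a dozen
  randomized-registry draws per property — chosen to exercise every
  branch while keeping the suite fast.

## Limitations

* Profile-level, not element-level: the registry maps profile names, and
  the validator codifies a rule catalogue rather than evaluating real
  StructureDefinition / FHIRPath constraints.
* The packaged concept maps are excerpts; production use requires the
  full licensed HIRA/HINS tables in the same CSV schema.
* No XML serialization, no server interaction, no terminology-server
  binding validation, and no transformation of the profiles without
  rule-sets (they appear in the gap registry only).
* KCD → LOINC mapping for laboratory reports has no published table and
  is out of scope.
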