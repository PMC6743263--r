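---
title: "Managing clinical-trial imaging data: deidentification, QC, records, and export"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing clinical-trial imaging data: deidentification, QC, records, and export}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctimr)
```

`ctimr` implements the data-management core an imaging core lab needs to
run imaging endpoints in a multicenter trial: DICOM deidentification with
verifiable ground truth, protocol-conformance quality control, tamper-
evident records with electronic signatures and query management, and a
RECIST-based imaging eCRF exported in CDISC SDTM style. This vignette
explains the models and the decisions behind them; the README shows the
happy-path workflow.

## The DICOM model and its deliberate limits

All modules operate on a minimal in-memory model: a dataset is an ordered
map of attributes (tag → VR + value) plus an optional integer pixel
matrix and the group-0002 file-meta attributes; a series is an ordered
list of datasets sharing a Series Instance UID; a study set groups series
under one Study Instance UID.

File I/O is restricted to **uncompressed explicit-VR little-endian
Part 10** encoding. That restriction is a design choice, not an accident:
the blackout step must edit pixel values in place, which is only
well-defined on uncompressed data, and a single canonical transfer syntax
makes the read–write round trip exactly value-preserving (a property the
test suite checks across seeds, and cross-checks against an independent
Python DICOM reader). Sequences (SQ), multi-frame objects, and DICOM
networking are out of scope. Slices are ordered by the projection of
Image Position (Patient) onto the normal of Image Orientation (Patient),
with Instance Number as the tie-break; pixel indices are 1-based
inclusive `(row, column)`, the natural R convention, used consistently by
the generator, the blackout, and the verifier.

## Deidentification

### Action codes

The engine is rule-driven: one rule per tag, five actions.

* **D** replaces the value with the 9-character literal `"DE-IDENTI"` —
  exactly that string, deliberately not expanded to "DE-IDENTIFIED".
* **R** reduces a date. Two conventions circulate for this action: blank
  the date entirely, or keep the year and normalize month/day. The
  worked convention here is `YYYY0101` — the year survives, so age at
  scan remains computable and the value is still a valid DICOM DA string
  (an all-zero date like `"0000-0000"` is not); a `date_blank` profile
  flag selects full blanking where a trial demands it.
* **E** removes the element.
* **C** remaps a UID under the profile's `org_root`
  (default `1.2.410.200001`). New UIDs are a deterministic keyed hash of
  (org root, original UID): reruns reproduce the same map, the map is
  injective, and one shared map per study keeps every cross-reference
  consistent — in particular file-meta `(0002,0003)` always equals the
  remapped `(0008,0018)`. A UID already under the org root is left
  unchanged, which makes deidentification idempotent.
* **N** substitutes a trial-assigned context value. The default profile
  maps the patient-name rule to the patient alias (`patient01`), the
  patient-ID rule to the subject number (`Subject01`), and the study-ID
  rule to the project id (`Project01`).

The default profile ships sixteen rules covering the patient
name/ID/birth-date elements, other patient names/IDs, the patient and
institution addresses, institution name, referring/performing physicians,
accession number, study ID, and the four instance-hierarchy UIDs.

### Private elements and the residual scan

Vendor private elements (odd group numbers) can carry anything —
initials, phone numbers, national IDs — so the default policy is
conservative: private elements without an explicit rule are **removed**
(`default_private_action = "E"`, overridable per tag or set to `"keep"`).
Independently of the rules, `scan_for_phi()` sweeps every remaining
text-valued element for case-insensitive keywords (`name`, `birth`,
`patient`, `hosp`, `phone`, `tel`, `addr`, `physician`, `id`, plus an
institution list) and digit patterns (3-4-4 phone-style, 6–7 digit
national-ID-style, 8-digit date-like). Number patterns are not applied to
structural VRs (UI, DA, TM, DS, IS, US, UL): UIDs and date/numeric
elements are governed by per-tag rules, and flagging every UID digit run
would bury real findings in noise. Replacement values (`"DE-IDENTI"` and
the context values) are whitelisted by exact match. Findings are reports,
never errors — the scan is a detection aid, mirroring how upload staff
review flagged elements.

### Blackout and verification

Burned-in text is removed by filling rectangular regions with 0 (black
for the unsigned data this package writes) on every addressed slice; all
other pixels are bit-identical. Because the pixel content changes, each
modified dataset becomes a new DICOM object: it draws a fresh SOP
Instance UID from the study map (file meta follows). Optical character
recognition is out of scope — regions come from a predefined template or
from the fixture manifest, matching the semiautomatic workflow in which a
project predefines blackout regions for a known image format.

`verify_clean()` is the oracle the whole module is tested against: a
study is CLEAN iff no manifest token (and no original UID) occurs in any
attribute or file-meta value, and every manifest burned-in region is
fully zeroed. The acceptance suite additionally scans the raw output
bytes for every token, and checks that omitting any single rule or any
single region is detected.

## The synthetic-data generator

`fixture_spec()` describes a study the way a trial protocol would:
series/slice counts, modality, matrix, slice thickness, interslice gap,
pixel spacing, which PHI kinds to embed, burned-in regions, private
payloads, and a seed. Defaults are the worked CT conditions used
throughout: one 3-slice 512 × 512 CT series, 5 mm slices, 0 mm gap,
0.7 mm pixel spacing, all six PHI kinds, one burned-in band across the
image top. Generation is deterministic given the seed.

Two representation choices matter:

* **Thickness and gap are stored; positions are derived** (unless given
  explicitly). `perturb_protocol()` can therefore change exactly one
  acquisition parameter at a time — perturbing thickness with fixed
  positions would silently change the gap too, breaking one-factor QC
  tests.
* **Background noise is confined to 0–100**, so every other pixel byte is
  zero and no random pixel run can alias an ASCII PHI token during
  byte-level verification; the burned-in fill value 3000 encodes to
  non-alphanumeric bytes for the same reason. Birth dates are never drawn
  on January 1, whose year-preserving reduction would equal the original
  value and break token/replacement disjointness.

What the generator does **not** emulate: anatomy, realistic intensity
distributions, compressed transfer syntaxes, multi-frame objects, or
rendered text glyphs (burned-in "text" is a bright rectangle whose token
lives in the manifest). Passing the suite therefore demonstrates the
engine's contracts — rule coverage, referential integrity, byte-level
cleanliness, QC logic — on structurally faithful studies, not OCR
performance or robustness to malformed real-world encodings.

## Quality control

`derive_acquisition_params()` extracts per-series values and never
defaults silently: an absent element is `NA` and yields a `missing`
finding, treated as a failure for required rules (a Good-Clinical-
Practice bias toward flagging; both the policy and per-rule `optional`
are configurable). The interslice gap is defined as **mean spacing
between consecutive slice centers minus slice thickness**, using the
positions' projection on the slice normal, falling back to Spacing
Between Slices (0018,0088) − thickness when positions are absent; a
single-slice series has no measurable gap. Numeric equality comparisons
use an absolute tolerance of 1e-6, except the gap, which uses 1e-3 mm —
position strings round-trip through decimal text, and sub-micron
disagreement in a millimetre-scale quantity is measurement noise, not a
protocol deviation.

Rules are declarative (`parameter`, `eq`/`le`/`ge`/`in_set`, threshold,
units, optional) and serialize to YAML. The compiled quality assessment
report carries the quantitative findings, the four qualitative items
(artifacts, scan coverage, reconstruction, contrast enhancement — entry
restricted to QC-capable roles), the overall pass/fail (fail iff any
required finding or qualitative item fails), protocol deviations, and one
open corrective-action query per failing rule. It round-trips through
JSON and renders as plain text.

## Records: audit trail, signatures, queries, blinding

The audit trail is append-only and hash-chained: each record's SHA-256
digest covers sequence number, timestamp, editor, entity, action, old and
new values, reason, and the previous record's hash (genesis: 64 zeros).
Modify/delete events must carry a reason and always retain the old value.
`verify_chain()` recomputes everything; the suite tamper-tests every
field of every record across randomized logs. Timestamps are UTC ISO-8601
at seconds precision, injected through a clock function so tests are
deterministic. Electronic signatures bind printed name, meaning, and time
to a record's current hash; any later change invalidates them.
Authentication itself is stubbed behind the account object — password and
session management belong to a deployment, not to this library.

Queries implement CAPA in trial vocabulary: `system` or `clinical`
category, open → answered → closed with an escalation side-path, closed
queries immutable, closing reserved to project managers. Authorization is
checked before state (an unauthorized close reports an access error even
from an ineligible state). Alarms are realized as audit entries and CLI
notices; email delivery is out of scope.

Permissions are a pure function of (role, action, resource) over a
shipped role × action table, with three structural rules layered on top:
admin passes everything; central reviewers never read or write a peer
reviewer's measurements or forms (own records always allowed) — the
blinding that keeps independent reads independent; site CRCs are confined
to their own site. The master tracking report merges audit events, query
histories, signatures, and QC outcomes into one chronological table —
a pure function of its inputs, so regeneration is byte-identical.

## The imaging eCRF and export

Measurement math matches what an image viewer records: Euclidean distance
under anisotropic pixel spacing, shoelace polygon area scaled by row ×
column spacing (orientation-independent). `sum_of_diameters()` accepts
only target lesions and sums them.

`derive_response()` applies the published RECIST 1.1 thresholds, checked
in order: **PD** on any new lesion or growth from nadir of ≥ 20% *and*
≥ 5 mm; else **CR** when all targets have resolved and the sum is 0; else
**PR** on a ≥ 30% decrease from baseline; else **SD**; **NE** without an
evaluable baseline. Both percentage boundaries are inclusive ("at
least"). Nodal complete response is folded into the caller-supplied
`all_targets_resolved` flag rather than per-lesion short-axis tracking.
Growth from a nadir of 0 — reappearance after complete disappearance —
satisfies the percentage term by convention, so PD then turns on the 5 mm
absolute gain. The implementation is vectorized; the test suite checks it
against an independently written scalar oracle on the full integer grid
of (baseline, nadir, current) in 0–120 mm × both flags (≈ 7.1 million
cases, ~20 s), and the unit tests freeze the boundary cases.

Terminology mapping is an exact lookup after case/whitespace
normalization; unmapped terms become the explicit `UNCODED` marker, never
a silent pass-through. Export emits a minimal faithful subset of the SDTM
tumor domains — TU (one row per identified lesion), TR (one row per
measurement per visit, `LDIAM` in mm), RS (one row per timepoint
response, `OVRLRESP`) with fixed column sets (domain, subject, visit,
link id, test code, result, unit) — in deterministic (subject, visit,
lesion) order; export is blocked while any timepoint response is unsigned
(configurable). The full implementation-guide variable census and ADaM
analysis datasets are intentionally out of scope: the tabulation layer is
the deliverable.

## Interfaces and problem sizes

Profiles, protocols, and fixture specs are YAML; manifests, QC reports,
and deidentification reports are JSON; audit logs are JSON-lines; exports
are CSV. Result objects follow tidyverse conventions — tabular surfaces
are tibbles, fitted-object summaries come from `tidy()`/`glance()`, and
`autoplot()` gives quick-look figures — while the DICOM containers stay
plain hierarchical objects, which is what they are.

The shipped test suite validates at the defaults stated above: 20
end-to-end seeds at 512 × 512 × 3 slices for the cleanliness oracle, a
2-series × 10-slice study for referential integrity, 200 randomized logs
for tamper evidence, and the full 7.1-million-case RECIST grid — sizes
chosen so the whole suite documents the contracts in about a minute on
one core.

## Known limitations

* No OCR: burned-in text detection is template/manifest-driven.
* Explicit-VR little-endian only; no SQ, no multi-frame, no networking.
* The nonstandard-metadata repair some scanners require is unspecified
  upstream and deliberately absent here.
* Immune RECIST and Lugano response forms are not implemented.
* Re-identification key escrow (storing the UID map for authorized
  linkage) is left to the deploying organization.
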