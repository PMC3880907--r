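---
title: "Managing imaging studies with deterministic identifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing imaging studies with deterministic identifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicomvault)
```

## The problem

Longitudinal, multi-center MRI studies produce thousands of scanning
sessions, each a folder of hundreds of DICOM slice files, accompanied by
clinical, cognitive and genetic spreadsheets, and followed by waves of
derived results from versioned processing pipelines. Once files leave the
lab's directory conventions — downloaded, reprocessed, shared — their
identity is easily lost, results silently duplicate, and nobody can say
which pipeline release produced which volume table. dicomvault implements,
at desk scale, a data-management discipline that addresses this: every
managed entity (an *asset*) carries a deterministic 128-bit identifier
computed from its content or from the process that created it, raw data is
frozen into immutable checksummed archives, image extraction is gated on
acquisition-protocol compliance, and every derived asset is traceable back
to its original upload.

## Deterministic identifiers

An asset's identifier is a name-based UUID: the SHA-1 digest of a fixed
namespace UUID concatenated with a canonical key string, truncated to 128
bits with RFC-4122 version/variant bits forced (version 5). The canonical
key string joins the asset kind and its key components with an ASCII unit
separator; separator and escape characters inside components are escaped,
so distinct component lists can never collide after joining. Key
components are:

* **DICOM archives** — the sorted per-file md5 checksums. Identity is
  purely content-determined: folder layout, scan order and file names are
  irrelevant, and byte-identical uploads collide rather than duplicate.
* **Images** — the sorted md5s of the series' member files, with the same
  consequence: a series already extracted (from this archive or any other
  archive that contains a byte-identical copy) collides on re-extraction.
* **Output collections** — the activity name, version, parameter string
  and the sorted input identifiers. Sorting makes request order
  irrelevant; including the version means successive pipeline releases
  coexist; and re-requesting identical processing without removing
  previous results fails.

Two design points were genuinely open. First, the namespace constant is
project- and instance-independent, so archives migrate between stores
without re-identification; mixing a per-store identity into asset keys
would have broken migration for no benefit. Second, the activity
*parameter string* participates in output keys. Only name, version and
inputs are strictly necessary for versioning, but two instances of the
same release run with different parameter sets (say, field-strength
specific flags) on the same inputs would otherwise collide; we treat the
parameters as part of the process identity.

The rendering grammar is fixed: 32 lowercase hexadecimal digits in
8-4-4-4-12 groups, 36 characters total, and `duuid_parse()` inverts
`duuid_render()` exactly. The test-suite cross-checks the derivation
against an independent re-implementation built on a different crypto
library, and verifies zero collisions and byte-identical identifier sets
over repeated 10,000-key corpora.

## The archive format

`create_archive()` freezes one session folder into
`<id>.tar.gz` (POSIX tar, gzip) plus a JSON sidecar `<id>.json` whose
structural contract is published in
`inst/extdata/archive-descriptor.schema.json`. The descriptor carries
three metadata domains — the archive (identity, container checksum), its
series (echo time, repetition time, slice thickness in ms/ms/mm, field
strength in tesla, manufacturer, scanner serial, software version,
acquisition date, subject code), and every member file (member path, SOP
instance, instance number, md5). A conservation law ties the domains
together: series file counts must sum to the file-record count.

Choices worth recording: gzip was chosen as the codec because archive
identity is content-derived, not byte-derived — the codec is a storage
detail and may be recompressed without changing identity (the container
md5 is recorded separately and updated at creation only). DICOM `DA`
dates are normalized to ISO-8601 at descriptor build; missing numeric
headers are stored as absent, never zero. The `created` timestamp is
excluded from identity. Archives are immutable: extraction reads members
out without touching the container, and `verify_archive()` localizes any
corruption to the exact member file.

Because no DICOM toolkit ships with this stack, the package includes its
own minimal Part-10 codec restricted to Explicit VR Little Endian — the
dictionary of header attributes the archival layer documents, plus
uncompressed pixel data. It is deliberately not a general DICOM library
(no sequences, no other transfer syntaxes, no private-tag decoding);
unknown attributes are skipped on read and survive untouched inside
archived bytes. The generator's output is validated in the test-suite by
an independent strict third-party reader.

## De-identification gate and protocol gating

Header content of newly packaged data may contain protected health
information. `phi_scan()` reports every watchlisted attribute found
non-empty, per series; the default watchlist is PatientName,
OtherPatientIDs, InstitutionAddress and ReferringPhysicianName.
PatientID and PatientBirthDate are deliberately retained: study subject
codes are pseudonymous and the search interface filters on birth dates.
Assignment of an archive to a project is refused until a human confirms
anonymization (`confirm_anonymized()`); the scan informs that decision
but does not replace it.

Acquisition protocols are named constraint sets per project: closed
numeric intervals (after unit normalization to ms, mm, T), exact strings,
or allowed sets. There is no epsilon beyond the interval itself —
tolerance belongs in the range a project declares. A constrained
parameter missing from a series is a violation (strict-missing policy):
absence of evidence of compliance is non-compliance. New protocols start
inactive; `protocol_test()` is the validate-only dry run, and activation
enables `extract_images()`, which partitions every series of an archive
into exactly one image asset or one rejection record. Collisions are
checked for all compliant series before any write, so a failed extraction
leaves no partial state.

## Registry semantics

The registry is an embedded single-file transactional store (SQLite)
holding projects, timepoints, individuals, assets, asset files, series
metadata, ratings, scalar variables, resources and jobs. Its contracts:
store-wide identifier uniqueness (duplicate registration is always a
collision error, never an overwrite), referential integrity (assets
belong to existing project/individual/timepoint), and session gating
(searches and queries see only session-active projects). Authentication
and roles are out of scope — this is a single-user tool with the same
uniqueness semantics as a server deployment.

Search criteria are conjunctive `field:op:value` triples. The date
boundary conventions are declared, not inferred: "born prior to 1963"
means `date_of_birth < 1963-01-01`, "scanned after January 2006" means
`acquisition_date >= 2006-02-01` (strictly after the month), and
manufacturer matching is case-insensitive. An asset qualifies when one of
its series satisfies all series-level predicates simultaneously.

Quality ratings are multi-rater ordinal scores on a fixed 1–5 scale with
free-text notes; each rater's history is preserved and their latest score
flagged current. Download names follow the user's preference — plain
(`<id>.tar`), typed (`dicomArchive.<id>.tar`), or enriched via a token
template such as `DCM.<AcquisitionDate>.<PatientID>` resolved from the
asset's own headers.

## Scalar data at three levels

Spreadsheets import into named variable collections at a level inferred
from their key columns: `Project, Individual` (permanent traits),
`Project, Individual, TimePoint` (visit measures), or a single `UUID`
column (asset-attached measures — the asset already knows its project,
individual and timepoint). A sheet with both a UUID key and
individual/timepoint keys is ambiguous and rejected rather than guessed.
Import is an upsert: identical re-import is a no-op, and a conflicting
value for an existing key+field is a row error, never a silent
overwrite. Collections sharing a name (and hence field names) are
queryable across projects.

`query_scalars()` builds the wide table: one row per (individual,
timepoint) in scope regardless of which variables are requested
(row-count law), individual-level values repeated across an individual's
rows, asset-level values joined through the asset's assignment, missing
cells left missing. When several assets carry values for one session the
behaviour is explicit: `expand` emits one row per asset, `strict` errors.
The test-suite checks the output cell-by-cell against a brute-force
triple-loop join.

## Activities, jobs, provenance

Remote execution (schedulers, clusters, cloud machines) is replaced at
desk scale by two faithful mechanisms: the external-completion convention
— a job's result must be uploaded as `<output_id>.tar.gz`, anything else
is rejected and the job untouched — and a local subprocess executor for
tests and small runs. Output identifiers are computed at request time;
staging directories are named after them and populated with the input
files; and completing a job never changes its identifier (the registered
collection's id equals the id computed at request). Job states move only
along `pending → staged → running → {completed, failed}`.

Every output collection contains at least one item. Instances may declare
a stats member (a `key value` text file inside the collection); on
completion it is parsed into an asset-level variable collection named
`<activity>-<version>`, so pipeline measures become queryable alongside
clinical data with no schema work. The native stats dialect of any
particular pipeline is out of scope; the simple key/value format stands
in for it. `trace()` walks the provenance edges from any asset back to an
upload event — for a processed volume: collection ← image ← archive, with
the (name, version, parameters) triple attached to the producing link.
How multi-input activities should group assets per timepoint is not
well-defined in general; the package keeps one-job-per-asset as the
default and treats grouping as instance configuration, with no claim of
fidelity to any particular production system.

## The synthetic study generator

`generate_study()` emulates a multi-individual, multi-timepoint MRI study:
folder-per-session layout, valid Part-10 files, controllable header
fields, and a truth table (per-series headers, compliance flag, per-file
md5s) that downstream tests treat as their only oracle. Defaults were
chosen once as the reference conditions: 4 individuals × 2 timepoints ×
2 series per session × 3 slices (a T1 gradient-echo template at
TE 3.2 ms / TR 7.1 ms / 1.2 mm and a T2 TSE template at TE 90 ms /
TR 3000 ms / 3 mm), scanners cycled across three manufacturers with
realistic serial/software strings, birth years 1935–1975, acquisition
dates 2005–2010, and a 0.25 violation rate that pushes a quarter of T1
series out of the embedded protocol's echo-time range so rejection paths
are exercised. Pixel payloads are 16×16 16-bit gradients plus
seed-hashed low-amplitude noise — tiny, byte-deterministic given the
seed, and compressible enough to exercise the lossless codec. All UIDs
derive under a reserved private root so synthetic data can never collide
with real studies, and no identity-bearing value reads the wall clock.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: realistic anatomy or noise statistics,
vendor private tags, implicit-VR or compressed transfer syntaxes, the
data-dependent compression ratios of clinical MRI, multi-frame or
non-MR modalities, and header pathologies of real scanner exports
(missing UIDs, inconsistent dates). The management contracts
(identity, immutability, gating, provenance) are what the fixtures
validate; robustness to arbitrary real-world DICOM is not claimed.

## Problem sizes and numerical choices

The test-suite and the acceptance script run entirely on generated
fixtures: the 16-series reference study for archival and gating, a
10-archive single-timepoint cohort for search semantics, a 6-row
three-individual cohort for the join oracle, 10,000-key corpora (twice)
for collision and stability checks, and two pipeline versions over one
image for provenance. These sizes were chosen to exercise every contract
with seconds-scale runs; all counts scale linearly if larger fixtures are
wanted. Numeric protocol comparisons are exact closed-interval checks on
double-precision values after unit normalization; md5 and SHA-1 are used
as integrity and identity digests respectively, not for security.

## Known limitations

* The identifier recipe is a documented, portable reconstruction of the
  deterministic-identifier idea; it is not wire-compatible with any
  production system's unpublished hashing.
* The DICOM codec reads what it writes (Explicit VR LE and a fixed
  dictionary); archiving arbitrary clinical exports would require a full
  toolkit behind the same descriptor interface.
* One registry handle per process; concurrent multi-user access is out of
  scope, as are networking, authentication and streaming download.
* Image-format conversion (NIfTI and friends) is deliberately absent;
  extracted image assets stay DICOM.
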