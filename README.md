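# dicomvault

Desk-scale management of DICOM imaging studies with deterministic asset
identifiers.

Longitudinal and multi-center MRI studies accumulate thousands of scanning
sessions — each a folder of DICOM slice files — alongside clinical and
cognitive spreadsheets and waves of derived results from versioned
processing pipelines. dicomvault is for researchers and data managers who
need that material organized, checksummed, and traceable without running a
server: it freezes raw sessions into immutable single-file archives,
validates acquisitions against per-project protocols before extracting
image assets, integrates scalar variables at three attachment levels into
one queryable table, and tracks every processing job so any derived file
can be traced back to its original upload.

## The core model

Every managed entity (*asset*) carries a deterministic universally unique
identifier (dUUID): a 128-bit name-based UUID

```
id = truncate128( SHA-1( namespace ∥ canonical_key ) )   [version/variant bits forced]
```

where the canonical key is derived from what the asset *is* or the process
that made it:

| asset kind        | key components                                            |
|-------------------|-----------------------------------------------------------|
| `dicomArchive`    | sorted md5 checksums of every member DICOM file           |
| `image`           | sorted md5 checksums of the series' files                 |
| `outputCollection`| activity name, version, parameters, sorted input dUUIDs   |

Identity is therefore content- and process-determined: byte-identical data
or an identical processing request always maps to the same identifier, so
accidental duplication surfaces as a hard *collision error* instead of a
silent copy, and a new pipeline version (whose version string is part of
the key) coexists with the old one. Identifiers render canonically as 36
characters — 32 lowercase hex digits in 8-4-4-4-12 groups, e.g.
`6d0b1c00-2a11-4aaa-a337-3ba06e9ee2ef`.

Around that core: archives carry a three-domain JSON descriptor (archive /
series / files, with md5s at every level and a published schema in
`inst/extdata/archive-descriptor.schema.json`); archives must be confirmed
anonymized (after a PHI header scan) before project assignment; protocol
gating rejects series whose echo time, repetition time or slice thickness
fall outside the project's declared closed intervals; and a seedable
synthetic DICOM study generator makes the whole system testable with no
external data.

## Worked example

Generate a synthetic 4-individual × 2-timepoint study, archive a session,
register it, and extract protocol-compliant images:

```r
library(dicomvault)

study <- generate_study(study_spec(seed = 7), file.path(tempdir(), "study"))
study$series[1:4, c("individual", "timepoint", "description",
                    "echo_time", "manufacturer", "compliant")]
#> # A tibble: 4 × 6
#>   individual timepoint description echo_time manufacturer       compliant
#>   <chr>      <chr>     <chr>           <dbl> <chr>              <lgl>
#> 1 S001       M00       T1 MPRAGE         3.2 GE MEDICAL SYSTEMS TRUE
#> 2 S001       M00       T2 TSE           90   GE MEDICAL SYSTEMS FALSE
#> 3 S001       M12       T1 MPRAGE         3.2 GE MEDICAL SYSTEMS TRUE
#> 4 S001       M12       T2 TSE           90   GE MEDICAL SYSTEMS FALSE

out <- create_archive(unique(study$series$session_dir)[1],
                      file.path(tempdir(), "archives"))
out$descriptor$archive_id
#> [1] "71d1fb84-bee3-51b4-bc05-a5995efe35a7"
verify_archive(out$archive)
#> <verification> archive 71d1fb84-bee3-51b4-bc05-a5995efe35a7: container ok, 6/6 members ok

reg <- registry_open()
project_create(reg, "synth", timepoints = c("M00", "M12"))
inds <- unique(study$series[, c("individual", "gender", "patient_birth_date")])
register_individuals(reg, data.frame(Project = "synth", SiteId = inds$individual,
                                     Gender = inds$gender,
                                     DateOfBirth = inds$patient_birth_date))
#> <individual import> 4 new, 0 existing, 0 row error(s)

assign_archive(reg, confirm_anonymized(out$descriptor), out$archive,
               project = "synth", individual = "S001", timepoint = "M00")
res <- extract_images(reg, out$archive,
                      protocol_activate(default_t1_protocol("synth")))
nrow(res$assets); nrow(res$rejections)
#> [1] 1
#> [1] 1
```

The session held two series; the T1 acquisition (TE 3.2 ms, inside the
protocol's [3.0, 3.5] ms gate) became an image asset, the T2 acquisition
was rejected. Re-running `extract_images()` on the same archive raises a
collision error rather than duplicating the asset. Download names follow
user preference:

```r
download_name("6d0b1c00-2a11-4aaa-a337-3ba06e9ee2ef", "dicomArchive", "tar", "typed")
#> [1] "dicomArchive.6d0b1c00-2a11-4aaa-a337-3ba06e9ee2ef.tar"
```

From there, `import_table()` attaches spreadsheets at individual,
timepoint or asset level; `query_scalars()` builds the cross-level wide
table; `request_jobs()` / `run_local()` / `complete_job()` run versioned
activities with precomputed output identifiers; and `trace()` walks any
result back to its source archive. The methods vignette
(`vignettes/dicomvault-methods.Rmd`) documents the model, the design
decisions and their rationale.

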