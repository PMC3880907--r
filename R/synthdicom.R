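#' Synthetic DICOM study generator
#'
#' Seedable generator of small, fully valid Part-10 DICOM studies with
#' controllable header fields, so archival, protocol gating, search, and
#' querying can be exercised without downloading any data. Alongside the
#' files it emits a machine-readable truth table (one row per series plus a
#' per-file table with md5 checksums and an intended protocol-compliance
#' flag) which downstream tests treat as the sole oracle.
#'
#' Pixel payloads are 16x16 16-bit gradients plus seed-hashed low-amplitude
#' noise: tiny, deterministic, and compressible. All UIDs are derived under
#' a reserved private root so synthetic data can never collide with real
#' studies, and no identity-bearing value consults the wall clock.
#'
#' @name synthdicom
NULL

# run expr under a temporary RNG state; global stream untouched
.local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic sub-seed (< 2^28) from string parts
.sub_seed <- function(...) {
  strtoi(substr(digest::digest(paste(..., sep = "/"), algo = "sha1",
                               serialize = FALSE), 1, 7), 16L)
}

#' Describe one series to generate
#'
#' Defaults describe a 3 T T1-weighted ultrafast gradient-echo volume; pass
#' `manufacturer = NULL` to let the study spec cycle scanners across
#' individuals.
#'
#' @param modality DICOM modality (default `"MR"`).
#' @param description Series description / image type hint.
#' @param echo_time,repetition_time Echo / repetition time in ms.
#' @param slice_thickness Slice thickness in mm.
#' @param manufacturer Scanner manufacturer, or `NULL` to inherit the study
#'   cycle.
#' @param scanner_serial,software_version Device provenance strings (`NULL`
#'   to inherit per-scanner defaults).
#' @param field_strength Main field in tesla.
#' @param n_slices Number of slices (files) in the series, >= 1.
#' @return A `series_template`.
#' @export
series_template <- function(modality = "MR", description = "T1 MPRAGE",
                            echo_time = 3.2, repetition_time = 7.1,
                            slice_thickness = 1.2, manufacturer = NULL,
                            scanner_serial = NULL, software_version = NULL,
                            field_strength = 3.0, n_slices = 3L) {
  if (!is.numeric(n_slices) || n_slices < 1L) {
    stop("n_slices must be >= 1", call. = FALSE)
  }
  structure(list(modality = modality, description = description,
                 echo_time = echo_time, repetition_time = repetition_time,
                 slice_thickness = slice_thickness, manufacturer = manufacturer,
                 scanner_serial = scanner_serial, software_version = software_version,
                 field_strength = field_strength, n_slices = as.integer(n_slices)),
            class = "series_template")
}

.scanner_defaults <- list(
  "GE MEDICAL SYSTEMS" = list(serial = "GE-00001", software = "DV24.0"),
  "SIEMENS"            = list(serial = "SIE-41002", software = "syngo MR B17"),
  "Philips"            = list(serial = "PH-77231", software = "5.1.7")
)

#' Default protocol embedded in generated studies
#'
#' T1 gradient-echo gate: TE in \[3.0, 3.5\] ms, TR in \[6.0, 8.0\] ms,
#' slice thickness in \[1.0, 1.5\] mm, modality MR. The generator computes
#' each series' compliance flag against this (or a caller-supplied) protocol.
#'
#' @param project Project name the protocol is defined for.
#' @return A `protocol_definition` (inactive; activate before extraction).
#' @export
default_t1_protocol <- function(project = "synth") {
  protocol_define(
    name = "T1-3T", project = project, image_type = "T1",
    constraints = list(
      modality = constraint_exact("MR"),
      echo_time = constraint_range(3.0, 3.5, "ms"),
      repetition_time = constraint_range(6.0, 8.0, "ms"),
      slice_thickness = constraint_range(1.0, 1.5, "mm")
    )
  )
}

#' Specify a synthetic multi-individual, multi-timepoint study
#'
#' Defaults give the reference fixture used throughout the test-suite:
#' 4 individuals x 2 timepoints x 2 series per session (a compliant T1
#' template and a T2 template that the embedded T1 protocol rejects),
#' 3 slices per series, scanners cycled across GE / SIEMENS / Philips,
#' births 1935--1975, acquisitions 2005--2010.
#'
#' @param project Project name.
#' @param n_individuals Number of individuals, >= 1.
#' @param timepoints Character vector of visit labels.
#' @param templates List of [series_template()]s acquired at every session.
#' @param birth_year_range Inclusive integer range of birth years.
#' @param acq_date_range Inclusive ISO-date range of acquisition dates.
#' @param manufacturers Scanner cycle for templates without a fixed
#'   manufacturer.
#' @param protocol Protocol used to compute truth-table compliance flags.
#' @param violation_rate Fraction of otherwise-compliant T1 series whose
#'   echo time is pushed out of protocol range, to exercise rejection paths.
#' @param phi Named list of PHI header values to plant (e.g.
#'   `list(PatientName = "DOE^JANE")`); empty by default (anonymized).
#' @param seed Integer seed; every byte of the output is a function of it.
#' @return A `study_spec`.
#' @export
study_spec <- function(project = "synth", n_individuals = 4L,
                       timepoints = c("M00", "M12"),
                       templates = list(series_template(),
                                        series_template(description = "T2 TSE",
                                                        echo_time = 90,
                                                        repetition_time = 3000,
                                                        slice_thickness = 3.0)),
                       birth_year_range = c(1935L, 1975L),
                       acq_date_range = c("2005-01-01", "2010-12-31"),
                       manufacturers = names(.scanner_defaults),
                       protocol = default_t1_protocol(project),
                       violation_rate = 0.25,
                       phi = list(),
                       seed = 1L) {
  if (n_individuals < 1L || length(timepoints) < 1L || length(templates) < 1L) {
    stop("invalid study spec: all counts must be >= 1", call. = FALSE)
  }
  if (diff(as.integer(birth_year_range)) < 0L ||
      as.Date(acq_date_range[2]) < as.Date(acq_date_range[1])) {
    stop("invalid study spec: empty demographic span", call. = FALSE)
  }
  ok <- vapply(templates, inherits, logical(1), "series_template")
  if (!all(ok)) stop("templates must be series_template objects", call. = FALSE)
  structure(list(project = project, n_individuals = as.integer(n_individuals),
                 timepoints = timepoints, templates = templates,
                 birth_year_range = as.integer(birth_year_range),
                 acq_date_range = acq_date_range, manufacturers = manufacturers,
                 protocol = protocol, violation_rate = violation_rate,
                 phi = phi, seed = as.integer(seed)),
            class = "study_spec")
}

.pixel_payload <- function(seed_key, rows = 16L, cols = 16L) {
  base <- as.integer(outer(seq_len(rows) - 1L, seq_len(cols) - 1L, `+`)) * 128L
  noise <- .local_seed(.sub_seed("pixels", seed_key),
                       sample.int(256L, rows * cols, replace = TRUE) - 1L)
  writeBin(base + noise, raw(), size = 2L, endian = "little")
}

#' Generate one DICOM series into a folder
#'
#' @param template A [series_template()].
#' @param seed Integer seed; identical seeds give byte-identical folders.
#' @param out_dir Folder to write into (created if needed).
#' @param patient_id,patient_birth_date,patient_sex Subject headers.
#' @param acquisition_date ISO acquisition date.
#' @param study_uid Study instance UID (derived from the seed if `NULL`).
#' @param series_index Index used in UID derivation, letting several series
#'   share a study.
#' @param extra_elements Named list of additional header values planted in
#'   every slice (e.g. PHI tags for scan tests).
#' @return Tibble with one row per written file: `path`, `sop_instance_uid`,
#'   `instance_number`, `md5`, `series_uid`.
#' @export
generate_series <- function(template, seed, out_dir,
                            patient_id = "SYN001",
                            patient_birth_date = "1960-01-01",
                            patient_sex = "F",
                            acquisition_date = "2006-03-15",
                            study_uid = NULL, series_index = 1L,
                            extra_elements = list()) {
  stopifnot(inherits(template, "series_template"))
  if (template$n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manufacturer <- template$manufacturer %||% "GE MEDICAL SYSTEMS"
  defaults <- .scanner_defaults[[manufacturer]] %||% list(serial = "GEN-0001", software = "1.0")
  serial <- template$scanner_serial %||% defaults$serial
  software <- template$software_version %||% defaults$software

  study_uid <- study_uid %||% dicom_uid("study", seed, patient_id)
  series_uid <- dicom_uid("series", seed, patient_id, series_index)

  rows <- purrr::map(seq_len(template$n_slices), function(i) {
    sop_uid <- dicom_uid("sop", seed, patient_id, series_index, i)
    elements <- c(list(
      SOPClassUID = SOP_CLASS_MR,
      SOPInstanceUID = sop_uid,
      AcquisitionDate = .iso_to_da(acquisition_date),
      Modality = template$modality,
      Manufacturer = manufacturer,
      SeriesDescription = template$description,
      PatientID = patient_id,
      PatientBirthDate = .iso_to_da(patient_birth_date),
      PatientSex = patient_sex,
      SliceThickness = template$slice_thickness,
      RepetitionTime = template$repetition_time,
      EchoTime = template$echo_time,
      MagneticFieldStrength = template$field_strength,
      DeviceSerialNumber = serial,
      SoftwareVersions = software,
      StudyInstanceUID = study_uid,
      SeriesInstanceUID = series_uid,
      InstanceNumber = i,
      SamplesPerPixel = 1L,
      PhotometricInterpretation = "MONOCHROME2",
      Rows = 16L, Columns = 16L,
      BitsAllocated = 16L, BitsStored = 16L, HighBit = 15L,
      PixelRepresentation = 0L,
      PixelData = .pixel_payload(paste(seed, patient_id, series_index, i))
    ), extra_elements)
    elements <- elements[!duplicated(names(elements), fromLast = TRUE)]
    path <- file.path(out_dir, sprintf("%s.%04d.dcm", tolower(template$modality), i))
    write_dicom(path, elements)
    tibble::tibble(path = path, sop_instance_uid = sop_uid, instance_number = i,
                   md5 = unname(tools::md5sum(path)), series_uid = series_uid)
  })
  dplyr::bind_rows(rows)
}

# compliance check done inline (plain comparisons) so the truth table stays
# an oracle independent of validate_series()
.truth_compliant <- function(values, protocol) {
  if (is.null(protocol)) return(NA)
  all(vapply(names(protocol$constraints), function(p) {
    .constraint_holds(protocol$constraints[[p]], values[[p]])
  }, logical(1)))
}

#' Generate a full synthetic study with its truth table
#'
#' Writes a folder-per-session layout
#' `out_dir/<individual>/<timepoint>/<series_k>/*.dcm` and returns the truth
#' table that downstream tests use as their only oracle.
#'
#' @param spec A [study_spec()].
#' @param out_dir Root folder to populate.
#' @return A `synth_study`: list with `root`, `series` (one row per series:
#'   all planted header values, `session_dir`, `file_count`, `compliant`),
#'   `files` (per-file md5s), and `spec`.
#' @export
generate_study <- function(spec, out_dir) {
  stopifnot(inherits(spec, "study_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  demo <- .local_seed(.sub_seed("demographics", spec$seed), {
    years <- sample(seq(spec$birth_year_range[1], spec$birth_year_range[2]),
                    spec$n_individuals, replace = TRUE)
    months <- sample.int(12L, spec$n_individuals, replace = TRUE)
    days <- sample.int(28L, spec$n_individuals, replace = TRUE)
    sexes <- sample(c("F", "M"), spec$n_individuals, replace = TRUE)
    list(dob = sprintf("%04d-%02d-%02d", years, months, days), sex = sexes)
  })
  date_span <- seq(as.Date(spec$acq_date_range[1]), as.Date(spec$acq_date_range[2]), by = "day")
  n_sessions <- spec$n_individuals * length(spec$timepoints)
  acq_dates <- .local_seed(.sub_seed("acqdates", spec$seed),
                           format(sample(date_span, n_sessions, replace = TRUE)))
  violated <- .local_seed(
    .sub_seed("violations", spec$seed),
    stats::runif(n_sessions * length(spec$templates)) < spec$violation_rate
  )

  series_rows <- list()
  file_rows <- list()
  k <- 0L
  session <- 0L
  for (i in seq_len(spec$n_individuals)) {
    sid <- sprintf("S%03d", i)
    manufacturer <- spec$manufacturers[(i - 1L) %% length(spec$manufacturers) + 1L]
    for (tp in spec$timepoints) {
      session <- session + 1L
      session_dir <- file.path(out_dir, sid, tp)
      for (j in seq_along(spec$templates)) {
        k <- k + 1L
        tmpl <- spec$templates[[j]]
        if (is.null(tmpl$manufacturer)) tmpl$manufacturer <- manufacturer
        if (violated[k]) {
          # push an otherwise-constrained parameter out of range
          tmpl$echo_time <- tmpl$echo_time + 100
        }
        sdir <- file.path(session_dir, sprintf("series_%d", j))
        files <- generate_series(
          tmpl, seed = spec$seed, out_dir = sdir,
          patient_id = sid, patient_birth_date = demo$dob[i],
          patient_sex = demo$sex[i], acquisition_date = acq_dates[session],
          study_uid = dicom_uid("study", spec$seed, sid, tp),
          series_index = .sub_seed("seriesidx", spec$seed, sid, tp, j),
          extra_elements = spec$phi
        )
        values <- list(modality = tmpl$modality, echo_time = tmpl$echo_time,
                       repetition_time = tmpl$repetition_time,
                       slice_thickness = tmpl$slice_thickness,
                       manufacturer = tmpl$manufacturer,
                       field_strength = tmpl$field_strength)
        series_rows[[k]] <- tibble::tibble(
          project = spec$project, individual = sid, timepoint = tp,
          session_dir = session_dir, series_uid = files$series_uid[1],
          modality = tmpl$modality, description = tmpl$description,
          echo_time = tmpl$echo_time, repetition_time = tmpl$repetition_time,
          slice_thickness = tmpl$slice_thickness,
          manufacturer = tmpl$manufacturer,
          scanner_serial = tmpl$scanner_serial %||%
            (.scanner_defaults[[tmpl$manufacturer]] %||% list(serial = "GEN-0001"))$serial,
          software_version = tmpl$software_version %||%
            (.scanner_defaults[[tmpl$manufacturer]] %||% list(software = "1.0"))$software,
          field_strength = tmpl$field_strength,
          acquisition_date = acq_dates[session],
          patient_id = sid, patient_birth_date = demo$dob[i], gender = demo$sex[i],
          file_count = nrow(files),
          compliant = isTRUE(.truth_compliant(values, spec$protocol))
        )
        file_rows[[k]] <- files
      }
    }
  }
  structure(list(root = out_dir,
                 series = dplyr::bind_rows(series_rows),
                 files = dplyr::bind_rows(file_rows),
                 spec = spec),
            class = "synth_study")
}

#' Write a study's truth table to CSV + JSON
#' @param study A `synth_study`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_truth_table <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "truth.series.csv")
  p2 <- file.path(dir, "truth.files.csv")
  p3 <- file.path(dir, "truth.json")
  utils::write.csv(study$series, p1, row.names = FALSE)
  utils::write.csv(study$files, p2, row.names = FALSE)
  jsonlite::write_json(list(series = study$series, files = study$files), p3,
                       dataframe = "rows", digits = NA)
  invisible(c(p1, p2, p3))
}
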