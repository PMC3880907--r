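#' Immutable single-file DICOM archives
#'
#' A DICOM archive packages one session folder of DICOM files into a single
#' losslessly compressed container (`<id>.tar.gz`) plus a JSON sidecar
#' descriptor (`<id>.json`). The descriptor carries three metadata domains:
#' the archive itself (identity, checksum), the series it contains
#' (acquisition parameters and scanner provenance), and every single file
#' (member path, SOP instance, md5). The archive identifier is derived from
#' the sorted per-file checksums, so byte-identical content always yields
#' the identical archive regardless of folder layout or scan order, and
#' archives migrate between stores without re-identification. Once created,
#' archives are immutable: series are extracted without modifying the
#' container.
#'
#' @name dicom_archive
NULL

DESCRIPTOR_FORMAT_VERSION <- "1.0"

#' Default PHI watchlist
#'
#' Header attributes whose non-empty presence blocks project assignment
#' until anonymization is confirmed. PatientID and PatientBirthDate are
#' retained deliberately: search filters use birth dates and the study's own
#' pseudonymous subject codes.
#'
#' @return Character vector of DICOM keywords.
#' @export
default_phi_watchlist <- function() {
  c("PatientName", "OtherPatientIDs", "InstitutionAddress", "ReferringPhysicianName")
}

.list_dicom_candidates <- function(folder) {
  files <- list.files(folder, recursive = TRUE, full.names = TRUE, all.files = FALSE)
  files[!file.info(files)$isdir]
}

.na_scalar <- function(x, as = "character") {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))) {
    return(if (as == "numeric") NA_real_ else NA_character_)
  }
  if (as == "numeric") as.numeric(x[1]) else as.character(x[1])
}

#' Build the three-domain descriptor for a folder of DICOM files
#'
#' Reads every DICOM file under `folder` (recursively), computes per-file
#' md5 checksums, groups files into series, and derives the archive
#' identifier from the sorted checksums. `anonymized_confirmed` starts
#' `FALSE`: data cannot be assigned to a project until a human confirms
#' anonymization.
#'
#' @param folder Folder containing at least one DICOM Part-10 file.
#' @param strict If `TRUE` (default), any non-DICOM file in the folder is an
#'   error naming the file; if `FALSE`, such files are skipped.
#' @param project,individual,timepoint Optional assignment carried in the
#'   descriptor for later registration (used by manifest batches).
#' @return An `archive_descriptor`.
#' @export
build_descriptor <- function(folder, strict = TRUE,
                             project = NA_character_, individual = NA_character_,
                             timepoint = NA_character_) {
  if (!dir.exists(folder)) stop(sprintf("folder '%s' does not exist", folder), call. = FALSE)
  candidates <- .list_dicom_candidates(folder)
  if (length(candidates) == 0L) {
    stop(sprintf("folder '%s' contains no files", folder), call. = FALSE)
  }
  is_dcm <- vapply(candidates, is_dicom_file, logical(1))
  if (strict && any(!is_dcm)) {
    stop("not parseable as DICOM: ", paste(candidates[!is_dcm], collapse = ", "),
         call. = FALSE)
  }
  files <- candidates[is_dcm]
  if (length(files) == 0L) {
    stop(sprintf("folder '%s' contains no parseable DICOM files", folder), call. = FALSE)
  }

  headers <- purrr::map(files, read_dicom)
  md5s <- unname(tools::md5sum(files))
  series_uid <- vapply(headers, function(h) .na_scalar(h$SeriesInstanceUID), character(1))
  if (anyNA(series_uid)) {
    stop("DICOM file(s) without SeriesInstanceUID: ",
         paste(files[is.na(series_uid)], collapse = ", "), call. = FALSE)
  }

  member <- file.path("series", series_uid, basename(files))
  # disambiguate duplicate basenames within a series
  dup <- duplicated(member)
  while (any(dup)) {
    member[dup] <- sub("(\\.[^.]*)?$", "_\\0", member[dup])
    dup <- duplicated(member)
  }

  file_tbl <- tibble::tibble(
    member_path = member,
    sop_instance_uid = vapply(headers, function(h) .na_scalar(h$SOPInstanceUID), character(1)),
    instance_number = vapply(headers, function(h) as.integer(.na_scalar(h$InstanceNumber, "numeric")), integer(1)),
    md5 = md5s,
    series_uid = series_uid,
    source_path = files
  )
  file_tbl <- dplyr::arrange(file_tbl, .data$series_uid, .data$instance_number,
                             .data$member_path)

  series_tbl <- dplyr::bind_rows(purrr::map(split(seq_along(files), series_uid), function(ix) {
    h <- headers[[ix[1]]]
    tibble::tibble(
      series_uid = .na_scalar(h$SeriesInstanceUID),
      modality = .na_scalar(h$Modality),
      description = .na_scalar(h$SeriesDescription),
      echo_time = .na_scalar(h$EchoTime, "numeric"),
      repetition_time = .na_scalar(h$RepetitionTime, "numeric"),
      slice_thickness = .na_scalar(h$SliceThickness, "numeric"),
      manufacturer = .na_scalar(h$Manufacturer),
      scanner_serial = .na_scalar(h$DeviceSerialNumber),
      software_version = .na_scalar(h$SoftwareVersions),
      field_strength = .na_scalar(h$MagneticFieldStrength, "numeric"),
      acquisition_date = .da_to_iso(.na_scalar(h$AcquisitionDate)),
      patient_id = .na_scalar(h$PatientID),
      patient_birth_date = .da_to_iso(.na_scalar(h$PatientBirthDate)),
      file_count = length(ix)
    )
  }))
  series_tbl <- dplyr::arrange(series_tbl, .data$series_uid)

  archive_id <- derive_id(asset_key("dicomArchive", sort(file_tbl$md5)))
  structure(list(
    archive_id = as.character(archive_id),
    archive_md5 = NA_character_,
    format_version = DESCRIPTOR_FORMAT_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    anonymized_confirmed = FALSE,
    project = project, individual = individual, timepoint = timepoint,
    series = series_tbl,
    files = file_tbl
  ), class = "archive_descriptor")
}

#' Structural validation of a descriptor
#'
#' Checks the contract published in
#' `system.file("extdata", "archive-descriptor.schema.json", package = "dicomvault")`:
#' required fields present and well-typed, a supported `format_version`, a
#' canonical `archive_id`, and the conservation law (sum of series file
#' counts equals the number of file records).
#'
#' @param descriptor An `archive_descriptor` or a list read from JSON.
#' @return `TRUE`, invisibly; otherwise an error describing the defect.
#' @export
descriptor_validate <- function(descriptor) {
  d <- descriptor
  required <- c("archive_id", "format_version", "anonymized_confirmed", "series", "files")
  missing <- setdiff(required, names(d))
  if (length(missing)) stop("descriptor missing field(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  if (!identical(as.character(d$format_version), DESCRIPTOR_FORMAT_VERSION)) {
    stop(sprintf("unsupported descriptor format_version '%s'", d$format_version),
         call. = FALSE)
  }
  if (!is_duuid(d$archive_id)) stop("archive_id is not a canonical identifier", call. = FALSE)
  series <- tibble::as_tibble(d$series)
  files <- tibble::as_tibble(d$files)
  need_s <- c("series_uid", "file_count")
  need_f <- c("member_path", "md5", "series_uid")
  if (!all(need_s %in% names(series))) stop("descriptor series domain incomplete", call. = FALSE)
  if (!all(need_f %in% names(files))) stop("descriptor file domain incomplete", call. = FALSE)
  if (sum(series$file_count) != nrow(files)) {
    stop("descriptor violates conservation: sum(series$file_count) != nrow(files)",
         call. = FALSE)
  }
  if (anyDuplicated(files$member_path)) stop("duplicate member_path in descriptor", call. = FALSE)
  if (!all(grepl("^[0-9a-f]{32}$", files$md5))) stop("malformed md5 in file domain", call. = FALSE)
  invisible(TRUE)
}

#' Write / read the JSON sidecar descriptor
#'
#' @param descriptor An `archive_descriptor`.
#' @param path JSON file path.
#' @return `descriptor_write()`: `path`, invisibly. `descriptor_read()`: the
#'   validated `archive_descriptor`.
#' @export
descriptor_write <- function(descriptor, path) {
  stopifnot(inherits(descriptor, "archive_descriptor"))
  d <- unclass(descriptor)
  d$files <- dplyr::select(d$files, -dplyr::any_of("source_path"))
  jsonlite::write_json(d, path, dataframe = "rows", auto_unbox = TRUE,
                       na = "null", null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname descriptor_write
#' @export
descriptor_read <- function(path) {
  if (!file.exists(path)) stop(sprintf("descriptor '%s' not found", path), call. = FALSE)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$series <- tibble::as_tibble(d$series)
  d$files <- tibble::as_tibble(d$files)
  for (f in c("project", "individual", "timepoint")) d[[f]] <- d[[f]] %||% NA_character_
  d <- structure(d, class = "archive_descriptor")
  descriptor_validate(d)
  d
}

#' Confirm that an archive's headers are anonymized
#'
#' Flips the human-confirmation flag required before the archive can be
#' assigned to a project. Typically preceded by [phi_scan()].
#'
#' @param descriptor An `archive_descriptor`.
#' @param path Optional sidecar path to rewrite with the flag set.
#' @return The updated descriptor.
#' @export
confirm_anonymized <- function(descriptor, path = NULL) {
  stopifnot(inherits(descriptor, "archive_descriptor"))
  descriptor$anonymized_confirmed <- TRUE
  if (!is.null(path)) descriptor_write(descriptor, path)
  descriptor
}

.sidecar_path <- function(archive) sub("\\.tar\\.gz$", ".json", archive)

#' Create an immutable archive from a folder
#'
#' Packages the folder as `<id>.tar.gz` (POSIX tar, gzip) with members
#' stored under `series/<series_uid>/<filename>`, plus the `<id>.json`
#' sidecar. The container md5 is recorded in the descriptor. The archive is
#' treated as immutable from here on.
#'
#' @param folder Source folder of DICOM files.
#' @param target Writable target directory.
#' @inheritParams build_descriptor
#' @return List with `archive` (container path), `descriptor_path`, and
#'   `descriptor`.
#' @export
create_archive <- function(folder, target, strict = TRUE,
                           project = NA_character_, individual = NA_character_,
                           timepoint = NA_character_) {
  desc <- build_descriptor(folder, strict = strict, project = project,
                           individual = individual, timepoint = timepoint)
  if (!dir.exists(target)) dir.create(target, recursive = TRUE, showWarnings = FALSE)
  if (file.access(target, mode = 2L) != 0L) {
    stop(sprintf("target '%s' is not writable", target), call. = FALSE)
  }
  archive_path <- file.path(target, paste0(desc$archive_id, ".tar.gz"))
  if (file.exists(archive_path)) {
    stop(sprintf("collision: archive %s already exists in '%s'", desc$archive_id, target),
         call. = FALSE)
  }

  staging <- tempfile("dvstage")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  for (i in seq_len(nrow(desc$files))) {
    dest <- file.path(staging, desc$files$member_path[i])
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(desc$files$source_path[i], dest)
  }
  old <- setwd(staging)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(archive_path, files = "series", compression = "gzip", tar = "internal")
  setwd(old)

  desc$archive_md5 <- unname(tools::md5sum(archive_path))
  descriptor_path <- .sidecar_path(archive_path)
  descriptor_write(desc, descriptor_path)
  list(archive = archive_path, descriptor_path = descriptor_path, descriptor = desc)
}

#' Extract one series from an archive without touching it
#'
#' @param archive Path to the `<id>.tar.gz` container (sidecar `<id>.json`
#'   expected next to it unless `descriptor` is given).
#' @param series_uid Series to extract.
#' @param target Directory to write the member files into.
#' @param descriptor Optional pre-loaded `archive_descriptor`.
#' @return Character vector of extracted file paths (under
#'   `target/series/<series_uid>/`).
#' @export
extract_series <- function(archive, series_uid, target, descriptor = NULL) {
  desc <- descriptor %||% descriptor_read(.sidecar_path(archive))
  if (!series_uid %in% desc$series$series_uid) {
    stop(sprintf("series '%s' not present in archive %s", series_uid, desc$archive_id),
         call. = FALSE)
  }
  members <- desc$files$member_path[desc$files$series_uid == series_uid]
  dir.create(target, recursive = TRUE, showWarnings = FALSE)
  utils::untar(archive, files = members, exdir = target, tar = "internal")
  out <- file.path(target, members)
  missing <- out[!file.exists(out)]
  if (length(missing)) stop("extraction incomplete: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  out
}

#' Verify an archive against its descriptor
#'
#' Checks the container md5 and every member file's md5 against the stored
#' records.
#'
#' @inheritParams extract_series
#' @return A `verification_report`: list with `archive_id`, `archive_ok`,
#'   `all_ok`, and a `files` tibble (member_path, expected, actual, ok).
#' @export
verify_archive <- function(archive, descriptor = NULL) {
  desc <- descriptor %||% descriptor_read(.sidecar_path(archive))
  archive_ok <- identical(unname(tools::md5sum(archive)), desc$archive_md5)
  work <- tempfile("dvverify")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE))
  utils::untar(archive, exdir = work, tar = "internal")
  actual <- unname(tools::md5sum(file.path(work, desc$files$member_path)))
  files <- tibble::tibble(
    member_path = desc$files$member_path,
    expected = desc$files$md5,
    actual = actual,
    ok = !is.na(actual) & actual == desc$files$md5
  )
  structure(list(archive_id = desc$archive_id, archive_ok = archive_ok,
                 all_ok = archive_ok && all(files$ok), files = files),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification> archive %s: container %s, %d/%d members ok\n",
              x$archive_id, if (x$archive_ok) "ok" else "FAILED",
              sum(x$files$ok), nrow(x$files)))
  invisible(x)
}

#' Plan archive creation from a batch manifest
#'
#' The manifest is a CSV with columns `Project`, `Individual`, `TimePoint`,
#' `SourceLocation`, `TargetLocation` — one archive-creation job per row.
#' Planning and execution need no live registry connection; the resulting
#' descriptors carry each row's assignment for later registration.
#'
#' @param manifest Path to the manifest CSV, or a data frame.
#' @return Tibble of job specs (one per row).
#' @export
batch_from_manifest <- function(manifest) {
  tbl <- if (is.data.frame(manifest)) manifest
         else utils::read.csv(manifest, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("Project", "Individual", "TimePoint", "SourceLocation", "TargetLocation")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("manifest missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tbl[required])
}

#' Execute archive-creation job specs
#'
#' Rows whose `SourceLocation` is missing or fails to package are recorded
#' as failures; the batch continues.
#'
#' @param specs Tibble from [batch_from_manifest()].
#' @param strict Passed to [build_descriptor()].
#' @return Tibble with one row per spec: the spec columns plus `status`
#'   (`"ok"`/`"failed"`), `archive_id`, `archive`, `descriptor_path`,
#'   `error`.
#' @export
run_archive_jobs <- function(specs, strict = TRUE) {
  rows <- purrr::map(seq_len(nrow(specs)), function(i) {
    row <- specs[i, ]
    res <- tryCatch({
      out <- create_archive(row$SourceLocation, row$TargetLocation, strict = strict,
                            project = row$Project, individual = row$Individual,
                            timepoint = row$TimePoint)
      tibble::tibble(status = "ok", archive_id = out$descriptor$archive_id,
                     archive = out$archive, descriptor_path = out$descriptor_path,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(status = "failed", archive_id = NA_character_,
                     archive = NA_character_, descriptor_path = NA_character_,
                     error = conditionMessage(e))
    })
    dplyr::bind_cols(row, res)
  })
  dplyr::bind_rows(rows)
}

#' Scan DICOM headers for protected health information
#'
#' Reads every DICOM file in a folder (or inside an archive) and reports, per
#' series, each watchlisted attribute found non-empty. The report supports
#' the human anonymization confirmation; it does not modify any data.
#'
#' @param x A folder of DICOM files or a `<id>.tar.gz` archive path.
#' @param watchlist Character vector of DICOM keywords to flag; defaults to
#'   [default_phi_watchlist()]. Must be non-empty.
#' @return A `phi_report` tibble: one row per (series_uid, tag) found
#'   non-empty, with `value` and `n_files`; zero rows mean a clean scan.
#' @export
phi_scan <- function(x, watchlist = default_phi_watchlist()) {
  if (length(watchlist) == 0L || !is.character(watchlist)) {
    stop("PHI watchlist must be a non-empty character vector", call. = FALSE)
  }
  folder <- x
  if (!dir.exists(x) && file.exists(x) && grepl("\\.tar\\.gz$", x)) {
    folder <- tempfile("dvphi")
    dir.create(folder)
    on.exit(unlink(folder, recursive = TRUE))
    utils::untar(x, exdir = folder, tar = "internal")
  }
  files <- .list_dicom_candidates(folder)
  files <- files[vapply(files, is_dicom_file, logical(1))]
  if (length(files) == 0L) stop("nothing to scan: no DICOM files found", call. = FALSE)
  hits <- purrr::map(files, function(f) {
    h <- read_dicom(f)
    uid <- .na_scalar(h$SeriesInstanceUID)
    found <- purrr::keep(watchlist, function(tag) {
      v <- h[[tag]]
      !is.null(v) && length(v) > 0L && any(nzchar(trimws(as.character(v))))
    })
    if (length(found) == 0L) return(NULL)
    tibble::tibble(series_uid = uid, tag = found,
                   value = vapply(found, function(tag) as.character(h[[tag]][1]), character(1)))
  })
  report <- dplyr::bind_rows(hits)
  if (nrow(report) == 0L) {
    report <- tibble::tibble(series_uid = character(), tag = character(),
                             value = character(), n_files = integer())
  } else {
    report <- dplyr::summarise(dplyr::group_by(report, .data$series_uid, .data$tag),
                               value = .data$value[1], n_files = dplyr::n(),
                               .groups = "drop")
  }
  class(report) <- c("phi_report", class(report))
  report
}
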