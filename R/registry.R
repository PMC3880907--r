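#' The asset registry
#'
#' A transactional, single-file embedded store (SQLite) of projects,
#' individuals, timepoints, assets, asset files, ratings, scalar variables,
#' resources and jobs. It enforces the contracts the rest of the system
#' relies on: store-wide identifier uniqueness (duplicate registration is a
#' collision error, never an overwrite), referential integrity (every asset
#' belongs to an existing project, individual and timepoint), and session
#' gating (queries only see projects activated in the current session).
#' Authentication is out of scope: this is a single-user desk-scale store
#' with the same uniqueness semantics as its server-scale counterpart.
#'
#' @name registry
NULL

.reg_schema <- c(
  "CREATE TABLE IF NOT EXISTS projects (
     name TEXT PRIMARY KEY, active INTEGER NOT NULL DEFAULT 1,
     default_formats TEXT)",
  "CREATE TABLE IF NOT EXISTS timepoints (
     project TEXT NOT NULL, label TEXT NOT NULL, position INTEGER,
     UNIQUE(project, label))",
  "CREATE TABLE IF NOT EXISTS individuals (
     project TEXT NOT NULL, site_id TEXT NOT NULL, gender TEXT,
     date_of_birth TEXT, UNIQUE(project, site_id))",
  "CREATE TABLE IF NOT EXISTS assets (
     id TEXT PRIMARY KEY, kind TEXT NOT NULL, project TEXT, individual TEXT,
     timepoint TEXT, md5 TEXT, provenance_type TEXT, provenance_ref TEXT,
     registered_at TEXT)",
  "CREATE TABLE IF NOT EXISTS asset_files (
     asset_id TEXT NOT NULL, location TEXT NOT NULL, format TEXT, md5 TEXT)",
  "CREATE TABLE IF NOT EXISTS archive_series (
     asset_id TEXT NOT NULL, series_uid TEXT NOT NULL, modality TEXT,
     description TEXT, echo_time REAL, repetition_time REAL,
     slice_thickness REAL, manufacturer TEXT, scanner_serial TEXT,
     software_version TEXT, field_strength REAL, acquisition_date TEXT,
     patient_id TEXT, patient_birth_date TEXT, file_count INTEGER)",
  "CREATE TABLE IF NOT EXISTS ratings (
     asset_id TEXT NOT NULL, rater TEXT NOT NULL, score INTEGER NOT NULL,
     note TEXT, timestamp TEXT, current INTEGER NOT NULL DEFAULT 1)",
  "CREATE TABLE IF NOT EXISTS collections (
     name TEXT PRIMARY KEY, level TEXT NOT NULL, fields TEXT NOT NULL)",
  "CREATE TABLE IF NOT EXISTS scalars (
     collection TEXT NOT NULL, project TEXT, individual TEXT, timepoint TEXT,
     asset_id TEXT, field TEXT NOT NULL, value TEXT,
     UNIQUE(collection, project, individual, timepoint, asset_id, field))",
  "CREATE TABLE IF NOT EXISTS resources (
     name TEXT PRIMARY KEY, host TEXT, purpose TEXT NOT NULL,
     input_path TEXT, output_path TEXT, owner TEXT)",
  "CREATE TABLE IF NOT EXISTS instances (
     activity_name TEXT NOT NULL, version TEXT NOT NULL, parameters TEXT NOT NULL,
     resource TEXT NOT NULL, projects TEXT NOT NULL, group_by TEXT,
     stats_member TEXT, UNIQUE(activity_name, version, parameters))",
  "CREATE TABLE IF NOT EXISTS jobs (
     output_id TEXT PRIMARY KEY, activity_name TEXT, version TEXT,
     parameters TEXT, input_ids TEXT, resource TEXT, state TEXT NOT NULL,
     project TEXT, individual TEXT, timepoint TEXT, created_at TEXT,
     finished_at TEXT, exit_code INTEGER, log TEXT, staging_dir TEXT)",
  "CREATE TABLE IF NOT EXISTS provenance (
     asset_id TEXT NOT NULL, parent_id TEXT, activity_name TEXT,
     version TEXT, parameters TEXT)"
)

#' Open (or create) a registry
#'
#' @param path Path of the single-file store; `":memory:"` (default) keeps
#'   everything in RAM for the current session.
#' @return A `dv_registry` handle.
#' @export
registry_open <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  for (sql in .reg_schema) DBI::dbExecute(con, sql)
  structure(list(con = con, path = path), class = "dv_registry")
}

#' Close a registry handle
#' @param reg A `dv_registry`.
#' @return `NULL`, invisibly.
#' @export
registry_close <- function(reg) {
  stopifnot(inherits(reg, "dv_registry"))
  DBI::dbDisconnect(reg$con)
  invisible(NULL)
}

.reg <- function(reg) {
  if (!inherits(reg, "dv_registry")) stop("not a registry handle", call. = FALSE)
  reg$con
}

.q <- function(reg, sql, params = NULL) {
  if (!is.null(params)) params <- unname(as.list(params))
  tibble::as_tibble(DBI::dbGetQuery(.reg(reg), sql, params = params))
}

.x <- function(reg, sql, params = NULL) {
  if (!is.null(params)) params <- unname(as.list(params))
  DBI::dbExecute(.reg(reg), sql, params = params)
}

#' @export
print.dv_registry <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM assets")$n
  cat(sprintf("<registry> %s (%d assets)\n", x$path, n))
  invisible(x)
}

#' Create a project with its timepoint labels
#'
#' @param reg A `dv_registry`.
#' @param name Unique project name.
#' @param timepoints Ordered character vector of visit labels (must be
#'   unique within the project).
#' @param formats Default image formats generated at extraction.
#' @param activate Activate the project in this session (default `TRUE`).
#' @return `reg`, invisibly.
#' @export
project_create <- function(reg, name, timepoints = character(),
                           formats = "dicom", activate = TRUE) {
  if (anyDuplicated(timepoints)) stop("timepoint labels must be unique within a project",
                                      call. = FALSE)
  if (nrow(.q(reg, "SELECT 1 FROM projects WHERE name = ?", list(name)))) {
    stop(sprintf("project '%s' already exists", name), call. = FALSE)
  }
  .x(reg, "INSERT INTO projects (name, active, default_formats) VALUES (?, ?, ?)",
     list(name, as.integer(activate), paste(formats, collapse = ",")))
  for (i in seq_along(timepoints)) {
    .x(reg, "INSERT INTO timepoints (project, label, position) VALUES (?, ?, ?)",
       list(name, timepoints[i], i))
  }
  invisible(reg)
}

#' Activate / deactivate projects in the current session
#'
#' Only assets of active projects are visible to searches and queries; a
#' user authorized for many projects works with just those of current
#' interest.
#'
#' @param reg A `dv_registry`.
#' @param name Project name.
#' @return `reg`, invisibly.
#' @export
project_activate <- function(reg, name) {
  n <- .x(reg, "UPDATE projects SET active = 1 WHERE name = ?", list(name))
  if (n == 0L) stop(sprintf("unknown project '%s'", name), call. = FALSE)
  invisible(reg)
}

#' @rdname project_activate
#' @export
project_deactivate <- function(reg, name) {
  n <- .x(reg, "UPDATE projects SET active = 0 WHERE name = ?", list(name))
  if (n == 0L) stop(sprintf("unknown project '%s'", name), call. = FALSE)
  invisible(reg)
}

#' @rdname project_activate
#' @export
active_projects <- function(reg) {
  .q(reg, "SELECT name FROM projects WHERE active = 1 ORDER BY name")$name
}

project_timepoints <- function(reg, project) {
  .q(reg, "SELECT label FROM timepoints WHERE project = ? ORDER BY position",
     list(project))$label
}

#' Import an individual list
#'
#' Upserts individuals from a CSV (or data frame) with columns `Project`
#' (or an explicit `project` argument, or a `<project>.individuals.list.csv`
#' file-naming convention) and `SiteId`; `Gender` and `DateOfBirth` are
#' optional. Idempotent on (project, site_id): re-importing the identical
#' file registers nothing new. Rows without a SiteId are collected as
#' row-level errors, not fatal.
#'
#' @param reg A `dv_registry`.
#' @param table CSV path or data frame.
#' @param project Project override; if `NULL`, taken from the `Project`
#'   column or the file name.
#' @return An `individual_import_report`: list with `new`, `existing`, and
#'   an `errors` tibble.
#' @export
register_individuals <- function(reg, table, project = NULL) {
  from_file <- is.character(table) && length(table) == 1L
  tbl <- if (from_file) utils::read.csv(table, stringsAsFactors = FALSE,
                                        colClasses = "character")
         else as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(project) && !"Project" %in% names(tbl) && from_file) {
    # convention: <project>.individuals.list.csv
    m <- regmatches(basename(table), regexec("^([^.]+)\\.individuals\\.list\\.csv$",
                                             basename(table)))[[1]]
    if (length(m) == 2L) project <- m[2]
  }
  if (!"SiteId" %in% names(tbl)) stop("individual list must have a SiteId column", call. = FALSE)
  if (is.null(project) && !"Project" %in% names(tbl)) {
    stop("no project: provide a Project column, a project argument, or name the file <project>.individuals.list.csv",
         call. = FALSE)
  }

  new <- 0L; existing <- 0L
  errors <- list()
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, , drop = FALSE]
    proj <- project %||% row$Project
    sid <- trimws(row$SiteId %||% "")
    if (is.na(sid) || !nzchar(sid)) {
      errors[[length(errors) + 1L]] <- tibble::tibble(row = i, error = "missing SiteId")
      next
    }
    if (!nrow(.q(reg, "SELECT 1 FROM projects WHERE name = ?", list(proj)))) {
      errors[[length(errors) + 1L]] <- tibble::tibble(row = i,
                                                      error = sprintf("unknown project '%s'", proj))
      next
    }
    hit <- .q(reg, "SELECT 1 FROM individuals WHERE project = ? AND site_id = ?",
              list(proj, sid))
    if (nrow(hit)) {
      existing <- existing + 1L
      next
    }
    .x(reg, "INSERT INTO individuals (project, site_id, gender, date_of_birth) VALUES (?, ?, ?, ?)",
       list(proj, sid, row$Gender %||% NA_character_, row$DateOfBirth %||% NA_character_))
    new <- new + 1L
  }
  structure(list(new = new, existing = existing,
                 errors = if (length(errors)) dplyr::bind_rows(errors)
                          else tibble::tibble(row = integer(), error = character())),
            class = "individual_import_report")
}

#' @export
print.individual_import_report <- function(x, ...) {
  cat(sprintf("<individual import> %d new, %d existing, %d row error(s)\n",
              x$new, x$existing, nrow(x$errors)))
  invisible(x)
}

asset_exists <- function(reg, id) {
  nrow(.q(reg, "SELECT 1 FROM assets WHERE id = ?", list(as.character(id)))) > 0L
}

#' Register an asset
#'
#' Atomic insert of an asset record with its files, series metadata and
#' provenance edges. A duplicate identifier is a collision error — nothing
#' is overwritten and no partial rows are left behind.
#'
#' @param reg A `dv_registry`.
#' @param id The asset's deterministic identifier (canonical string).
#' @param kind Registered asset kind.
#' @param project,individual,timepoint Assignment (checked for referential
#'   integrity when non-`NA`).
#' @param md5 Content checksum of the asset's primary file.
#' @param provenance_type `"upload"` or `"job"`.
#' @param provenance_ref Upload note or producing job identifier.
#' @param files Optional tibble (`location`, `format`, `md5`).
#' @param series Optional tibble of series metadata rows to attach.
#' @param parents Optional tibble of provenance edges (`parent_id`,
#'   `activity_name`, `version`, `parameters`).
#' @return The canonical id, invisibly.
#' @export
register_asset <- function(reg, id, kind, project = NA, individual = NA,
                           timepoint = NA, md5 = NA, provenance_type = "upload",
                           provenance_ref = NA, files = NULL, series = NULL,
                           parents = NULL) {
  id <- as.character(id)
  if (!is_duuid(id)) stop("asset id is not a canonical identifier", call. = FALSE)
  con <- .reg(reg)
  DBI::dbWithTransaction(con, {
    if (asset_exists(reg, id)) {
      stop(sprintf("collision: asset %s is already registered", id), call. = FALSE)
    }
    if (!is.na(project)) {
      if (!nrow(.q(reg, "SELECT 1 FROM projects WHERE name = ?", list(project)))) {
        stop(sprintf("unknown project '%s'", project), call. = FALSE)
      }
      if (!is.na(individual) &&
          !nrow(.q(reg, "SELECT 1 FROM individuals WHERE project = ? AND site_id = ?",
                   list(project, individual)))) {
        stop(sprintf("unknown individual '%s' in project '%s'", individual, project),
             call. = FALSE)
      }
      if (!is.na(timepoint) &&
          !nrow(.q(reg, "SELECT 1 FROM timepoints WHERE project = ? AND label = ?",
                   list(project, timepoint)))) {
        stop(sprintf("unknown timepoint '%s' in project '%s'", timepoint, project),
             call. = FALSE)
      }
    }
    .x(reg, "INSERT INTO assets (id, kind, project, individual, timepoint, md5,
              provenance_type, provenance_ref, registered_at)
             VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?)",
       list(id, kind, project, individual, timepoint, md5, provenance_type,
            provenance_ref, format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
    if (!is.null(files)) {
      for (i in seq_len(nrow(files))) {
        .x(reg, "INSERT INTO asset_files (asset_id, location, format, md5) VALUES (?, ?, ?, ?)",
           list(id, files$location[i], files$format[i], files$md5[i]))
      }
    }
    if (!is.null(series)) {
      cols <- c("series_uid", "modality", "description", "echo_time",
                "repetition_time", "slice_thickness", "manufacturer",
                "scanner_serial", "software_version", "field_strength",
                "acquisition_date", "patient_id", "patient_birth_date", "file_count")
      for (i in seq_len(nrow(series))) {
        vals <- lapply(cols, function(cl) if (cl %in% names(series)) series[[cl]][i] else NA)
        .x(reg, sprintf("INSERT INTO archive_series (asset_id, %s) VALUES (%s)",
                        paste(cols, collapse = ", "),
                        paste(rep("?", length(cols) + 1L), collapse = ", ")),
           c(list(id), vals))
      }
    }
    if (!is.null(parents)) {
      for (i in seq_len(nrow(parents))) {
        .x(reg, "INSERT INTO provenance (asset_id, parent_id, activity_name, version, parameters)
                 VALUES (?, ?, ?, ?, ?)",
           list(id, parents$parent_id[i], parents$activity_name[i],
                parents$version[i], parents$parameters[i]))
      }
    } else if (identical(provenance_type, "upload")) {
      .x(reg, "INSERT INTO provenance (asset_id, parent_id, activity_name, version, parameters)
               VALUES (?, NULL, 'upload', NULL, NULL)", list(id))
    }
  })
  invisible(structure(id, class = "duuid"))
}

#' Fetch one asset record
#' @param reg A `dv_registry`.
#' @param id Asset identifier.
#' @return One-row tibble, or an error for an unknown id.
#' @export
asset_get <- function(reg, id) {
  out <- .q(reg, "SELECT * FROM assets WHERE id = ?", list(as.character(id)))
  if (nrow(out) == 0L) stop(sprintf("unknown asset %s", id), call. = FALSE)
  out
}

#' List assets of the session-active projects
#' @param reg A `dv_registry`.
#' @param project Optional project filter.
#' @return Tibble of asset records.
#' @export
list_assets <- function(reg, project = NULL) {
  sql <- "SELECT a.* FROM assets a JOIN projects p ON a.project = p.name WHERE p.active = 1"
  if (!is.null(project)) {
    return(.q(reg, paste(sql, "AND a.project = ?"), list(project)))
  }
  .q(reg, sql)
}

#' Assign a confirmed archive to project, individual and timepoint
#'
#' Registers the archive asset and attaches its series metadata. Refused
#' unless the descriptor has been confirmed as anonymized; the individual
#' and timepoint must already exist in the project.
#'
#' @param reg A `dv_registry`.
#' @param descriptor A confirmed `archive_descriptor`.
#' @param archive_path Location of the container file.
#' @param project,individual,timepoint Assignment; default to the values
#'   carried in the descriptor (e.g. from a manifest batch).
#' @return The archive asset id, invisibly.
#' @export
assign_archive <- function(reg, descriptor, archive_path,
                           project = descriptor$project,
                           individual = descriptor$individual,
                           timepoint = descriptor$timepoint) {
  stopifnot(inherits(descriptor, "archive_descriptor"))
  if (!isTRUE(descriptor$anonymized_confirmed)) {
    stop("archive must be confirmed as anonymized before it can be assigned to a project",
         call. = FALSE)
  }
  if (is.na(project) || is.na(individual) || is.na(timepoint)) {
    stop("assignment requires project, individual and timepoint", call. = FALSE)
  }
  register_asset(
    reg, descriptor$archive_id, "dicomArchive",
    project = project, individual = individual, timepoint = timepoint,
    md5 = descriptor$archive_md5, provenance_type = "upload",
    provenance_ref = "archive upload",
    files = tibble::tibble(location = archive_path, format = "tar",
                           md5 = descriptor$archive_md5),
    series = descriptor$series
  )
}

.search_fields <- c("project", "timepoint", "individual", "kind", "manufacturer",
                    "scanner_serial", "software_version", "field_strength",
                    "acquisition_date", "birth_date", "rating")

#' Search assets with conjunctive filter criteria
#'
#' Criteria are `field:op:value` triples (as strings, or a list of
#' 3-element vectors) combined with AND. Supported fields: `project`,
#' `timepoint`, `individual`, `kind`, `manufacturer`, `scanner_serial`,
#' `software_version`, `field_strength`, `acquisition_date`, `birth_date`,
#' `rating`; operators `eq, ne, lt, le, gt, ge, contains`. Dates compare as ISO
#' strings; `manufacturer` matches case-insensitively; `rating` is the
#' asset's latest score per rater. Only assets of session-active projects
#' are returned. An asset qualifies if any of its series satisfies all
#' series-level predicates simultaneously.
#'
#' @param reg A `dv_registry`.
#' @param criteria Character vector of `"field:op:value"` strings (empty for
#'   all assets of active projects).
#' @return Tibble of matching asset records.
#' @export
search_assets <- function(reg, criteria = character()) {
  crit <- purrr::map(criteria, function(x) {
    if (is.character(x) && length(x) == 1L) {
      parts <- strsplit(x, ":", fixed = TRUE)[[1]]
      if (length(parts) < 3L) stop(sprintf("malformed criterion '%s'", x), call. = FALSE)
      c(parts[1], parts[2], paste(parts[-(1:2)], collapse = ":"))
    } else if (length(x) == 3L) as.character(x)
    else stop("criteria must be field:op:value triples", call. = FALSE)
  })
  for (cr in crit) {
    if (!cr[1] %in% .search_fields) {
      stop(sprintf("unknown search field '%s'", cr[1]), call. = FALSE)
    }
  }

  rows <- .q(reg,
    "SELECT a.id, a.kind, a.project, a.individual, a.timepoint,
            s.series_uid, s.manufacturer, s.scanner_serial, s.software_version,
            s.field_strength, s.acquisition_date,
            i.date_of_birth AS birth_date,
            (SELECT MAX(score) FROM ratings r WHERE r.asset_id = a.id AND r.current = 1)
              AS rating
     FROM assets a
     JOIN projects p ON a.project = p.name AND p.active = 1
     LEFT JOIN archive_series s ON s.asset_id = a.id
     LEFT JOIN individuals i ON i.project = a.project AND i.site_id = a.individual")
  if (nrow(rows) == 0L) return(rows[0, c("id", "kind", "project", "individual", "timepoint")])

  keep <- rep(TRUE, nrow(rows))
  for (cr in crit) {
    field <- cr[1]; op <- cr[2]; value <- cr[3]
    obs <- rows[[field]]
    if (field == "manufacturer") {
      obs <- toupper(obs); value <- toupper(value)
    }
    if (field %in% c("field_strength", "rating")) {
      obs <- as.numeric(obs); value <- as.numeric(value)
    }
    res <- switch(op,
      eq = obs == value,
      ne = obs != value,
      lt = obs < value,
      le = obs <= value,
      gt = obs > value,
      ge = obs >= value,
      contains = grepl(value, obs, fixed = TRUE),
      stop(sprintf("unknown operator '%s'", op), call. = FALSE))
    res[is.na(res)] <- FALSE
    keep <- keep & res
  }
  hits <- rows[keep, ]
  out <- dplyr::distinct(hits, .data$id, .keep_all = TRUE)
  dplyr::select(out, "id", "kind", "project", "individual", "timepoint")
}

#' Render a download filename for an asset
#'
#' `download_name()` is the pure renderer; [render_download_name()] resolves
#' an asset in the registry and calls it. Preferences: `plain` gives
#' `<id>.<ext>`, `typed` gives `<kind>.<id>.<ext>`, `enriched` substitutes a
#' template of header tokens (e.g. `DCM.<AcquisitionDate>.<PatientID>`) and
#' appends `<id>.<ext>`.
#'
#' @param id Canonical asset identifier.
#' @param kind Asset kind (used by `typed`).
#' @param format File extension, e.g. `"tar"`.
#' @param preference `"plain"`, `"typed"`, or `"enriched"`.
#' @param template Token template, required for `enriched`; tokens in angle
#'   brackets are substituted from `tokens`.
#' @param tokens Named list of token values (dates in compact DICOM form).
#' @return The filename string.
#' @export
download_name <- function(id, kind, format = "tar",
                          preference = c("plain", "typed", "enriched"),
                          template = NULL, tokens = list()) {
  preference <- match.arg(preference)
  id <- as.character(id)
  if (!is_duuid(id)) stop("not a canonical identifier", call. = FALSE)
  if (preference == "plain") return(paste0(id, ".", format))
  if (preference == "typed") return(paste0(kind, ".", id, ".", format))
  if (is.null(template)) stop("enriched naming requires a template", call. = FALSE)
  out <- template
  for (tok in regmatches(template, gregexpr("<[^>]+>", template))[[1]]) {
    name <- substr(tok, 2, nchar(tok) - 1L)
    val <- tokens[[name]]
    if (is.null(val) || is.na(val)) {
      stop(sprintf("token '%s' unavailable for this asset", name), call. = FALSE)
    }
    out <- sub(tok, as.character(val), out, fixed = TRUE)
  }
  paste0(out, ".", id, ".", format)
}

#' @rdname download_name
#' @param reg A `dv_registry`.
#' @param asset_id Identifier of a registered asset.
#' @export
render_download_name <- function(reg, asset_id,
                                 preference = c("plain", "typed", "enriched"),
                                 template = NULL) {
  preference <- match.arg(preference)
  asset <- asset_get(reg, asset_id)
  fmt <- .q(reg, "SELECT format FROM asset_files WHERE asset_id = ? LIMIT 1",
            list(as.character(asset_id)))$format
  if (length(fmt) == 0L || is.na(fmt)) fmt <- "tar"
  s <- .q(reg, "SELECT * FROM archive_series WHERE asset_id = ? LIMIT 1",
          list(as.character(asset_id)))
  tokens <- list()
  if (nrow(s) == 1L) {
    tokens <- list(
      AcquisitionDate = if (!is.na(s$acquisition_date)) .iso_to_da(s$acquisition_date) else NA,
      PatientID = s$patient_id,
      Manufacturer = s$manufacturer,
      SeriesDescription = s$description,
      Modality = s$modality
    )
  }
  download_name(asset$id, asset$kind, fmt, preference, template, tokens)
}

#' Record a quality rating
#'
#' Multi-rater: each authorized rater's scores are kept separately, and the
#' full history is preserved — a new score by the same rater supersedes
#' their previous one (which stays on record as non-current).
#'
#' @param reg A `dv_registry`.
#' @param asset_id Rated asset.
#' @param rater Rater login/name.
#' @param score Integer 1--5.
#' @param note Optional free-text note.
#' @return Tibble of the asset's current ratings.
#' @export
record_rating <- function(reg, asset_id, rater, score, note = "") {
  asset_id <- as.character(asset_id)
  if (!asset_exists(reg, asset_id)) stop(sprintf("unknown asset %s", asset_id), call. = FALSE)
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score != as.integer(score) || score < 1L || score > 5L) {
    stop("score must be an integer between 1 and 5", call. = FALSE)
  }
  .x(reg, "UPDATE ratings SET current = 0 WHERE asset_id = ? AND rater = ?",
     list(asset_id, rater))
  .x(reg, "INSERT INTO ratings (asset_id, rater, score, note, timestamp, current)
           VALUES (?, ?, ?, ?, ?, 1)",
     list(asset_id, rater, as.integer(score), note,
          format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  ratings_get(reg, asset_id)
}

#' @rdname record_rating
#' @param current_only Return only each rater's current rating.
#' @export
ratings_get <- function(reg, asset_id, current_only = TRUE) {
  sql <- "SELECT asset_id, rater, score, note, timestamp, current FROM ratings WHERE asset_id = ?"
  if (current_only) sql <- paste(sql, "AND current = 1")
  .q(reg, paste(sql, "ORDER BY timestamp"), list(as.character(asset_id)))
}
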