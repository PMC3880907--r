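#' Activities, jobs, and provenance
#'
#' Processing is modeled as versioned *activity instances* — a named
#' command at a fixed version with fixed parameters, bound to a registered
#' resource and authorized for specific projects. Requesting work creates
#' *jobs* whose output-collection identifier is computed **up front** from
#' the activity triple and the sorted input identifiers; the job's staging
#' directory and its expected result file are named after that identifier.
#' Completion follows the external-upload convention: when a file named
#' `<output_id>.tar.gz` appears in the resource's output path the job is
#' completed and the output collection registered, inheriting project,
#' individual and timepoint from its inputs. Because the version is part of
#' the identifier, outputs of successive pipeline releases coexist, and
#' re-requesting identical processing without removing previous results
#' fails with a collision. Every derived asset traces back through
#' (activity, version, parameters) links to an original upload.
#'
#' @name activity
NULL

.job_states <- c("pending", "staged", "running", "completed", "failed")
.job_transitions <- list(pending = "staged", staged = c("running", "completed", "failed"),
                         running = c("completed", "failed"),
                         completed = character(), failed = character())

#' Register a compute / storage resource
#'
#' @param reg A `dv_registry`.
#' @param name Unique resource name.
#' @param host Hostname (informational at desk scale).
#' @param purpose `"processing"`, `"project-server"`, or `"dropbox"`.
#' @param input_path,output_path Staging and result directories; both are
#'   required for processing resources.
#' @param owner Owner login.
#' @return `reg`, invisibly.
#' @export
resource_add <- function(reg, name, host = "localhost",
                         purpose = c("processing", "project-server", "dropbox"),
                         input_path = NULL, output_path = NULL, owner = "local") {
  purpose <- match.arg(purpose)
  if (purpose == "processing" && (is.null(input_path) || is.null(output_path))) {
    stop("a processing resource needs both an input and an output path", call. = FALSE)
  }
  .x(reg, "INSERT INTO resources (name, host, purpose, input_path, output_path, owner)
           VALUES (?, ?, ?, ?, ?, ?)",
     list(name, host, purpose, input_path %||% NA_character_,
          output_path %||% NA_character_, owner))
  invisible(reg)
}

#' Create a versioned activity instance
#'
#' The (name, version, parameters) triple is immutable after creation and
#' unique in the store.
#'
#' @param reg A `dv_registry`.
#' @param activity_name,version Program name and version (e.g.
#'   `"freesurfer"`, `"5.1"`).
#' @param parameters Command-line parameter string (may be empty; it still
#'   distinguishes instances and output identifiers).
#' @param resource Name of a registered processing resource.
#' @param projects Projects authorized to use the instance.
#' @param stats_member Optional file name inside completed output
#'   collections holding `key value` lines; when present it is parsed into
#'   an asset-level variable collection named `<activity>-<version>` on
#'   completion.
#' @return `reg`, invisibly.
#' @export
instance_create <- function(reg, activity_name, version, parameters = "",
                            resource, projects, stats_member = NULL) {
  if (!nzchar(trimws(activity_name)) || !nzchar(trimws(version))) {
    stop("activity_name and version must be non-empty", call. = FALSE)
  }
  res <- .q(reg, "SELECT purpose FROM resources WHERE name = ?", list(resource))
  if (nrow(res) == 0L) stop(sprintf("unknown resource '%s'", resource), call. = FALSE)
  if (nrow(.q(reg, "SELECT 1 FROM instances WHERE activity_name = ? AND version = ? AND parameters = ?",
              list(activity_name, version, parameters)))) {
    stop(sprintf("instance (%s, %s, '%s') already exists", activity_name, version, parameters),
         call. = FALSE)
  }
  .x(reg, "INSERT INTO instances (activity_name, version, parameters, resource, projects, group_by, stats_member)
           VALUES (?, ?, ?, ?, ?, 'asset', ?)",
     list(activity_name, version, parameters, resource,
          paste(projects, collapse = ","), stats_member %||% NA_character_))
  invisible(reg)
}

.instance_get <- function(reg, activity_name, version, parameters = "") {
  inst <- .q(reg, "SELECT * FROM instances WHERE activity_name = ? AND version = ? AND parameters = ?",
             list(activity_name, version, parameters))
  if (nrow(inst) == 0L) {
    stop(sprintf("unknown activity instance (%s, %s, '%s')", activity_name, version, parameters),
         call. = FALSE)
  }
  inst
}

.job_get <- function(reg, output_id) {
  job <- .q(reg, "SELECT * FROM jobs WHERE output_id = ?", list(as.character(output_id)))
  if (nrow(job) == 0L) stop(sprintf("unknown job %s", output_id), call. = FALSE)
  job
}

.job_set_state <- function(reg, output_id, new, exit_code = NA_integer_, log = NA_character_) {
  job <- .job_get(reg, output_id)
  if (!new %in% .job_transitions[[job$state]]) {
    stop(sprintf("illegal job transition %s -> %s for %s", job$state, new, output_id),
         call. = FALSE)
  }
  .x(reg, "UPDATE jobs SET state = ?, finished_at = ?, exit_code = COALESCE(?, exit_code),
            log = COALESCE(?, log) WHERE output_id = ?",
     list(new,
          if (new %in% c("completed", "failed")) format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
          else NA_character_,
          exit_code, log, as.character(output_id)))
  invisible(output_id)
}

#' Request jobs for assets
#'
#' One job per asset: the output identifier is derived from the instance
#' triple and the input identifier, the staging directory
#' `<input_path>/<output_id>/` is created and populated with the input
#' files, and the job is recorded as `staged`. Assets outside the
#' instance's authorized projects are refused; an already-registered output
#' identifier (job or asset) is a collision — the request to reprocess data
#' with the same algorithm without removing previous results fails.
#'
#' @param reg A `dv_registry`.
#' @param activity_name,version,parameters Identify the instance.
#' @param asset_ids Input asset identifiers.
#' @return Tibble of created jobs (`output_id`, `input_id`, `state`,
#'   `staging_dir`).
#' @export
request_jobs <- function(reg, activity_name, version, parameters = "", asset_ids) {
  inst <- .instance_get(reg, activity_name, version, parameters)
  authorized <- strsplit(inst$projects, ",", fixed = TRUE)[[1]]
  res <- .q(reg, "SELECT * FROM resources WHERE name = ?", list(inst$resource))

  assets <- purrr::map(asset_ids, function(id) asset_get(reg, id))
  for (a in assets) {
    if (!a$project %in% authorized) {
      stop(sprintf("asset %s belongs to project '%s', which is not authorized for this instance",
                   a$id, a$project), call. = FALSE)
    }
  }
  out_ids <- vapply(asset_ids, function(id) {
    as.character(derive_output_id(activity_name, version, parameters, id))
  }, character(1))
  clash <- out_ids[vapply(out_ids, function(id) {
    asset_exists(reg, id) || nrow(.q(reg, "SELECT 1 FROM jobs WHERE output_id = ?", list(id))) > 0L
  }, logical(1))]
  if (length(clash)) {
    stop(sprintf("collision: output id(s) already registered (%s); remove previous results before reprocessing",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }

  rows <- purrr::map2(asset_ids, out_ids, function(aid, oid) {
    a <- asset_get(reg, aid)
    staging <- file.path(res$input_path, oid)
    dir.create(staging, recursive = TRUE, showWarnings = FALSE)
    locs <- .q(reg, "SELECT location FROM asset_files WHERE asset_id = ?",
               list(as.character(aid)))$location
    for (loc in locs) {
      if (dir.exists(loc)) {
        file.copy(loc, staging, recursive = TRUE)
      } else if (file.exists(loc)) {
        file.copy(loc, staging)
      }
    }
    .x(reg, "INSERT INTO jobs (output_id, activity_name, version, parameters, input_ids,
              resource, state, project, individual, timepoint, created_at, staging_dir)
             VALUES (?, ?, ?, ?, ?, ?, 'staged', ?, ?, ?, ?, ?)",
       list(oid, activity_name, version, parameters,
            jsonlite::toJSON(as.character(aid)), inst$resource,
            a$project, a$individual, a$timepoint,
            format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"), staging))
    tibble::tibble(output_id = oid, input_id = as.character(aid), state = "staged",
                   staging_dir = staging)
  })
  dplyr::bind_rows(rows)
}

#' Complete a job from an uploaded result file
#'
#' The external-completion convention: a result file must be named
#' `<output_id>.tar.gz`. A file matching a staged or running job completes
#' that job and registers the output collection under the identifier
#' computed at request time; anything else is rejected. Completing an
#' already-completed job is an error.
#'
#' @param reg A `dv_registry`.
#' @param path Path to the uploaded `<output_id>.tar.gz`.
#' @return The output-collection asset id, invisibly.
#' @export
complete_job <- function(reg, path) {
  fname <- basename(path)
  m <- regmatches(fname, regexec("^([0-9a-f-]{36})\\.tar\\.gz$", fname))[[1]]
  if (length(m) != 2L || !is_duuid(m[2])) {
    stop(sprintf("rejected: '%s' does not follow the <output_id>.tar.gz naming convention", fname),
         call. = FALSE)
  }
  oid <- m[2]
  job <- tryCatch(.job_get(reg, oid), error = function(e) {
    stop(sprintf("rejected: '%s' matches no known job", fname), call. = FALSE)
  })
  if (!job$state %in% c("staged", "running")) {
    stop(sprintf("job %s is already %s", oid, job$state), call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("result file '%s' not found", path), call. = FALSE)

  members <- tryCatch(utils::untar(path, list = TRUE, tar = "internal"),
                      error = function(e) character())
  members <- members[!grepl("/$", members)]
  if (length(members) == 0L) members <- fname  # a collection contains at least one item
  input_ids <- as.character(jsonlite::fromJSON(job$input_ids))
  register_asset(
    reg, oid, "outputCollection",
    project = job$project, individual = job$individual, timepoint = job$timepoint,
    md5 = unname(tools::md5sum(path)), provenance_type = "job", provenance_ref = oid,
    files = tibble::tibble(location = path, format = "tar",
                           md5 = unname(tools::md5sum(path))),
    parents = tibble::tibble(parent_id = input_ids,
                             activity_name = job$activity_name,
                             version = job$version, parameters = job$parameters)
  )
  .job_set_state(reg, oid, "completed")

  inst <- .q(reg, "SELECT stats_member FROM instances WHERE activity_name = ? AND version = ? AND parameters = ?",
             list(job$activity_name, job$version, job$parameters))
  if (nrow(inst) == 1L && !is.na(inst$stats_member) && inst$stats_member %in% members) {
    .ingest_stats(reg, path, inst$stats_member, oid,
                  paste0(job$activity_name, "-", job$version))
  }
  invisible(structure(oid, class = "duuid"))
}

# post-completion hook: parse `key value` lines from a declared stats member
# into an asset-level variable collection named <activity>-<version>
.ingest_stats <- function(reg, collection_tar, member, asset_id, collection_name) {
  work <- tempfile("dvstats")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE))
  utils::untar(collection_tar, files = member, exdir = work, tar = "internal")
  lines <- readLines(file.path(work, member), warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) return(invisible(NULL))
  kv <- do.call(rbind, strsplit(trimws(lines), "[ \t]+"))
  sheet <- tibble::as_tibble(stats::setNames(as.list(kv[, 2]), kv[, 1]))
  sheet$UUID <- as.character(asset_id)
  import_table(reg, sheet, collection = collection_name)
  invisible(NULL)
}

#' Run a staged job locally
#'
#' Desk-scale executor standing in for a scheduler: renders the command
#' template (`{staging}`, `{outdir}`, `{params}` placeholders), runs it via
#' the shell, captures the exit status into accounting, and on success
#' packages `{outdir}` as the properly named collection and routes it
#' through [complete_job()]. A nonzero exit marks the job failed with the
#' captured log.
#'
#' @param reg A `dv_registry`.
#' @param output_id Identifier of a staged job.
#' @param command_template Shell command with placeholders.
#' @return Tibble row of the finished job.
#' @export
run_local <- function(reg, output_id, command_template) {
  output_id <- as.character(output_id)
  job <- .job_get(reg, output_id)
  if (job$state != "staged") {
    stop(sprintf("job %s is %s, not staged", output_id, job$state), call. = FALSE)
  }
  res <- .q(reg, "SELECT * FROM resources WHERE name = ?", list(job$resource))
  outdir <- tempfile("dvrun")
  dir.create(outdir)
  on.exit(unlink(outdir, recursive = TRUE))

  cmd <- command_template
  cmd <- gsub("{staging}", job$staging_dir, cmd, fixed = TRUE)
  cmd <- gsub("{outdir}", outdir, cmd, fixed = TRUE)
  cmd <- gsub("{params}", job$parameters, cmd, fixed = TRUE)

  .job_set_state(reg, output_id, "running")
  out <- suppressWarnings(system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  log <- paste(out, collapse = "\n")

  if (status != 0L) {
    .job_set_state(reg, output_id, "failed", exit_code = as.integer(status), log = log)
    return(.job_get(reg, output_id))
  }

  produced <- list.files(outdir, recursive = TRUE)
  if (length(produced) == 0L) {
    .job_set_state(reg, output_id, "failed", exit_code = 1L,
                   log = paste0(log, "\n(no output produced)"))
    return(.job_get(reg, output_id))
  }
  result <- file.path(res$output_path, paste0(output_id, ".tar.gz"))
  dir.create(res$output_path, recursive = TRUE, showWarnings = FALSE)
  old <- setwd(outdir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(result, files = produced, compression = "gzip", tar = "internal")
  setwd(old)
  .x(reg, "UPDATE jobs SET exit_code = 0, log = ? WHERE output_id = ?",
     list(log, output_id))
  complete_job(reg, result)
  .job_get(reg, output_id)
}

#' List jobs
#' @param reg A `dv_registry`.
#' @param state Optional state filter.
#' @return Tibble of the job ledger.
#' @export
list_jobs <- function(reg, state = NULL) {
  if (is.null(state)) return(.q(reg, "SELECT * FROM jobs ORDER BY created_at"))
  .q(reg, "SELECT * FROM jobs WHERE state = ? ORDER BY created_at", list(state))
}

#' Trace an asset's provenance chain
#'
#' Walks the provenance links from the asset back to its original upload:
#' an output collection leads through its (activity, version, parameters)
#' link to its inputs, an extracted image to its archive, an archive to its
#' upload event. The chain is complete and acyclic.
#'
#' @param reg A `dv_registry`.
#' @param asset_id Asset to trace.
#' @return Tibble, one row per chain link starting at the asset itself:
#'   `depth`, `id`, `kind`, `activity_name`, `version`, `parameters`,
#'   `parent_id`.
#' @export
trace <- function(reg, asset_id) {
  asset_id <- as.character(asset_id)
  if (!asset_exists(reg, asset_id)) stop(sprintf("unknown asset %s", asset_id), call. = FALSE)
  rows <- list()
  frontier <- asset_id
  depth <- 0L
  seen <- character()
  while (length(frontier)) {
    nxt <- character()
    for (id in frontier) {
      if (id %in% seen) stop("provenance cycle detected", call. = FALSE)
      seen <- c(seen, id)
      a <- asset_get(reg, id)
      edges <- .q(reg, "SELECT parent_id, activity_name, version, parameters
                        FROM provenance WHERE asset_id = ?", list(id))
      if (nrow(edges) == 0L) {
        edges <- tibble::tibble(parent_id = NA_character_, activity_name = NA_character_,
                                version = NA_character_, parameters = NA_character_)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        depth = depth, id = id, kind = a$kind,
        activity_name = edges$activity_name, version = edges$version,
        parameters = edges$parameters, parent_id = edges$parent_id
      )
      nxt <- c(nxt, edges$parent_id[!is.na(edges$parent_id)])
    }
    frontier <- unique(nxt)
    depth <- depth + 1L
  }
  dplyr::bind_rows(rows)
}

#' Summarize the job ledger
#'
#' @param reg A `dv_registry`.
#' @param project,activity_name Optional filters.
#' @return Tibble of counts (and mean wall-clock duration where recorded)
#'   per (activity, version, state); all job states appear, zero-filled.
#' @export
accounting_summary <- function(reg, project = NULL, activity_name = NULL) {
  jobs <- list_jobs(reg)
  if (!is.null(project)) jobs <- jobs[!is.na(jobs$project) & jobs$project == project, ]
  if (!is.null(activity_name)) jobs <- jobs[jobs$activity_name == activity_name, ]
  base <- tibble::tibble(state = .job_states, n = 0L)
  if (nrow(jobs) == 0L) return(base)
  counts <- dplyr::count(jobs, .data$activity_name, .data$version, .data$state)
  grid <- tidyr::expand_grid(dplyr::distinct(jobs, .data$activity_name, .data$version),
                             state = .job_states)
  full <- dplyr::left_join(grid, counts, by = c("activity_name", "version", "state"))
  full$n[is.na(full$n)] <- 0L
  dur <- dplyr::mutate(jobs, duration = suppressWarnings(
    as.numeric(difftime(strptime(.data$finished_at, "%Y-%m-%dT%H:%M:%OS"),
                        strptime(.data$created_at, "%Y-%m-%dT%H:%M:%OS"),
                        units = "secs"))))
  dur <- dplyr::summarise(dplyr::group_by(dur, .data$activity_name, .data$version, .data$state),
                          mean_duration_s = mean(.data$duration, na.rm = TRUE),
                          .groups = "drop")
  dplyr::left_join(full, dur, by = c("activity_name", "version", "state"))
}
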