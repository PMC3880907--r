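#' Scalar variables at three attachment levels
#'
#' Tabular (clinical, cognitive, genetic, or pipeline-derived) variables are
#' grouped into named variable collections and attached at one of three
#' levels, inferred from the key columns of the imported sheet:
#'
#' * individual level — columns `Project`, `Individual` (permanent traits
#'   such as gender or genotype);
#' * timepoint level — columns `Project`, `Individual`, `TimePoint`
#'   (visit-specific measures such as cognitive tests);
#' * asset level — a single `UUID` key column (measures describing one
#'   asset, e.g. volumes from a processing pipeline; the asset already knows
#'   its project, individual and timepoint, so providing the identifier is
#'   enough).
#'
#' The first line of the sheet names the fields; re-using a collection name
#' adds data to that collection, and identically keyed fields are queryable
#' across projects.
#'
#' @name scalar_data
NULL

.level_keys <- list(
  individual = c("Project", "Individual"),
  timepoint = c("Project", "Individual", "TimePoint")
)

.uuid_col <- function(nms) nms[toupper(nms) %in% c("UUID", "ASSETID", "ASSET_ID")]

.infer_level <- function(nms) {
  has_uuid <- length(.uuid_col(nms)) > 0L
  has_tp <- "TimePoint" %in% nms
  has_ind <- all(c("Project", "Individual") %in% nms)
  if (has_uuid && (has_tp || has_ind)) {
    stop("ambiguous sheet layout: both a UUID key and Project/Individual/TimePoint keys present",
         call. = FALSE)
  }
  if (has_uuid) return("asset")
  if (has_ind && has_tp) return("timepoint")
  if (has_ind) return("individual")
  stop("cannot infer attachment level: need Project+Individual(+TimePoint) columns or a UUID column",
       call. = FALSE)
}

#' Import a scalar-variable sheet into a collection
#'
#' Upserts records keyed by the sheet's key columns; identical re-import is
#' a no-op, while a conflicting value for an existing key+field is a
#' row-level error (no silent overwrite). Unknown asset identifiers and
#' unknown individuals are row-level errors too; the import continues.
#'
#' @param reg A `dv_registry`.
#' @param table CSV path or data frame. A path named
#'   `<project>.<collection>.csv` supplies the collection name if
#'   `collection` is `NULL`.
#' @param collection Variable-collection name.
#' @return A `scalar_import_report`: list with `collection`, `level`,
#'   `new`, `updated`, `unchanged`, and an `errors` tibble.
#' @export
import_table <- function(reg, table, collection = NULL) {
  from_file <- is.character(table) && length(table) == 1L
  tbl <- if (from_file) utils::read.csv(table, stringsAsFactors = FALSE,
                                        check.names = FALSE, colClasses = "character")
         else as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(collection) && from_file) {
    m <- regmatches(basename(table), regexec("^[^.]+\\.(.+)\\.csv$", basename(table)))[[1]]
    if (length(m) == 2L) collection <- m[2]
  }
  if (is.null(collection)) stop("no collection name given or inferable from the file name",
                                call. = FALSE)
  if (nrow(tbl) == 0L && ncol(tbl) == 0L) stop("empty sheet: header row required", call. = FALSE)

  level <- .infer_level(names(tbl))
  keys <- if (level == "asset") .uuid_col(names(tbl)) else .level_keys[[level]]
  fields <- setdiff(names(tbl), keys)
  if (length(fields) == 0L) stop("sheet has key columns but no variable fields", call. = FALSE)

  existing <- .q(reg, "SELECT level, fields FROM collections WHERE name = ?", list(collection))
  if (nrow(existing)) {
    if (!identical(existing$level, level)) {
      stop(sprintf("collection '%s' is %s-level; sheet layout is %s-level",
                   collection, existing$level, level), call. = FALSE)
    }
    merged <- union(strsplit(existing$fields, ",", fixed = TRUE)[[1]], fields)
    .x(reg, "UPDATE collections SET fields = ? WHERE name = ?",
       list(paste(merged, collapse = ","), collection))
  } else {
    .x(reg, "INSERT INTO collections (name, level, fields) VALUES (?, ?, ?)",
       list(collection, level, paste(fields, collapse = ",")))
  }

  new <- 0L; updated <- 0L; unchanged <- 0L
  errors <- list()
  fail <- function(i, msg) errors[[length(errors) + 1L]] <<- tibble::tibble(row = i, error = msg)

  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, , drop = FALSE]
    if (level == "asset") {
      aid <- trimws(as.character(row[[keys]]))
      if (!is_duuid(aid) || !asset_exists(reg, aid)) {
        fail(i, sprintf("unknown asset UUID '%s'", aid)); next
      }
      key <- list(project = "", individual = "", timepoint = "", asset_id = aid)
    } else {
      proj <- trimws(row$Project); ind <- trimws(row$Individual)
      if (!nzchar(proj) || !nzchar(ind)) { fail(i, "missing Project/Individual key"); next }
      if (!nrow(.q(reg, "SELECT 1 FROM individuals WHERE project = ? AND site_id = ?",
                   list(proj, ind)))) {
        fail(i, sprintf("unknown individual '%s' in project '%s'", ind, proj)); next
      }
      tp <- if (level == "timepoint") trimws(row$TimePoint) else ""
      if (level == "timepoint" &&
          !nrow(.q(reg, "SELECT 1 FROM timepoints WHERE project = ? AND label = ?",
                   list(proj, tp)))) {
        fail(i, sprintf("unknown timepoint '%s' in project '%s'", tp, proj)); next
      }
      key <- list(project = proj, individual = ind, timepoint = tp, asset_id = "")
    }

    prior <- .q(reg, "SELECT field, value FROM scalars WHERE collection = ? AND project = ?
                      AND individual = ? AND timepoint = ? AND asset_id = ?",
                c(list(collection), key))
    row_new <- nrow(prior) == 0L
    conflict <- FALSE; wrote <- FALSE
    for (f in fields) {
      v <- as.character(row[[f]])
      if (is.na(v) || !nzchar(v)) next
      old <- prior$value[prior$field == f]
      if (length(old) == 1L) {
        if (!identical(old, v)) {
          fail(i, sprintf("conflicting value for field '%s' (has '%s', sheet has '%s')",
                          f, old, v))
          conflict <- TRUE
          break
        }
      } else {
        .x(reg, "INSERT INTO scalars (collection, project, individual, timepoint, asset_id, field, value)
                 VALUES (?, ?, ?, ?, ?, ?, ?)",
           c(list(collection), key, list(f, v)))
        wrote <- TRUE
      }
    }
    if (conflict) next
    if (row_new && wrote) new <- new + 1L
    else if (wrote) updated <- updated + 1L
    else unchanged <- unchanged + 1L
  }

  structure(list(collection = collection, level = level, new = new,
                 updated = updated, unchanged = unchanged,
                 errors = if (length(errors)) dplyr::bind_rows(errors)
                          else tibble::tibble(row = integer(), error = character())),
            class = "scalar_import_report")
}

#' @export
print.scalar_import_report <- function(x, ...) {
  cat(sprintf("<scalar import> '%s' (%s level): %d new, %d updated, %d unchanged, %d error(s)\n",
              x$collection, x$level, x$new, x$updated, x$unchanged, nrow(x$errors)))
  invisible(x)
}

#' List variable collections
#' @param reg A `dv_registry`.
#' @return Tibble (`name`, `level`, `fields`).
#' @export
list_collections <- function(reg) {
  .q(reg, "SELECT name, level, fields FROM collections ORDER BY name")
}

.maybe_numeric <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (all(is.na(v) == is.na(x))) v else x
}

#' Cross-level wide-table query
#'
#' Aggregates variables from all three attachment levels into one wide
#' table: one row per (individual, timepoint) in scope. Individual-level
#' variables repeat across an individual's rows; asset-level variables join
#' through the asset's own project/individual/timepoint assignment. Missing
#' values stay missing — nothing is fabricated.
#'
#' @param reg A `dv_registry`.
#' @param projects Projects to query (must be active in the session).
#' @param variables Character vector of `"collection.field"` names, >= 1.
#' @param timepoints Optional filter of timepoint labels.
#' @param asset_mode When several assets carry values for the same
#'   (individual, timepoint): `"expand"` emits one row per asset,
#'   `"strict"` errors.
#' @return A tibble with columns `project`, `individual`, `timepoint`
#'   (plus `asset_id` when asset-level variables are expanded) and one
#'   column per requested variable; numeric where all values parse.
#' @export
query_scalars <- function(reg, projects, variables, timepoints = NULL,
                          asset_mode = c("expand", "strict")) {
  asset_mode <- match.arg(asset_mode)
  if (length(variables) == 0L) stop("at least one variable must be requested", call. = FALSE)
  inactive <- setdiff(projects, active_projects(reg))
  if (length(inactive)) {
    stop("project(s) not active in this session: ", paste(inactive, collapse = ", "),
         call. = FALSE)
  }

  parsed <- purrr::map(variables, function(v) {
    m <- regmatches(v, regexec("^(.+)\\.([^.]+)$", v))[[1]]
    if (length(m) != 3L) stop(sprintf("variable '%s' is not of the form collection.field", v),
                              call. = FALSE)
    info <- .q(reg, "SELECT level, fields FROM collections WHERE name = ?", list(m[2]))
    if (nrow(info) == 0L) stop(sprintf("unknown collection '%s'", m[2]), call. = FALSE)
    if (!m[3] %in% strsplit(info$fields, ",", fixed = TRUE)[[1]]) {
      stop(sprintf("unknown variable '%s' in collection '%s'", m[3], m[2]), call. = FALSE)
    }
    list(name = v, collection = m[2], field = m[3], level = info$level)
  })

  grid <- dplyr::bind_rows(purrr::map(projects, function(p) {
    inds <- .q(reg, "SELECT site_id FROM individuals WHERE project = ? ORDER BY site_id",
               list(p))$site_id
    tps <- project_timepoints(reg, p)
    if (!is.null(timepoints)) tps <- intersect(tps, timepoints)
    if (length(inds) == 0L || length(tps) == 0L) return(NULL)
    tidyr::expand_grid(project = p, individual = inds, timepoint = tps)
  }))
  if (nrow(grid) == 0L) {
    return(tibble::tibble(project = character(), individual = character(),
                          timepoint = character()))
  }

  has_asset_vars <- any(vapply(parsed, function(v) v$level == "asset", logical(1)))
  if (has_asset_vars) {
    acolls <- unique(vapply(purrr::keep(parsed, ~ .x$level == "asset"),
                            function(v) v$collection, character(1)))
    ph <- paste(rep("?", length(acolls)), collapse = ",")
    amap <- .q(reg, sprintf(
      "SELECT DISTINCT s.asset_id, a.project, a.individual, a.timepoint
       FROM scalars s JOIN assets a ON a.id = s.asset_id
       WHERE s.collection IN (%s)", ph), as.list(acolls))
    if (asset_mode == "strict") {
      dup <- dplyr::count(amap, .data$project, .data$individual, .data$timepoint)
      if (any(dup$n > 1L)) {
        stop("multiple assets carry values for the same (individual, timepoint); use asset_mode = 'expand'",
             call. = FALSE)
      }
    }
    grid <- dplyr::left_join(grid, amap,
                             by = c("project", "individual", "timepoint"))
    grid <- dplyr::rename(grid, asset_id = "asset_id")
  }

  for (v in parsed) {
    vals <- .q(reg, "SELECT project, individual, timepoint, asset_id, value
                     FROM scalars WHERE collection = ? AND field = ?",
               list(v$collection, v$field))
    col <- switch(v$level,
      individual = {
        m <- dplyr::select(vals, "project", "individual", value = "value")
        dplyr::left_join(grid, m, by = c("project", "individual"))$value
      },
      timepoint = {
        m <- dplyr::select(vals, "project", "individual", "timepoint", value = "value")
        dplyr::left_join(grid, m, by = c("project", "individual", "timepoint"))$value
      },
      asset = {
        m <- dplyr::select(vals, "asset_id", value = "value")
        dplyr::left_join(grid, m, by = "asset_id")$value
      })
    grid[[v$name]] <- .maybe_numeric(col)
  }
  grid
}
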