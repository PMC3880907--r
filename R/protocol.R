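#' Acquisition protocols and compliance gating
#'
#' A protocol names, per project, the acquisition parameters an image type
#' must satisfy (echo time, repetition time, slice thickness, ...). Series
#' are validated against the protocol before image assets may be extracted
#' from an archive: by default extraction of acquisitions with invalid
#' scanning parameters is rejected. Ranges are closed intervals evaluated
#' after unit normalization (ms, mm, T); tolerance belongs in the range
#' itself, not in an epsilon.
#'
#' @name protocol
NULL

#' Constraint constructors
#'
#' @param min,max Inclusive numeric bounds, `min <= max`.
#' @param units Optional unit label (documentation only; values are expected
#'   already normalized to ms / mm / T).
#' @param value Exact string a parameter must equal.
#' @param values Allowed set of strings.
#' @return A constraint object usable in [protocol_define()].
#' @export
constraint_range <- function(min, max, units = NULL) {
  if (!is.numeric(min) || !is.numeric(max) || is.na(min) || is.na(max) || min > max) {
    stop("malformed range constraint: need numeric min <= max", call. = FALSE)
  }
  structure(list(type = "range", min = as.numeric(min), max = as.numeric(max),
                 units = units), class = "dv_constraint")
}

#' @rdname constraint_range
#' @export
constraint_exact <- function(value) {
  if (!is.character(value) || length(value) != 1L) {
    stop("malformed exact constraint: need a single string", call. = FALSE)
  }
  structure(list(type = "exact", value = value), class = "dv_constraint")
}

#' @rdname constraint_range
#' @export
constraint_set <- function(values) {
  if (!is.character(values) || length(values) == 0L) {
    stop("malformed set constraint: need >= 1 string", call. = FALSE)
  }
  structure(list(type = "set", values = values), class = "dv_constraint")
}

.constraint_label <- function(con) {
  switch(con$type,
         range = sprintf("[%g, %g]%s", con$min, con$max,
                         if (is.null(con$units)) "" else paste0(" ", con$units)),
         exact = sprintf("== '%s'", con$value),
         set = sprintf("in {%s}", paste(con$values, collapse = ", ")),
         stop("malformed constraint", call. = FALSE))
}

.constraint_holds <- function(con, observed) {
  if (is.null(observed) || length(observed) == 0L || all(is.na(observed))) return(FALSE)
  observed <- observed[1]
  switch(con$type,
         range = {
           v <- suppressWarnings(as.numeric(observed))
           !is.na(v) && v >= con$min && v <= con$max
         },
         exact = identical(as.character(observed), con$value),
         set = as.character(observed) %in% con$values,
         stop("malformed constraint", call. = FALSE))
}

#' Define an acquisition protocol
#'
#' @param name Protocol name.
#' @param project Project the protocol belongs to.
#' @param image_type Image type label produced by compliant series (e.g.
#'   `"T1"`).
#' @param constraints Named list of constraints ([constraint_range()],
#'   [constraint_exact()], [constraint_set()]); names are series-record
#'   parameters (`echo_time`, `repetition_time`, `slice_thickness`,
#'   `modality`, `field_strength`, `manufacturer`, ...). At least one.
#' @param active Whether the protocol is confirmed for automatic extraction.
#'   New protocols start inactive; run a test validation, then
#'   [protocol_activate()].
#' @return A `protocol_definition`.
#' @export
protocol_define <- function(name, project, image_type, constraints, active = FALSE) {
  stopifnot(is.character(name), nzchar(name), is.character(project),
            is.character(image_type))
  if (!is.list(constraints) || length(constraints) == 0L ||
      is.null(names(constraints)) || any(!nzchar(names(constraints)))) {
    stop("a protocol needs >= 1 named constraint", call. = FALSE)
  }
  ok <- vapply(constraints, inherits, logical(1), what = "dv_constraint")
  if (!all(ok)) stop("malformed constraint(s): ", paste(names(constraints)[!ok], collapse = ", "),
                     call. = FALSE)
  structure(list(name = name, project = project, image_type = image_type,
                 constraints = constraints, active = isTRUE(active)),
            class = "protocol_definition")
}

#' Confirm a protocol as valid, enabling automatic extraction
#' @param protocol A `protocol_definition`.
#' @return The protocol with its `active` flag set.
#' @export
protocol_activate <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_definition"))
  protocol$active <- TRUE
  protocol
}

#' Validate one series record against a protocol
#'
#' Every constraint is evaluated; a missing parameter counts as a violation
#' (strict policy: absence of evidence of compliance is non-compliance).
#'
#' @param series A series record: a named list or one-row data frame with
#'   the descriptor's series fields (`series_uid`, `echo_time`, ...).
#' @param protocol A `protocol_definition`.
#' @return A `validation_result`: list with `series_uid`, `compliant`, and a
#'   `violations` tibble (parameter, observed, constraint).
#' @export
validate_series <- function(series, protocol) {
  stopifnot(inherits(protocol, "protocol_definition"))
  if (is.data.frame(series)) series <- as.list(series[1, , drop = FALSE])
  rows <- purrr::imap(protocol$constraints, function(con, param) {
    observed <- series[[param]]
    if (.constraint_holds(con, observed)) return(NULL)
    tibble::tibble(parameter = param,
                   observed = if (is.null(observed) || length(observed) == 0L ||
                                  all(is.na(observed))) NA_character_
                              else as.character(observed[1]),
                   constraint = .constraint_label(con))
  })
  violations <- dplyr::bind_rows(rows)
  if (nrow(violations) == 0L) {
    violations <- tibble::tibble(parameter = character(), observed = character(),
                                 constraint = character())
  }
  structure(list(series_uid = series$series_uid %||% NA_character_,
                 compliant = nrow(violations) == 0L,
                 violations = violations),
            class = "validation_result")
}

#' Dry-run a protocol against every series of a descriptor
#'
#' The "test search" used before confirming a protocol: validate-only, no
#' assets are created.
#'
#' @param descriptor An `archive_descriptor` (or its `series` tibble).
#' @param protocol A `protocol_definition`.
#' @return Tibble with one row per series: `series_uid`, `compliant`,
#'   `n_violations`, and a `violations` list-column.
#' @export
protocol_test <- function(descriptor, protocol) {
  series <- if (inherits(descriptor, "archive_descriptor")) descriptor$series else descriptor
  stopifnot(is.data.frame(series))
  res <- purrr::map(seq_len(nrow(series)), function(i) {
    validate_series(as.list(series[i, ]), protocol)
  })
  tibble::tibble(
    series_uid = vapply(res, function(r) r$series_uid, character(1)),
    compliant = vapply(res, function(r) r$compliant, logical(1)),
    n_violations = vapply(res, function(r) nrow(r$violations), integer(1)),
    violations = purrr::map(res, "violations")
  )
}

#' Save / load a protocol definition as JSON
#' @param protocol A `protocol_definition`.
#' @param path File path.
#' @return `protocol_save()`: `path`, invisibly. `protocol_load()`: the
#'   `protocol_definition`.
#' @export
protocol_save <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol_definition"))
  x <- unclass(protocol)
  x$constraints <- purrr::map(x$constraints, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname protocol_save
#' @export
protocol_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cons <- purrr::map(x$constraints, function(con) {
    switch(con$type,
           range = constraint_range(con$min, con$max, con$units),
           exact = constraint_exact(con$value),
           set = constraint_set(unlist(con$values)),
           stop("malformed constraint in ", path, call. = FALSE))
  })
  protocol_define(x$name, x$project, x$image_type, cons, active = isTRUE(x$active))
}

#' @export
print.protocol_definition <- function(x, ...) {
  cat(sprintf("<protocol> %s (project %s, image type %s, %s)\n", x$name, x$project,
              x$image_type, if (x$active) "active" else "inactive"))
  for (p in names(x$constraints)) {
    cat(sprintf("  %s %s\n", p, .constraint_label(x$constraints[[p]])))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
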