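#' Deterministic asset identifiers
#'
#' Every asset managed by dicomvault carries a deterministic universally
#' unique identifier (dUUID): a 128-bit number computed from what the asset
#' *is* (its content checksums) or from the process that created it (activity
#' name, version, parameters, inputs), never drawn at random. Identical
#' content always maps to the identical identifier on any platform, which
#' turns accidental re-registration into a hard collision error and lets
#' archives migrate between stores without re-identification.
#'
#' The recipe is an RFC-4122-style name-based UUID: the SHA-1 digest of a
#' fixed namespace UUID concatenated with the canonical key string, truncated
#' to 128 bits with the version nibble forced to 5 and the variant bits to
#' `10`. The canonical key string is the asset kind and its key components
#' joined with an ASCII unit separator (0x1F); separator and escape
#' characters occurring inside components are backslash-escaped so distinct
#' component lists can never collide on the joined string.
#'
#' @name duuid
NULL

# Fixed project-independent namespace. Deliberately NOT mixed with any
# per-store identity so archives keep their ids across stores.
DUUID_NAMESPACE <- "b5e1f8c2-7d94-4c1a-9f3e-2a6b8d0c4e71"

.kinds <- new.env(parent = emptyenv())

.default_kinds <- c("dicomArchive", "image", "outputCollection")

.kind_registry <- function() {
  if (is.null(.kinds$set)) .kinds$set <- .default_kinds
  .kinds$set
}

#' Register an additional asset kind
#'
#' The built-in kinds are `dicomArchive`, `image` and `outputCollection`.
#' User-defined asset types (the system is open to new binary asset types)
#' must be registered before identifiers can be derived for them.
#'
#' @param kind Character scalar naming the new asset kind.
#' @return The updated character vector of registered kinds, invisibly.
#' @export
register_asset_kind <- function(kind) {
  stopifnot(is.character(kind), length(kind) == 1L, nzchar(kind))
  .kinds$set <- union(.kind_registry(), kind)
  invisible(.kinds$set)
}

#' Construct an asset key
#'
#' An asset key is the deterministic input to identifier derivation: a
#' registered asset kind plus an ordered list of key components (for a DICOM
#' archive, the sorted per-file md5 checksums; for an activity output, the
#' activity triple plus sorted input identifiers). Components are trimmed;
#' empty components are rejected.
#'
#' @param kind Registered asset kind (e.g. `"dicomArchive"`).
#' @param components Character vector of key components, all non-empty.
#' @return An object of class `asset_key`.
#' @export
asset_key <- function(kind, components) {
  if (!is.character(kind) || length(kind) != 1L || !nzchar(kind)) {
    stop("`kind` must be a single non-empty string", call. = FALSE)
  }
  if (!kind %in% .kind_registry()) {
    stop(sprintf("unknown asset kind '%s' (register it with register_asset_kind())", kind),
         call. = FALSE)
  }
  components <- trimws(as.character(components))
  if (length(components) == 0L || any(is.na(components)) || any(!nzchar(components))) {
    stop("invalid asset key: components must be non-empty strings", call. = FALSE)
  }
  structure(list(kind = kind, components = components), class = "asset_key")
}

# Unit separator join with escaping, so c("a","b") can never collide
# with c("a\x1fb").
.escape_component <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\x1f", "\\\x1f", x, fixed = TRUE)
}

canonical_key_string <- function(key) {
  stopifnot(inherits(key, "asset_key"))
  paste(c(key$kind, .escape_component(key$components)), collapse = "\x1f")
}

#' Derive the deterministic identifier for an asset key
#'
#' @param key An [asset_key()].
#' @return A `duuid`: the 36-character canonical lowercase rendering
#'   (8-4-4-4-12 hex groups) with class `"duuid"`.
#' @examples
#' derive_id(asset_key("dicomArchive", c("aa", "bb")))
#' @export
derive_id <- function(key) {
  if (!inherits(key, "asset_key")) {
    stop("`key` must be an asset_key", call. = FALSE)
  }
  name <- canonical_key_string(key)
  bytes <- c(duuid_parse(DUUID_NAMESPACE), charToRaw(enc2utf8(name)))
  dg <- digest::digest(bytes, algo = "sha1", serialize = FALSE, raw = TRUE)
  id <- dg[1:16]
  id[7] <- as.raw(bitwOr(bitwAnd(as.integer(id[7]), 0x0FL), 0x50L))
  id[9] <- as.raw(bitwOr(bitwAnd(as.integer(id[9]), 0x3FL), 0x80L))
  duuid_render(id)
}

#' Derive the identifier of an activity output collection
#'
#' Output identifiers are computed from the activity name, version,
#' parameters, and the identifiers of all inputs. Inputs are sorted before
#' keying, so request order is irrelevant; the version is part of the key, so
#' re-running a newer release of the same pipeline yields a fresh identifier
#' while re-requesting the identical processing collides.
#'
#' @param activity_name,version Non-empty strings identifying the activity.
#' @param parameters Command-line parameter string of the activity instance
#'   (may be empty; it still participates in the key).
#' @param input_ids Character vector of input `duuid`s, non-empty.
#' @return A `duuid`.
#' @export
derive_output_id <- function(activity_name, version, parameters, input_ids) {
  if (!nzchar(trimws(activity_name)) || !nzchar(trimws(version))) {
    stop("activity_name and version must be non-empty", call. = FALSE)
  }
  input_ids <- as.character(input_ids)
  if (length(input_ids) == 0L) {
    stop("output identifier requires at least one input id", call. = FALSE)
  }
  input_ids <- vapply(input_ids, function(x) duuid_render(duuid_parse(x)), character(1))
  key <- asset_key("outputCollection",
                   c(trimws(activity_name), trimws(version),
                     paste0("p:", parameters), sort(unname(input_ids))))
  derive_id(key)
}

#' Render 16 identifier bytes in canonical form
#'
#' @param bytes A raw vector of length 16.
#' @return The canonical 36-character lowercase string, class `"duuid"`:
#'   32 hex digits in groups of 8-4-4-4-12 separated by four hyphens.
#' @export
duuid_render <- function(bytes) {
  stopifnot(is.raw(bytes), length(bytes) == 16L)
  h <- paste(format(bytes), collapse = "")
  s <- paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
             substr(h, 17, 20), substr(h, 21, 32), sep = "-")
  structure(tolower(s), class = "duuid")
}

#' Parse a canonical identifier string back to its 16 bytes
#'
#' @param x A 36-character canonical identifier string.
#' @return Raw vector of length 16.
#' @export
duuid_parse <- function(x) {
  x <- tolower(as.character(x))
  if (length(x) != 1L || !grepl(duuid_regex(), x)) {
    stop(sprintf("not a canonical identifier: '%s'", x), call. = FALSE)
  }
  h <- gsub("-", "", x, fixed = TRUE)
  as.raw(strtoi(substring(h, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

#' Canonical identifier grammar
#'
#' @return The regular expression matched by every canonical rendering:
#'   lowercase hex in 8-4-4-4-12 groups.
#' @export
duuid_regex <- function() {
  "^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$"
}

#' Test whether a string is a canonical identifier
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_duuid <- function(x) {
  grepl(duuid_regex(), tolower(as.character(x)))
}

#' @export
print.duuid <- function(x, ...) {
  cat("<duuid> ", unclass(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.duuid <- function(x, ...) unclass(x)

#' @export
as.character.duuid <- function(x, ...) unclass(x)
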