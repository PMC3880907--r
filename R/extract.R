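#' Protocol-gated image extraction
#'
#' Turns the compliant series of an assigned archive into image assets. Each
#' image asset's identifier derives from the series content (the sorted
#' per-file md5s), so extracting a series that is byte-identical to one
#' already extracted — from this archive or any other — collides instead of
#' silently duplicating. Non-compliant series are rejected, not extracted:
#' every series ends up as exactly one asset or one rejection record.
#'
#' @param reg A `dv_registry`; the archive must already be assigned
#'   ([assign_archive()]).
#' @param archive Path to the `<id>.tar.gz` container.
#' @param protocol An active [protocol_define()] for the archive's project.
#' @param target Directory for extracted image files; defaults to a
#'   directory next to the archive.
#' @param descriptor Optional pre-loaded `archive_descriptor`.
#' @return List with `assets` (tibble: `id`, `series_uid`, `image_type`,
#'   `path`) and `rejections` (tibble: `series_uid`, `n_violations`,
#'   `violations` list-column).
#' @export
extract_images <- function(reg, archive, protocol, target = NULL, descriptor = NULL) {
  stopifnot(inherits(protocol, "protocol_definition"))
  if (!isTRUE(protocol$active)) {
    stop("protocol must be confirmed (protocol_activate()) before automatic extraction; use protocol_test() for a dry run",
         call. = FALSE)
  }
  desc <- descriptor %||% descriptor_read(.sidecar_path(archive))
  arch <- asset_get(reg, desc$archive_id)
  if (!identical(arch$project, protocol$project)) {
    stop(sprintf("archive %s belongs to project '%s', protocol to '%s'",
                 desc$archive_id, arch$project, protocol$project), call. = FALSE)
  }
  target <- target %||% file.path(dirname(archive), paste0(desc$archive_id, ".images"))

  checks <- protocol_test(desc, protocol)
  compliant <- checks$series_uid[checks$compliant]

  # derive all ids first; a collision aborts before any write
  ids <- vapply(compliant, function(uid) {
    md5s <- desc$files$md5[desc$files$series_uid == uid]
    as.character(derive_id(asset_key("image", sort(md5s))))
  }, character(1))
  clash <- ids[vapply(ids, function(id) asset_exists(reg, id), logical(1))]
  if (length(clash)) {
    stop(sprintf("collision: image asset(s) already registered (%s); extraction refused",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("collision: archive contains byte-identical series", call. = FALSE)
  }

  asset_rows <- purrr::map2(compliant, ids, function(uid, id) {
    outdir <- file.path(target, id)
    files <- extract_series(archive, uid, outdir, descriptor = desc)
    srow <- desc$series[desc$series$series_uid == uid, ]
    register_asset(
      reg, id, "image",
      project = arch$project, individual = arch$individual, timepoint = arch$timepoint,
      md5 = desc$files$md5[desc$files$series_uid == uid][1],
      provenance_type = "extraction", provenance_ref = desc$archive_id,
      files = tibble::tibble(location = outdir, format = "dicom", md5 = NA_character_),
      series = srow,
      parents = tibble::tibble(parent_id = desc$archive_id,
                               activity_name = "imageExtraction",
                               version = DESCRIPTOR_FORMAT_VERSION,
                               parameters = protocol$name)
    )
    tibble::tibble(id = id, series_uid = uid, image_type = protocol$image_type,
                   path = outdir)
  })

  rejections <- checks[!checks$compliant, c("series_uid", "n_violations", "violations")]
  assets <- dplyr::bind_rows(asset_rows)
  if (nrow(assets) == 0L) {
    assets <- tibble::tibble(id = character(), series_uid = character(),
                             image_type = character(), path = character())
  }
  list(assets = assets, rejections = rejections)
}
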