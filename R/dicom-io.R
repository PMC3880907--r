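#' Minimal DICOM Part-10 reader and writer
#'
#' dicomvault ships its own small codec for DICOM Part-10 files restricted to
#' the Explicit VR Little Endian transfer syntax (1.2.840.10008.1.2.1), which
#' is what the bundled study generator emits and what the archival layer needs
#' to read back: a fixed set of header attributes (patient, acquisition,
#' scanner-provenance and image-geometry tags) plus uncompressed pixel data.
#' It is a codec for *managing* files, not a general DICOM toolkit: sequences,
#' other transfer syntaxes and vendor private tags are out of scope, and
#' unknown tags are skipped on read and preserved only inside the archived
#' bytes (archives always store the original file verbatim).
#'
#' @name dicom_io
NULL

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_MR <- "1.2.840.10008.5.1.4.1.1.4"
# Implementation / synthetic-UID root: a reserved sub-arc so generated UIDs
# can never collide with real studies.
DV_UID_ROOT <- "1.2.826.0.1.3680043.10.1187"

# keyword -> group, element, VR
.dcm_dict <- local({
  d <- rbind(
    c("SOPClassUID",               0x0008, 0x0016, "UI"),
    c("SOPInstanceUID",            0x0008, 0x0018, "UI"),
    c("AcquisitionDate",           0x0008, 0x0022, "DA"),
    c("Modality",                  0x0008, 0x0060, "CS"),
    c("Manufacturer",              0x0008, 0x0070, "LO"),
    c("InstitutionAddress",        0x0008, 0x0081, "ST"),
    c("ReferringPhysicianName",    0x0008, 0x0090, "PN"),
    c("SeriesDescription",         0x0008, 0x103E, "LO"),
    c("PatientName",               0x0010, 0x0010, "PN"),
    c("PatientID",                 0x0010, 0x0020, "LO"),
    c("PatientBirthDate",          0x0010, 0x0030, "DA"),
    c("PatientSex",                0x0010, 0x0040, "CS"),
    c("OtherPatientIDs",           0x0010, 0x1000, "LO"),
    c("SliceThickness",            0x0018, 0x0050, "DS"),
    c("RepetitionTime",            0x0018, 0x0080, "DS"),
    c("EchoTime",                  0x0018, 0x0081, "DS"),
    c("MagneticFieldStrength",     0x0018, 0x0087, "DS"),
    c("DeviceSerialNumber",        0x0018, 0x1000, "LO"),
    c("SoftwareVersions",          0x0018, 0x1020, "LO"),
    c("StudyInstanceUID",          0x0020, 0x000D, "UI"),
    c("SeriesInstanceUID",         0x0020, 0x000E, "UI"),
    c("InstanceNumber",            0x0020, 0x0013, "IS"),
    c("SamplesPerPixel",           0x0028, 0x0002, "US"),
    c("PhotometricInterpretation", 0x0028, 0x0004, "CS"),
    c("Rows",                      0x0028, 0x0010, "US"),
    c("Columns",                   0x0028, 0x0011, "US"),
    c("BitsAllocated",             0x0028, 0x0100, "US"),
    c("BitsStored",                0x0028, 0x0101, "US"),
    c("HighBit",                   0x0028, 0x0102, "US"),
    c("PixelRepresentation",       0x0028, 0x0103, "US"),
    c("PixelData",                 0x7FE0, 0x0010, "OW")
  )
  data.frame(keyword = d[, 1],
             group = as.integer(d[, 2]), element = as.integer(d[, 3]),
             vr = d[, 4], stringsAsFactors = FALSE)
})

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.pad_even <- function(bytes, pad) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.encode_value <- function(vr, value) {
  if (vr == "US") return(writeBin(as.integer(value), raw(), size = 2L, endian = "little"))
  if (vr == "OW" || vr == "OB") return(.pad_even(as.raw(value), as.raw(0L)))
  # all remaining VRs here are character-like (UI DA CS LO PN ST DS IS)
  s <- if (vr %in% c("DS", "IS")) {
    paste(vapply(value, function(v) format(v, scientific = FALSE, trim = TRUE), character(1)),
          collapse = "\\")
  } else {
    paste(as.character(value), collapse = "\\")
  }
  .pad_even(charToRaw(s), if (vr == "UI") as.raw(0L) else charToRaw(" "))
}

.encode_element <- function(group, element, vr, value_bytes) {
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  header <- c(.u16(group), .u16(element), charToRaw(vr),
              if (long) c(as.raw(c(0L, 0L)), .u32(length(value_bytes)))
              else .u16(length(value_bytes)))
  c(header, value_bytes)
}

#' Write a DICOM Part-10 file (Explicit VR Little Endian)
#'
#' @param path Output file path.
#' @param elements Named list of dataset attributes (DICOM keywords from the
#'   supported dictionary, e.g. `PatientID`, `EchoTime`, `SeriesInstanceUID`).
#'   `PixelData` may be given as a raw vector or integer vector (16-bit,
#'   unsigned). `NULL` entries are dropped.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(path, elements) {
  elements <- elements[!vapply(elements, is.null, logical(1))]
  unknown <- setdiff(names(elements), .dcm_dict$keyword)
  if (length(unknown)) {
    stop("unsupported DICOM keyword(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(elements$SOPClassUID)) elements$SOPClassUID <- SOP_CLASS_MR
  if (is.null(elements$SOPInstanceUID)) {
    stop("SOPInstanceUID is required", call. = FALSE)
  }

  idx <- match(names(elements), .dcm_dict$keyword)
  ord <- order(.dcm_dict$group[idx], .dcm_dict$element[idx])
  body <- raw(0)
  for (i in ord) {
    kw <- names(elements)[i]
    row <- .dcm_dict[match(kw, .dcm_dict$keyword), ]
    vb <- .encode_value(row$vr, elements[[kw]])
    body <- c(body, .encode_element(row$group, row$element, row$vr, vb))
  }

  meta_elems <- c(
    .encode_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    .encode_element(0x0002L, 0x0002L, "UI", .encode_value("UI", elements$SOPClassUID)),
    .encode_element(0x0002L, 0x0003L, "UI", .encode_value("UI", elements$SOPInstanceUID)),
    .encode_element(0x0002L, 0x0010L, "UI", .encode_value("UI", TRANSFER_SYNTAX_EXPLICIT_LE)),
    .encode_element(0x0002L, 0x0012L, "UI", .encode_value("UI", DV_UID_ROOT))
  )
  meta <- c(.encode_element(0x0002L, 0x0000L, "UL", .u32(length(meta_elems))), meta_elems)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' Test whether a file carries the DICOM Part-10 magic
#' @param path File path.
#' @return Logical scalar.
#' @export
is_dicom_file <- function(path) {
  if (!file.exists(path) || file.info(path)$isdir) return(FALSE)
  if (file.info(path)$size < 132L) return(FALSE)
  head <- readBin(path, raw(), n = 132L)
  identical(rawToChar(head[129:132]), "DICM")
}

.decode_value <- function(vr, bytes) {
  if (vr == "US") return(readBin(bytes, integer(), n = length(bytes) %/% 2L,
                                 size = 2L, endian = "little", signed = FALSE))
  if (vr %in% c("OW", "OB")) return(bytes)
  s <- rawToChar(bytes[bytes != as.raw(0L)])
  s <- sub("[ ]+$", "", s)
  if (vr %in% c("DS", "IS")) {
    v <- suppressWarnings(as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]]))
    return(v)
  }
  s
}

#' Read a DICOM Part-10 file (Explicit VR Little Endian)
#'
#' Parses the file meta group, requires the Explicit VR Little Endian
#' transfer syntax, and decodes every dictionary attribute it knows;
#' attributes outside the dictionary are skipped (they remain untouched in
#' the file itself).
#'
#' @param path Path to a Part-10 file.
#' @return Named list of decoded attributes; `PixelData` (if present) is a
#'   raw vector.
#' @export
read_dicom <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 132L) stop(sprintf("'%s' is not a DICOM Part-10 file", path), call. = FALSE)
  bytes <- readBin(path, raw(), n = n)
  if (!identical(rawToChar(bytes[129:132]), "DICM")) {
    stop(sprintf("'%s' is not a DICOM Part-10 file (missing DICM magic)", path), call. = FALSE)
  }
  pos <- 133L
  out <- list()
  transfer_syntax <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n + 1L && pos + 7L <= length(bytes) + 1L) {
    group <- readBin(bytes[pos:(pos + 1L)], integer(), size = 2L,
                     endian = "little", signed = FALSE)
    element <- readBin(bytes[(pos + 2L):(pos + 3L)], integer(), size = 2L,
                       endian = "little", signed = FALSE)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop(sprintf("unsupported (implicit VR?) encoding in '%s'", path), call. = FALSE)
    }
    if (vr %in% long_vrs) {
      len <- readBin(bytes[(pos + 8L):(pos + 11L)], integer(), size = 4L,
                     endian = "little")
      vstart <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6L):(pos + 7L)], integer(), size = 2L,
                     endian = "little", signed = FALSE)
      vstart <- pos + 8L
    }
    if (len < 0L || vstart + len - 1L > length(bytes)) {
      stop(sprintf("truncated DICOM element in '%s'", path), call. = FALSE)
    }
    value_bytes <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw(0)
    if (group == 0x0002L && element == 0x0010L) {
      transfer_syntax <- .decode_value("UI", value_bytes)
    }
    hit <- which(.dcm_dict$group == group & .dcm_dict$element == element)
    if (length(hit) == 1L) {
      out[[.dcm_dict$keyword[hit]]] <- .decode_value(.dcm_dict$vr[hit], value_bytes)
    }
    pos <- vstart + len
  }
  if (!is.null(transfer_syntax) && !identical(transfer_syntax, TRANSFER_SYNTAX_EXPLICIT_LE)) {
    stop(sprintf("unsupported transfer syntax '%s' in '%s'", transfer_syntax, path),
         call. = FALSE)
  }
  out
}

# DICOM DA (YYYYMMDD) <-> ISO-8601
.da_to_iso <- function(x) {
  if (is.null(x) || !nzchar(x)) return(NA_character_)
  if (!grepl("^[0-9]{8}$", x)) return(NA_character_)
  paste(substr(x, 1, 4), substr(x, 5, 6), substr(x, 7, 8), sep = "-")
}

.iso_to_da <- function(x) gsub("-", "", x, fixed = TRUE)

# Deterministic UID under the reserved synthetic root: decimal components
# from a SHA-1 of the parts. Always < 64 chars, never collides with real
# scanner UIDs.
dicom_uid <- function(...) {
  h <- digest::digest(paste(..., sep = "\x1f"), algo = "sha1", serialize = FALSE)
  a <- strtoi(substr(h, 1, 7), 16L)
  b <- strtoi(substr(h, 8, 14), 16L)
  c <- strtoi(substr(h, 15, 21), 16L)
  paste(DV_UID_ROOT, a, b, c, sep = ".")
}
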