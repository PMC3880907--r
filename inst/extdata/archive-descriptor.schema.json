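{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "DICOM archive descriptor",
  "description": "Sidecar document of a single-file DICOM archive, carrying the three metadata domains: the archive itself, the series it contains, and every member file with its md5 checksum.",
  "type": "object",
  "required": ["archive_id", "archive_md5", "format_version", "anonymized_confirmed", "series", "files"],
  "properties": {
    "archive_id": {
      "type": "string",
      "pattern": "^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$",
      "description": "Deterministic identifier derived from the sorted per-file md5s."
    },
    "archive_md5": {
      "type": "string",
      "pattern": "^[0-9a-f]{32}$",
      "description": "md5 of the compressed container bytes (descriptor excluded)."
    },
    "format_version": { "type": "string", "enum": ["1.0"] },
    "created": { "type": "string" },
    "anonymized_confirmed": { "type": "boolean" },
    "project": { "type": ["string", "null"] },
    "individual": { "type": ["string", "null"] },
    "timepoint": { "type": ["string", "null"] },
    "series": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["series_uid", "file_count"],
        "properties": {
          "series_uid": { "type": "string" },
          "modality": { "type": ["string", "null"] },
          "description": { "type": ["string", "null"] },
          "echo_time": { "type": ["number", "null"], "description": "ms" },
          "repetition_time": { "type": ["number", "null"], "description": "ms" },
          "slice_thickness": { "type": ["number", "null"], "description": "mm" },
          "manufacturer": { "type": ["string", "null"] },
          "scanner_serial": { "type": ["string", "null"] },
          "software_version": { "type": ["string", "null"] },
          "field_strength": { "type": ["number", "null"], "description": "tesla" },
          "acquisition_date": { "type": ["string", "null"], "description": "ISO-8601 date" },
          "patient_id": { "type": ["string", "null"] },
          "patient_birth_date": { "type": ["string", "null"], "description": "ISO-8601 date" },
          "file_count": { "type": "integer", "minimum": 1 }
        }
      }
    },
    "files": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["member_path", "md5", "series_uid"],
        "properties": {
          "member_path": { "type": "string" },
          "sop_instance_uid": { "type": ["string", "null"] },
          "instance_number": { "type": ["integer", "null"] },
          "md5": { "type": "string", "pattern": "^[0-9a-f]{32}$" },
          "series_uid": { "type": "string" }
        }
      }
    }
  }
}
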