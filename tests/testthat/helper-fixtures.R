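# Shared fixtures, all generated in code at test time.

# Independent reference for name-based identifiers, deliberately built on a
# different crypto library (openssl) than the implementation (digest).
oracle_uuid <- function(kind, components) {
  esc <- function(x) gsub("\x1f", "\\\x1f", gsub("\\", "\\\\", x, fixed = TRUE), fixed = TRUE)
  name <- paste(c(kind, esc(trimws(components))), collapse = "\x1f")
  ns_hex <- gsub("-", "", "b5e1f8c2-7d94-4c1a-9f3e-2a6b8d0c4e71")
  ns <- as.raw(strtoi(substring(ns_hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  dg <- openssl::sha1(c(ns, charToRaw(enc2utf8(name))))
  bytes <- as.raw(dg)[1:16]
  bytes[7] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[7]), 0x0FL), 0x50L))
  bytes[9] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[9]), 0x3FL), 0x80L))
  h <- paste(format(bytes), collapse = "")
  tolower(paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
                substr(h, 17, 20), substr(h, 21, 32), sep = "-"))
}

# md5 oracle: the system md5sum utility (external to R)
oracle_md5 <- function(paths) {
  out <- system2("md5sum", shQuote(paths), stdout = TRUE)
  vapply(strsplit(out, " +"), `[[`, character(1), 1L)
}

fixture_study <- function(seed = 7, dir = withr::local_tempdir(.local_envir = parent.frame()),
                          ...) {
  generate_study(study_spec(seed = seed, ...), dir)
}

session_table <- function(study) {
  unique(study$series[, c("project", "individual", "timepoint", "session_dir")])
}

# registry populated with a study: project + individuals registered, all
# sessions archived via a manifest, confirmed and assigned
fixture_registry <- function(study, archive_dir = withr::local_tempdir(.local_envir = parent.frame())) {
  reg <- registry_open()
  spec <- study$spec
  project_create(reg, spec$project, timepoints = spec$timepoints)
  inds <- unique(study$series[, c("project", "individual", "gender", "patient_birth_date")])
  register_individuals(reg, data.frame(Project = inds$project, SiteId = inds$individual,
                                       Gender = inds$gender,
                                       DateOfBirth = inds$patient_birth_date))
  sess <- session_table(study)
  manifest <- data.frame(Project = sess$project, Individual = sess$individual,
                         TimePoint = sess$timepoint, SourceLocation = sess$session_dir,
                         TargetLocation = archive_dir)
  batch <- run_archive_jobs(batch_from_manifest(manifest))
  stopifnot(all(batch$status == "ok"))
  for (i in seq_len(nrow(batch))) {
    desc <- confirm_anonymized(descriptor_read(batch$descriptor_path[i]),
                               batch$descriptor_path[i])
    assign_archive(reg, desc, batch$archive[i])
  }
  list(reg = reg, study = study, batch = batch)
}

# processing resource + io dirs for job tests
fixture_resource <- function(reg, name = "local",
                             root = withr::local_tempdir(.local_envir = parent.frame())) {
  inp <- file.path(root, "in"); outp <- file.path(root, "out")
  dir.create(inp, recursive = TRUE); dir.create(outp, recursive = TRUE)
  resource_add(reg, name, purpose = "processing", input_path = inp, output_path = outp)
  list(name = name, input = inp, output = outp)
}

stats_template <- function() {
  "printf 'Hippocampus 4100.5\nCortexVol 450000\n' > {outdir}/stats.txt"
}
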