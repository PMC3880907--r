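one_session <- function(seed = 7) {
  study <- fixture_study(seed = seed, dir = withr::local_tempdir(.local_envir = parent.frame()))
  sess <- session_table(study)
  list(study = study, dir = sess$session_dir[1],
       truth = study$series[study$series$session_dir == sess$session_dir[1], ],
       files = study$files[study$files$path %in%
                             list.files(sess$session_dir[1], recursive = TRUE,
                                        full.names = TRUE), ])
}

test_that("the descriptor documents archive, series and files with md5s", {
  fx <- one_session()
  desc <- build_descriptor(fx$dir)
  expect_s3_class(desc, "archive_descriptor")
  expect_identical(nrow(desc$series), 2L)
  expect_identical(nrow(desc$files), 6L)
  expect_identical(sum(desc$series$file_count), nrow(desc$files))
  expect_false(desc$anonymized_confirmed)
  expect_match(desc$archive_id, duuid_regex())
  # md5s equal the external checksum utility's values
  m <- match(desc$files$source_path, fx$study$files$path)
  expect_identical(desc$files$md5, unname(oracle_md5(fx$study$files$path[m])))
  # series metadata reflects the truth table
  tr <- fx$truth[match(desc$series$series_uid, fx$truth$series_uid), ]
  expect_equal(desc$series$echo_time, tr$echo_time)
  expect_identical(desc$series$manufacturer, tr$manufacturer)
  expect_identical(desc$series$acquisition_date, tr$acquisition_date)
  expect_identical(desc$series$patient_birth_date, tr$patient_birth_date)
  expect_silent(descriptor_validate(desc))
})

test_that("degenerate folders are rejected", {
  empty <- withr::local_tempdir()
  expect_error(build_descriptor(empty), "no files")
  expect_error(build_descriptor(file.path(empty, "nope")), "does not exist")

  fx <- one_session()
  bad <- file.path(fx$dir, "series_1", "notes.txt")
  writeLines("scanner operator notes", bad)
  withr::defer(unlink(bad))
  expect_error(build_descriptor(fx$dir, strict = TRUE), "notes.txt")
  desc <- build_descriptor(fx$dir, strict = FALSE)
  expect_identical(nrow(desc$files), 6L)
})

test_that("create/extract round-trips byte-identically and leaves the archive untouched", {
  fx <- one_session()
  target <- withr::local_tempdir()
  out <- create_archive(fx$dir, target)
  expect_true(file.exists(out$archive))
  expect_identical(basename(out$archive), paste0(out$descriptor$archive_id, ".tar.gz"))
  expect_true(file.exists(out$descriptor_path))
  expect_identical(out$descriptor$archive_md5, unname(oracle_md5(out$archive)))

  # compression is genuinely lossless and effective on the low-entropy fixture
  expect_lt(file.info(out$archive)$size, sum(file.info(fx$study$files$path[
    fx$study$files$series_uid %in% fx$truth$series_uid])$size))

  md5_before <- oracle_md5(out$archive)
  uid <- out$descriptor$series$series_uid[2]
  exdir <- withr::local_tempdir()
  got <- extract_series(out$archive, uid, exdir)
  expect_identical(length(got), 3L)
  expect_identical(unname(oracle_md5(sort(got))),
                   desc_md5 <- out$descriptor$files$md5[out$descriptor$files$series_uid == uid])
  expect_identical(oracle_md5(out$archive), md5_before)
  expect_error(extract_series(out$archive, "1.2.3.not.there", exdir), "not present")

  # full verification passes on the untouched archive
  rep <- verify_archive(out$archive)
  expect_true(rep$archive_ok)
  expect_true(rep$all_ok)
  expect_true(all(rep$files$ok))
})

test_that("identical content gives identical identity; same target collides", {
  fx <- one_session()
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  a1 <- create_archive(fx$dir, t1)
  a2 <- create_archive(fx$dir, t2)
  expect_identical(a1$descriptor$archive_id, a2$descriptor$archive_id)
  expect_error(create_archive(fx$dir, t1), "collision")
})

test_that("corruption of a single member is localized by verification", {
  fx <- one_session()
  out <- create_archive(fx$dir, withr::local_tempdir())
  desc <- out$descriptor
  # rebuild a copy of the archive with one member's byte flipped
  work <- withr::local_tempdir()
  utils::untar(out$archive, exdir = work, tar = "internal")
  victim <- desc$files$member_path[4]
  vpath <- file.path(work, victim)
  bytes <- readBin(vpath, raw(), file.info(vpath)$size)
  bytes[200] <- xor(bytes[200], as.raw(0xFF))
  writeBin(bytes, vpath)
  corrupted <- file.path(withr::local_tempdir(), basename(out$archive))
  withr::with_dir(work, utils::tar(corrupted, files = "series",
                                   compression = "gzip", tar = "internal"))
  file.copy(out$descriptor_path, sub("\\.tar\\.gz$", ".json", corrupted))

  rep <- verify_archive(corrupted)
  expect_false(rep$all_ok)
  expect_identical(rep$files$member_path[!rep$files$ok], victim)
  expect_identical(sum(!rep$files$ok), 1L)
  expect_error(verify_archive(file.path(withr::local_tempdir(), "ghost.tar.gz")),
               "not found")
})

test_that("descriptors reject unknown format versions and broken conservation", {
  fx <- one_session()
  desc <- build_descriptor(fx$dir)
  bad <- desc; bad$format_version <- "9.9"
  expect_error(descriptor_validate(bad), "format_version")
  bad2 <- desc; bad2$series$file_count[1] <- bad2$series$file_count[1] + 1L
  expect_error(descriptor_validate(bad2), "conservation")
})

test_that("manifest batches archive every row and survive per-row failures", {
  study <- fixture_study(seed = 9)
  sess <- session_table(study)
  target <- withr::local_tempdir()
  manifest_df <- data.frame(Project = sess$project, Individual = sess$individual,
                            TimePoint = sess$timepoint, SourceLocation = sess$session_dir,
                            TargetLocation = target)[1:5, ]
  mpath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(manifest_df, mpath, row.names = FALSE)

  specs <- batch_from_manifest(mpath)
  expect_identical(nrow(specs), 5L)
  res <- run_archive_jobs(specs)
  expect_identical(sum(res$status == "ok"), 5L)
  expect_true(all(file.exists(res$archive)))
  expect_true(all(file.exists(res$descriptor_path)))
  # descriptors carry the row's assignment
  d <- descriptor_read(res$descriptor_path[3])
  expect_identical(d$project, manifest_df$Project[3])
  expect_identical(d$individual, manifest_df$Individual[3])
  expect_identical(d$timepoint, manifest_df$TimePoint[3])

  # header-only manifest -> zero jobs
  empty <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(manifest_df[0, ], empty, row.names = FALSE)
  expect_identical(nrow(batch_from_manifest(empty)), 0L)

  # missing column is named
  expect_error(batch_from_manifest(manifest_df[, -3]), "TimePoint")

  # a bad source fails its row only
  manifest_df$SourceLocation[2] <- file.path(target, "no-such-folder")
  manifest_df$TargetLocation <- withr::local_tempdir()
  res2 <- run_archive_jobs(batch_from_manifest(manifest_df))
  expect_identical(res2$status, c("ok", "failed", "ok", "ok", "ok"))
  expect_match(res2$error[2], "does not exist")
})

test_that("phi scan flags planted identifying headers and only those", {
  clean <- fixture_study(seed = 4, n_individuals = 1L, timepoints = "M00")
  expect_identical(nrow(phi_scan(session_table(clean)$session_dir[1])), 0L)

  dirty <- generate_study(
    study_spec(seed = 4, n_individuals = 1L, timepoints = "M00",
               phi = list(PatientName = "DOE^JANE")),
    withr::local_tempdir())
  rep <- phi_scan(session_table(dirty)$session_dir[1])
  expect_identical(sort(unique(rep$tag)), "PatientName")
  expect_identical(unique(rep$value), "DOE^JANE")
  # flagged for every affected series
  expect_setequal(rep$series_uid, dirty$series$series_uid)

  expect_error(phi_scan(session_table(clean)$session_dir[1], watchlist = character()),
               "watchlist")

  # scanning an archive file works too
  out <- create_archive(session_table(dirty)$session_dir[1], withr::local_tempdir())
  rep2 <- phi_scan(out$archive)
  expect_identical(sort(unique(rep2$tag)), "PatientName")
})
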