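test_that("individual import is idempotent and collects row errors", {
  reg <- registry_open(); withr::defer(registry_close(reg))
  project_create(reg, "adni", timepoints = c("M00", "M12"))
  tbl <- data.frame(Project = "adni", SiteId = c("S001", "S002", "S003", "S004"),
                    Gender = c("F", "M", "F", "M"),
                    DateOfBirth = c("1950-01-01", "1961-06-15", "1970-12-31", "1940-03-03"))
  r1 <- register_individuals(reg, tbl)
  expect_identical(r1$new, 4L)
  r2 <- register_individuals(reg, tbl)
  expect_identical(r2$new, 0L)
  expect_identical(r2$existing, 4L)

  bad <- rbind(tbl, data.frame(Project = "adni", SiteId = "", Gender = "F",
                               DateOfBirth = NA))
  r3 <- register_individuals(reg, bad)
  expect_identical(r3$new, 0L)
  expect_identical(nrow(r3$errors), 1L)
  expect_match(r3$errors$error, "SiteId")
})

test_that("an individual list file routes to its project by naming convention", {
  reg <- registry_open(); withr::defer(registry_close(reg))
  project_create(reg, "adni", timepoints = "M00")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "adni.individuals.list.csv")
  utils::write.csv(data.frame(SiteId = c("A1", "A2")), path, row.names = FALSE)
  r <- register_individuals(reg, path)
  expect_identical(r$new, 2L)
  expect_identical(nrow(.q(reg, "SELECT * FROM individuals WHERE project = 'adni'")), 2L)
})

test_that("duplicate asset registration always collides, never overwrites", {
  reg <- registry_open(); withr::defer(registry_close(reg))
  project_create(reg, "p", timepoints = "M00")
  register_individuals(reg, data.frame(Project = "p", SiteId = "S1"))
  id <- derive_id(asset_key("dicomArchive", "deadbeef"))
  register_asset(reg, id, "dicomArchive", project = "p", individual = "S1",
                 timepoint = "M00")
  # fuzz: many duplicate attempts never break store-wide uniqueness
  for (i in 1:1000) {
    expect_error(register_asset(reg, id, "dicomArchive", project = "p",
                                individual = "S1", timepoint = "M00"),
                 "collision")
  }
  expect_identical(nrow(.q(reg, "SELECT * FROM assets")), 1L)
  # one differing key component -> distinct id -> both register
  id2 <- derive_id(asset_key("dicomArchive", "deadbeee"))
  expect_false(identical(as.character(id), as.character(id2)))
  register_asset(reg, id2, "dicomArchive", project = "p", individual = "S1",
                 timepoint = "M00")
  expect_identical(nrow(.q(reg, "SELECT * FROM assets")), 2L)
})

test_that("referential integrity is enforced at registration", {
  reg <- registry_open(); withr::defer(registry_close(reg))
  project_create(reg, "p", timepoints = "M00")
  register_individuals(reg, data.frame(Project = "p", SiteId = "S1"))
  id <- derive_id(asset_key("image", "x1"))
  expect_error(register_asset(reg, id, "image", project = "ghost"), "unknown project")
  expect_error(register_asset(reg, id, "image", project = "p", individual = "S9"),
               "unknown individual")
  expect_error(register_asset(reg, id, "image", project = "p", individual = "S1",
                              timepoint = "M99"), "unknown timepoint")
  expect_error(register_asset(reg, "not-an-id", "image"), "canonical")
})

test_that("archives cannot be assigned before anonymization is confirmed", {
  study <- fixture_study(seed = 5, n_individuals = 1L, timepoints = "M00")
  sess <- session_table(study)
  out <- create_archive(sess$session_dir[1], withr::local_tempdir(),
                        project = "p", individual = "S001", timepoint = "M00")
  reg <- registry_open(); withr::defer(registry_close(reg))
  project_create(reg, "p", timepoints = "M00")
  register_individuals(reg, data.frame(Project = "p", SiteId = "S001"))

  expect_error(assign_archive(reg, out$descriptor, out$archive), "anonymized")
  confirmed <- confirm_anonymized(out$descriptor)
  expect_error(assign_archive(reg, confirmed, out$archive, timepoint = "M99"),
               "unknown timepoint")
  id <- assign_archive(reg, confirmed, out$archive)
  listed <- list_assets(reg, project = "p")
  expect_identical(listed$id, as.character(id))
  expect_identical(listed$kind, "dicomArchive")
})

test_that("search reproduces a planted birth/date/scanner filter exactly", {
  # 10 archives with varied demographics and scanners
  study <- fixture_study(seed = 21, n_individuals = 10L, timepoints = "M00",
                         templates = list(series_template()),
                         birth_year_range = c(1940L, 1980L),
                         acq_date_range = c("2004-06-01", "2008-06-01"),
                         violation_rate = 0)
  fx <- fixture_registry(study)
  withr::defer(registry_close(fx$reg))

  truth <- study$series
  expected <- truth$series_uid[truth$patient_birth_date < "1963-01-01" &
                               truth$acquisition_date >= "2006-02-01" &
                               toupper(truth$manufacturer) != "SIEMENS"]
  got <- search_assets(fx$reg, c("birth_date:lt:1963-01-01",
                                 "acquisition_date:ge:2006-02-01",
                                 "manufacturer:ne:SIEMENS"))
  exp_assets <- unique(truth$individual[truth$series_uid %in% expected])
  expect_setequal(got$individual, exp_assets)
  expect_identical(nrow(got), length(exp_assets))

  # empty criteria -> all assets of active projects
  expect_identical(nrow(search_assets(fx$reg)), 10L)
  # deactivating the project empties the result
  project_deactivate(fx$reg, "synth")
  expect_identical(nrow(search_assets(fx$reg)), 0L)
  project_activate(fx$reg, "synth")
  expect_identical(nrow(search_assets(fx$reg)), 10L)
  # unknown fields are rejected
  expect_error(search_assets(fx$reg, "shoe_size:eq:42"), "unknown search field")
})

test_that("download names reproduce the documented renaming forms", {
  id <- "6d0b1c00-2a11-4aaa-a337-3ba06e9ee2ef"
  expect_identical(download_name(id, "dicomArchive", "tar", "plain"),
                   "6d0b1c00-2a11-4aaa-a337-3ba06e9ee2ef.tar")
  expect_identical(download_name(id, "dicomArchive", "tar", "typed"),
                   "dicomArchive.6d0b1c00-2a11-4aaa-a337-3ba06e9ee2ef.tar")
  expect_identical(
    download_name(id, "dicomArchive", "tar", "enriched",
                  template = "DCM.<AcquisitionDate>.<PatientID>",
                  tokens = list(AcquisitionDate = "20060315", PatientID = "S001")),
    "DCM.20060315.S001.6d0b1c00-2a11-4aaa-a337-3ba06e9ee2ef.tar")
  expect_error(download_name(id, "dicomArchive", "tar", "enriched",
                             template = "<NoSuchToken>", tokens = list()),
               "unavailable")
  expect_error(download_name(id, "dicomArchive", "tar", "enriched"), "template")
})

test_that("registry-resolved names embed the asset's own headers", {
  study <- fixture_study(seed = 5, n_individuals = 1L, timepoints = "M00")
  fx <- fixture_registry(study)
  withr::defer(registry_close(fx$reg))
  aid <- fx$batch$archive_id[1]
  expect_identical(render_download_name(fx$reg, aid, "plain"), paste0(aid, ".tar"))
  expect_identical(render_download_name(fx$reg, aid, "typed"),
                   paste0("dicomArchive.", aid, ".tar"))
  truth <- study$series[study$series$session_dir == fx$batch$SourceLocation[1], ][1, ]
  enriched <- render_download_name(fx$reg, aid, "enriched",
                                   template = "DCM.<AcquisitionDate>.<PatientID>")
  expect_identical(enriched, paste0("DCM.", gsub("-", "", truth$acquisition_date), ".",
                                    truth$patient_id, ".", aid, ".tar"))
})

test_that("ratings are multi-rater with preserved history and a 1-5 scale", {
  reg <- registry_open(); withr::defer(registry_close(reg))
  project_create(reg, "p", timepoints = "M00")
  register_individuals(reg, data.frame(Project = "p", SiteId = "S1"))
  id <- register_asset(reg, derive_id(asset_key("image", "r1")), "image",
                       project = "p", individual = "S1", timepoint = "M00")

  record_rating(reg, id, "alice", 4, "good contrast")
  cur <- record_rating(reg, id, "bob", 2, "motion artifact")
  expect_identical(nrow(cur), 2L)  # two raters, two current ratings
  expect_setequal(cur$rater, c("alice", "bob"))

  cur2 <- record_rating(reg, id, "alice", 5)
  expect_identical(nrow(cur2), 2L)
  expect_identical(cur2$score[cur2$rater == "alice"], 5L)
  hist <- ratings_get(reg, id, current_only = FALSE)
  expect_identical(nrow(hist), 3L)  # full history preserved
  expect_identical(sum(hist$current), 2L)

  expect_error(record_rating(reg, id, "carol", 0), "between 1 and 5")
  expect_error(record_rating(reg, id, "carol", 6), "between 1 and 5")
  expect_error(record_rating(reg, id, "carol", 3.5), "between 1 and 5")
})
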